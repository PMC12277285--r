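#' Homeostatic structural plasticity primitives
#'
#' The HSP controller senses activity through a per-neuron calcium trace
#' `Ca` that decays exponentially with time constant `tau_ca_s` and jumps by
#' `beta_ca` at each spike of the owning neuron; its stationary mean under
#' Poisson firing at rate `r` is `beta * tau_ca * r`. With the default
#' `beta = 1/tau_ca` the trace is numerically the firing rate in Hz.
#'
#' Both synaptic element types (axonal boutons, dendritic spines) follow the
#' same linear growth rule toward the calcium setpoint `eps`:
#' `dz = nu_g * (1 - Ca/eps) * dt`, clipped so `z >= 0`. Neurons below the
#' setpoint grow elements, neurons above it retract them.
#'
#' These functions are the scalar/vector form of the update the engine
#' applies at every structural step; they are exposed for scripted analyses
#' and for verifying the engine against closed forms.
#'
#' @param ca Calcium trace value(s).
#' @param n_spikes Number of spikes of the owning neuron within `dt_s`,
#'   all treated as occurring at the end of the interval.
#' @param dt_s Elapsed time (s).
#' @param tau_ca_s,beta_ca Trace decay constant (s) and per-spike increment.
#' @return Updated trace value(s).
#' @export
update_calcium <- function(ca, n_spikes, dt_s, tau_ca_s, beta_ca) {
  stopifnot(dt_s > 0, tau_ca_s > 0, beta_ca > 0)
  ca * exp(-dt_s / tau_ca_s) + n_spikes * beta_ca
}

#' @rdname update_calcium
#' @param z Element count(s) (continuous, non-negative).
#' @param nu_g Maximal element growth rate (elements/s).
#' @param eps Calcium setpoint.
#' @return `grow_elements()`: updated element count(s), clipped at zero.
#' @export
grow_elements <- function(z, ca, nu_g, eps, dt_s) {
  stopifnot(dt_s > 0, nu_g > 0, eps > 0)
  pmax(0, z + nu_g * (1 - ca / eps) * dt_s)
}

#' @rdname update_calcium
#' @param times Spike times (s) of one neuron.
#' @param t_eval Evaluation time(s) (s).
#' @return `calcium_trace()`: the closed-form trace
#'   `sum(beta * exp(-(t - t_i)/tau))` over spikes before `t`.
#' @export
calcium_trace <- function(times, t_eval, tau_ca_s, beta_ca) {
  vapply(t_eval, function(t) {
    s <- times[times <= t]
    sum(beta_ca * exp(-(t - s) / tau_ca_s))
  }, numeric(1))
}

#' One rewiring step of the structural plasticity rule
#'
#' Applies the synapse deletion/formation mechanics to an E-E connectivity
#' state given the continuous element counts:
#' \enumerate{
#'   \item Deletion: every neuron whose bound elements of a type exceed
#'     `floor(z)` removes the deficit by deleting uniformly random synapses
#'     from its synapse multiset (axonal deficits first, then dendritic;
#'     neurons in random order). The counterpart element of each removed
#'     synapse returns to its owner's free pool.
#'   \item Formation: all free axonal and free dendritic elements are pooled
#'     and paired uniformly at random without replacement until one pool is
#'     exhausted; self-pairings are redrawn (skipped if only self-pairings
#'     remain), so the matrix stays autapse-free. Multapses are allowed.
#' }
#'
#' @param A Sparse or dense `n_E x n_E` integer synapse-count matrix
#'   (`A[i, j]` = synapses from `j` onto `i`, zero diagonal).
#' @param z_axon,z_dend Per-neuron continuous element counts.
#' @param seed Seed for the rewiring stream.
#' @return List with the updated `A` (a `dgCMatrix`) and an `events` data
#'   frame (`type` is `"form"` or `"delete"`, `pre`, `post`).
#' @export
rewire <- function(A, z_axon, z_dend, seed = 1L) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  n_E <- nrow(A)
  if (ncol(A) != n_E) stop("A must be square")
  tr <- Matrix::summary(A)
  keep <- tr$x != 0
  pre <- rep.int(tr$j[keep], tr$x[keep])
  post <- rep.int(tr$i[keep], tr$x[keep])
  res <- cpp_rewire(n_E, as.integer(pre), as.integer(post),
                    as.numeric(z_axon), as.numeric(z_dend), as.double(seed))
  A2 <- Matrix::sparseMatrix(i = res$ee_post, j = res$ee_pre,
                             x = rep.int(1, length(res$ee_pre)),
                             dims = c(n_E, n_E))
  ev <- res$events
  list(A = A2,
       events = data.frame(
         type = ifelse(ev$type > 0, "form", "delete"),
         pre = ev$pre, post = ev$post))
}
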