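#' Construct an ungrown network
#'
#' Builds the static scaffold of the inhibition-dominated network: all
#' connections that involve inhibitory neurons (E-to-I, I-to-E, I-to-I) are
#' drawn once as Erdos-Renyi random graphs with probability `p_static` and
#' remain fixed for the lifetime of the network. The plastic E-to-E
#' connectivity starts empty and is grown by the homeostatic structural
#' plasticity rule (see [grow_network()]).
#'
#' Neurons are indexed globally: excitatory neurons are `1..n_E`, inhibitory
#' neurons are `n_E+1..n_E+n_I`.
#'
#' @param cfg An `hsp_config`.
#' @param seed Master seed; all random choices (scaffold, background input,
#'   stimuli, rewiring) derive from it.
#' @return An object of class `hsp_network`.
#' @export
new_network <- function(cfg, seed = 1L) {
  sz <- config_sizes(cfg)
  er_block <- function(n_pre, n_post, p, exclude_diag = FALSE) {
    pre <- integer(0); post <- integer(0)
    for (i in seq_len(n_post)) {
      k <- stats::rbinom(1L, n_pre, p)
      if (k > 0) {
        src <- sample.int(n_pre, k)
        if (exclude_diag) src <- src[src != i]
        pre <- c(pre, src)
        post <- c(post, rep.int(i, length(src)))
      }
    }
    list(pre = pre, post = post)
  }
  set.seed(seed)
  ei <- er_block(sz$n_E, sz$n_I, cfg$p_static)
  ie <- er_block(sz$n_I, sz$n_E, cfg$p_static)
  ii <- er_block(sz$n_I, sz$n_I, cfg$p_static, exclude_diag = TRUE)
  net <- list(
    n_E = sz$n_E, n_I = sz$n_I,
    ee_pre = integer(0), ee_post = integer(0),
    ei_pre = ei$pre, ei_post = ei$post,
    ie_pre = ie$pre, ie_post = ie$post,
    ii_pre = ii$pre, ii_post = ii$post,
    state = new_state(sz$n_E, sz$n_I),
    seed = as.integer(seed),
    meta = list()
  )
  class(net) <- "hsp_network"
  net
}

new_state <- function(n_E, n_I) {
  n <- n_E + n_I
  list(v_mv = numeric(n), ref_ms = numeric(n), ca = numeric(n_E),
       z_axon = numeric(n_E), z_dend = numeric(n_E), t0_s = 0)
}

net_core <- function(net) {
  net[c("n_E", "n_I", "ee_pre", "ee_post", "ei_pre", "ei_post",
        "ie_pre", "ie_post", "ii_pre", "ii_post")]
}

#' E-to-E connectivity matrix
#'
#' Returns the synapse-count matrix `A` as a sparse matrix, with `A[i, j]`
#' the number of synapses from excitatory neuron `j` onto excitatory neuron
#' `i` (multapses allowed, diagonal structurally zero).
#'
#' @param net An `hsp_network`.
#' @return A `dgCMatrix` of dimension `n_E x n_E`.
#' @export
connectivity_matrix <- function(net) {
  stopifnot(inherits(net, "hsp_network"))
  Matrix::sparseMatrix(i = net$ee_post, j = net$ee_pre,
                       x = rep.int(1, length(net$ee_pre)),
                       dims = c(net$n_E, net$n_E))
}

#' Poisson and DC drive segments
#'
#' Drive segments are the time-stamped entries of a stimulation schedule.
#' A Poisson segment delivers an independent Poisson spike train at
#' `rate_hz` to every neuron in `mask`, each event depolarizing the membrane
#' by `weight_mv`. A DC segment models the somatic polarization induced by
#' transcranial direct-current stimulation: a constant drive whose
#' threshold-free stationary effect on the membrane potential is exactly
#' `delta_vm_mv` (positive = depolarizing/anodal, negative =
#' hyperpolarizing/cathodal), implemented as an additive term in the
#' membrane equation (not a shifted resting potential).
#'
#' @param rate_hz Poisson rate per target neuron (1/s).
#' @param weight_mv Depolarization per input spike (mV).
#' @param mask Integer vector of global neuron ids.
#' @param start_s,duration_s Onset time and duration (s).
#' @return A drive segment (named list) for [simulate_network()].
#' @export
make_poisson_drive <- function(rate_hz, weight_mv, mask, start_s = 0,
                               duration_s) {
  if (rate_hz < 0) stop("Poisson rate must be non-negative")
  if (duration_s <= 0) stop("duration must be positive")
  list(type = "poisson", start_s = start_s, stop_s = start_s + duration_s,
       mask = as.integer(mask), rate_hz = rate_hz, weight_mv = weight_mv,
       dvm_mv = 0)
}

#' @rdname make_poisson_drive
#' @param delta_vm_mv Stationary membrane polarization of the DC drive (mV).
#' @param stop_s End time (s).
#' @export
make_dc_drive <- function(delta_vm_mv, mask, start_s, stop_s) {
  if (stop_s <= start_s) stop("stop must be after start")
  if (length(mask) == 0) {
    warning("DC drive with empty mask is a no-op segment")
  }
  list(type = "dc", start_s = start_s, stop_s = stop_s,
       mask = as.integer(mask), rate_hz = 0, weight_mv = 0,
       dvm_mv = delta_vm_mv)
}

#' Advance the network
#'
#' Low-level entry to the clock-driven engine: integrates the leaky
#' integrate-and-fire dynamics with delta-pulse synapses, per-neuron Poisson
#' background at `nu_ext_hz`, the given drive segments, and (optionally) the
#' homeostatic structural plasticity rule on E-E connections. Used by
#' [grow_network()] and [run_experiment()]; exposed for diagnostics and
#' custom protocols.
#'
#' @param net An `hsp_network` (its `state` carries membrane potentials,
#'   calcium traces, and element counts; time continues from `state$t0_s`).
#' @param cfg An `hsp_config`.
#' @param duration_s Simulated time to advance (s).
#' @param seed Seed for this call's background/stimulus/rewiring streams.
#' @param segments List of drive segments with absolute times
#'   (see [make_poisson_drive()]).
#' @param hsp Enable structural plasticity.
#' @param thresholds Disable to study subthreshold (free-membrane) dynamics.
#' @param record_spikes Keep the full spike record.
#' @param partition Optional integer vector of group labels (1-based) for
#'   all excitatory neurons; enables block-connectivity recording.
#' @param snapshot_s Absolute times at which to snapshot the E-E matrix.
#' @param diagnostics Record per-neuron input event counts.
#' @param record_rewire_events Keep the synapse formation/deletion log.
#' @return List with the updated `net`, rate-window counts, connectivity
#'   series, snapshots, and (optionally) spikes and diagnostics.
#' @export
simulate_network <- function(net, cfg, duration_s, seed = net$seed,
                             segments = list(), hsp = TRUE, thresholds = TRUE,
                             record_spikes = FALSE, partition = NULL,
                             snapshot_s = numeric(0), diagnostics = FALSE,
                             record_rewire_events = FALSE) {
  stopifnot(inherits(net, "hsp_network"))
  validate_config(cfg)
  opts <- list(duration_s = duration_s, hsp = hsp, thresholds = thresholds,
               record_spikes = record_spikes,
               record_window_s = cfg$window_s,
               gamma_stride_s = if (is.null(partition)) 0 else cfg$gamma_stride_s,
               part = if (is.null(partition)) integer(0) else as.integer(partition),
               snapshot_s = as.numeric(snapshot_s),
               seed = as.double(seed),
               diag_input_counts = diagnostics,
               record_rewire_events = record_rewire_events)
  res <- cpp_run(net_core(net), net$state, config_params(cfg), segments, opts)
  net$state <- res$state
  net$ee_pre <- res$ee_pre
  net$ee_post <- res$ee_post
  out <- list(net = net,
              win_counts = res$win_counts, win_t0 = res$win_t0,
              gamma_t = res$gamma_t, gamma_sums = res$gamma_sums,
              n_groups = res$n_groups,
              snapshots = lapply(res$snapshots, function(sn) {
                list(t = sn$t,
                     A = Matrix::sparseMatrix(i = sn$i, j = sn$j, x = sn$n,
                                              dims = c(net$n_E, net$n_E)))
              }))
  if (record_spikes) {
    out$spikes <- data.frame(id = res$spike_id, time_s = res$spike_t)
  }
  if (diagnostics) {
    out$bg_counts <- res$bg_counts
    out$seg_counts <- res$seg_counts
  }
  if (record_rewire_events) out$events <- as.data.frame(res$events)
  out
}

#' Grow the network to its structural equilibrium
#'
#' Runs the growth phase: starting from an empty E-E matrix, the network is
#' driven by background input only while the homeostatic structural
#' plasticity rule grows axonal boutons and dendritic spines toward the
#' firing-rate setpoint and pairs free elements into synapses. At the end of
#' the (profile-dependent) growth period the excitatory population fires
#' asynchronously and irregularly at the 8 Hz setpoint and the E-E
#' connection probability has settled near 9%.
#'
#' @param cfg An `hsp_config`.
#' @param seed Master seed.
#' @param record_spikes Keep the growth-phase spike record.
#' @return An `hsp_network` whose `meta` holds growth diagnostics:
#'   `rate_final_hz`, `gamma_final`, the rate/connectivity trajectories, and
#'   a `converged` flag (TRUE when the final rate is within 10% of the
#'   setpoint; a FALSE flag signals mis-calibrated growth parameters).
#' @export
grow_network <- function(cfg, seed = 1L, record_spikes = FALSE) {
  validate_config(cfg)
  net <- new_network(cfg, seed)
  if (cfg$growth_s <= 0) {
    net$meta <- list(rate_final_hz = 0, gamma_final = 0, converged = FALSE,
                     rate_hz = numeric(0), gamma = numeric(0),
                     time_s = numeric(0))
    return(net)
  }
  sim <- simulate_network(net, cfg, duration_s = cfg$growth_s, seed = seed,
                          partition = rep.int(1L, net$n_E),
                          record_spikes = record_spikes)
  net <- sim$net
  rate_e <- rowMeans(sim$win_counts[, seq_len(net$n_E), drop = FALSE]) /
    cfg$window_s
  gamma <- as.numeric(sim$gamma_sums[, 1]) / net$n_E^2
  k <- min(10L, length(rate_e))
  rate_final <- mean(rate_e[seq.int(length(rate_e) - k + 1L, length(rate_e))])
  converged <- abs(rate_final - cfg$target_rate_hz) <= 0.1 * cfg$target_rate_hz
  if (!converged) {
    warning(sprintf(
      "growth ended %.1f%% away from the %g Hz setpoint (rate %.2f Hz); %s",
      100 * abs(rate_final - cfg$target_rate_hz) / cfg$target_rate_hz,
      cfg$target_rate_hz, rate_final,
      "growth parameters may be mis-calibrated"))
  }
  net$meta <- list(rate_final_hz = rate_final,
                   gamma_final = gamma[length(gamma)],
                   converged = converged,
                   rate_hz = rate_e, time_s = sim$win_t0,
                   gamma = gamma, gamma_t = sim$gamma_t)
  if (record_spikes) net$meta$spikes <- sim$spikes
  net
}

#' @export
#' @method print hsp_network
print.hsp_network <- function(x, ...) {
  cat(sprintf("hsp_network: %d E + %d I neurons, %d E-E synapses, t = %g s\n",
              x$n_E, x$n_I, length(x$ee_pre), x$state$t0_s))
  if (!is.null(x$meta$rate_final_hz)) {
    cat(sprintf("  growth: final E rate %.2f Hz, E-E connectivity %.4f (%s)\n",
                x$meta$rate_final_hz, x$meta$gamma_final,
                if (isTRUE(x$meta$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}
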