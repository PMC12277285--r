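#' Population firing rate in fixed windows
#'
#' Mean firing rate of a neuron group, estimated from the spike count of
#' each member in contiguous recording windows (default 5 s) and averaged
#' over the group.
#'
#' @param spikes Data frame with columns `id`, `time_s` (a spike record).
#' @param group Integer vector of neuron ids (non-empty).
#' @param window_s Window length (s).
#' @param t_start,t_end Analysis interval; defaults to `[0, max spike time]`
#'   rounded up to a whole window.
#' @return Data frame with `window_start_s` and `rate_hz`.
#' @export
population_rate <- function(spikes, group, window_s = 5,
                            t_start = 0, t_end = NULL) {
  if (length(group) == 0) stop("group must be non-empty")
  stopifnot(window_s > 0)
  if (is.null(t_end)) {
    t_end <- if (nrow(spikes) == 0) t_start + window_s else
      t_start + window_s * ceiling((max(spikes$time_s) - t_start) / window_s)
  }
  edges <- seq(t_start, t_end, by = window_s)
  if (length(edges) < 2) stop("analysis interval shorter than one window")
  sub <- spikes[spikes$id %in% group &
                spikes$time_s > t_start & spikes$time_s <= t_end, ]
  # windows are (edge[k], edge[k+1]]: a spike stamped exactly on a window
  # edge belongs to the window it terminates
  idx <- findInterval(sub$time_s - 1e-12, edges)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(window_start_s = edges[-length(edges)],
             rate_hz = counts / (window_s * length(group)))
}

#' Block connectivity
#'
#' Normalized synapse count between an ordered pair of neuron groups:
#' `Gamma = sum(A[post, pre]) / (|pre| * |post|)`. For a single group of
#' size `n` used as both pre and post this is the within-group connectivity
#' `Gamma(t) = (1/n^2) * sum_ij A_ij`; the structurally zero diagonal is
#' included in the denominator, so the attainable maximum for a
#' multiplicity-1 block is `(n-1)/n`.
#'
#' @param A Synapse-count matrix (`A[i, j]` = synapses from `j` onto `i`).
#' @param pre,post Integer id vectors (presynaptic group `pre`, postsynaptic
#'   `post`); `post` defaults to `pre` (within-group connectivity).
#' @return The connectivity value (non-negative scalar).
#' @export
block_connectivity <- function(A, pre, post = pre) {
  if (length(pre) == 0 || length(post) == 0) stop("groups must be non-empty")
  n <- nrow(A)
  if (any(pre < 1 | pre > n) || any(post < 1 | post > n)) {
    stop("group ids outside matrix bounds")
  }
  sum(A[post, pre, drop = FALSE]) / (length(pre) * length(post))
}

#' Connectivity between all ordered pairs of partition groups
#'
#' Computes the block connectivity for every ordered (pre, post) pair of
#' disjoint groups; used for the engram/stimulated/background breakdown and
#' for the within-engram sub-block pattern that diagnoses engram distortion
#' under strong unfocused stimulation.
#'
#' @param A Synapse-count matrix.
#' @param partition Named list of disjoint id vectors; empty groups are
#'   omitted from the output.
#' @return Data frame with `pre_group`, `post_group`, `gamma`.
#' @export
engram_partition_metrics <- function(A, partition) {
  ids <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(ids)) stop("partition groups must be disjoint")
  partition <- partition[vapply(partition, length, integer(1)) > 0]
  if (length(partition) == 0) stop("partition has no non-empty group")
  grid <- expand.grid(pre_group = names(partition),
                      post_group = names(partition),
                      stringsAsFactors = FALSE)
  grid$gamma <- mapply(function(p, q) {
    block_connectivity(A, partition[[p]], partition[[q]])
  }, grid$pre_group, grid$post_group)
  grid
}
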