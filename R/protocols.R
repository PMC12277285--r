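#' Electrode montage
#'
#' Derives the set of DC-stimulated neurons from the montage kind:
#' \describe{
#'   \item{`uniform`}{All excitatory neurons are polarized (diffuse field).}
#'   \item{`targeted`}{Exactly the engram neurons are polarized (ideal focal
#'     stimulation).}
#'   \item{`unfocused`}{The stimulated set covers half of the engram plus an
#'     equal number of non-engram excitatory neurons (partial overlap); both
#'     halves are drawn uniformly at random.}
#'   \item{`none`}{No DC target (control runs).}
#' }
#'
#' @param kind Montage kind.
#' @param engram_ids Excitatory neuron ids forming the motor engram.
#' @param n_E Number of excitatory neurons.
#' @param seed Seed for the random halves of the unfocused montage.
#' @param overlap Fraction of the engram covered in the unfocused montage.
#' @return An `hsp_montage` list with `kind`, `engram_ids`, `dc_ids`.
#' @export
build_montage <- function(kind = c("uniform", "targeted", "unfocused", "none"),
                          engram_ids, n_E, seed = 1L, overlap = 0.5) {
  kind <- match.arg(kind)
  engram_ids <- as.integer(engram_ids)
  if (length(engram_ids) == 0 || any(engram_ids < 1 | engram_ids > n_E)) {
    stop("engram_ids must be non-empty excitatory ids within 1..n_E")
  }
  dc_ids <- switch(kind,
    uniform = seq_len(n_E),
    targeted = engram_ids,
    none = integer(0),
    unfocused = {
      k <- length(engram_ids) * overlap
      if (abs(k - round(k)) > 1e-9) {
        stop("unfocused montage needs overlap * engram size to be an integer")
      }
      k <- as.integer(round(k))
      non_engram <- setdiff(seq_len(n_E), engram_ids)
      if (length(non_engram) < k) stop("not enough non-engram neurons")
      set.seed(seed)
      c(sample(engram_ids, k), sample(non_engram, k))
    })
  structure(list(kind = kind, engram_ids = engram_ids,
                 dc_ids = as.integer(dc_ids)),
            class = "hsp_montage")
}

#' Experiment plan
#'
#' Fixes the protocol of one simulated experiment: phase durations, the
#' timing of DC stimulation relative to motor learning, and the DC
#' amplitude. Learning drives the engram with Poisson input (default
#' 1.5 kHz at 0.1 mV, a stationary mean depolarization of 1.50 mV); tDCS
#' polarizes its target population by `delta_vm_mv`.
#'
#' Timings (phases abut with zero gap, "immediately" before/after):
#' \describe{
#'   \item{`none`}{Learning only (control).}
#'   \item{`before`}{DC on `[growth, growth+dc_s)`, learning follows.}
#'   \item{`during`}{DC and learning both start at end of growth.}
#'   \item{`after`}{Learning first, DC follows.}
#' }
#' The simulation always continues to `relax_end_s` so the network returns
#' to its homeostatic equilibrium before the final readout.
#'
#' @param cfg An `hsp_config`.
#' @param timing One of `"none"`, `"before"`, `"during"`, `"after"`.
#' @param delta_vm_mv DC amplitude as stationary membrane polarization (mV);
#'   amplitudes beyond `cfg$dvm_max_mv` in magnitude are rejected unless
#'   `cfg$allow_strong` is set.
#' @param learn_on Set `FALSE` for DC-only runs (no learning input).
#' @param snapshot_s Absolute snapshot times; defaults to phase boundaries
#'   and the final readout time.
#' @param seed Seed attached to the plan (used by [run_experiment()]).
#' @return An `hsp_plan` list.
#' @export
experiment_plan <- function(cfg, timing = c("none", "before", "during", "after"),
                            delta_vm_mv = 0, learn_on = TRUE,
                            snapshot_s = NULL, seed = 1L) {
  timing <- match.arg(timing)
  validate_config(cfg)
  if (abs(delta_vm_mv) > cfg$dvm_max_mv + 1e-9 && !isTRUE(cfg$allow_strong)) {
    stop("|delta_vm| = ", abs(delta_vm_mv), " mV exceeds the weak-stimulation ",
         "range (dvm_max_mv = ", cfg$dvm_max_mv,
         "); set allow_strong = TRUE to use strong tDCS")
  }
  g <- cfg$growth_s
  windows <- switch(timing,
    none   = list(learn = c(g, g + cfg$learn_s), dc = NULL),
    before = list(dc = c(g, g + cfg$dc_s),
                  learn = c(g + cfg$dc_s, g + cfg$dc_s + cfg$learn_s)),
    during = list(learn = c(g, g + cfg$learn_s), dc = c(g, g + cfg$dc_s)),
    after  = list(learn = c(g, g + cfg$learn_s),
                  dc = c(g + cfg$learn_s, g + cfg$learn_s + cfg$dc_s)))
  if (!learn_on) {
    windows$learn <- NULL
    if (timing == "none") windows$dc <- NULL else windows$dc <- c(g, g + cfg$dc_s)
  }
  t_end <- max(cfg$relax_end_s, unlist(windows))
  if (is.null(snapshot_s)) {
    snapshot_s <- sort(unique(c(g, unlist(windows), t_end)))
  }
  if (any(snapshot_s < g)) stop("snapshots before the end of growth are invalid")
  structure(list(timing = timing, delta_vm_mv = delta_vm_mv,
                 learn_on = learn_on, growth_s = g,
                 learn_window = windows$learn, dc_window = windows$dc,
                 t_end_s = t_end, snapshot_s = snapshot_s,
                 learn_rate_hz = cfg$learn_rate_hz,
                 learn_j_mv = cfg$learn_j_mv, seed = as.integer(seed)),
            class = "hsp_plan")
}

#' Stimulation schedule
#'
#' Expands a plan and montage into drive segments for the engine.
#'
#' @param plan An `hsp_plan`.
#' @param montage An `hsp_montage`.
#' @return List of drive segments.
#' @export
build_schedule <- function(plan, montage) {
  stopifnot(inherits(plan, "hsp_plan"), inherits(montage, "hsp_montage"))
  segments <- list()
  if (!is.null(plan$learn_window)) {
    w <- plan$learn_window
    segments <- c(segments, list(make_poisson_drive(
      plan$learn_rate_hz, plan$learn_j_mv, montage$engram_ids,
      start_s = w[1], duration_s = w[2] - w[1])))
  }
  if (!is.null(plan$dc_window) && plan$delta_vm_mv != 0 &&
      length(montage$dc_ids) > 0) {
    w <- plan$dc_window
    segments <- c(segments, list(make_dc_drive(
      plan$delta_vm_mv, montage$dc_ids, start_s = w[1], stop_s = w[2])))
  }
  segments
}

#' Population partition induced by a montage
#'
#' Labels every excitatory neuron as `engram_overlap` (engram and
#' DC-stimulated), `engram_rest` (engram only), `dc_only` (DC-stimulated
#' only), or `background_E`; the fixed label order is used by the engine's
#' block-connectivity recording.
#'
#' @param montage An `hsp_montage`.
#' @param n_E Number of excitatory neurons.
#' @return List with integer `labels` (length `n_E`) and the `groups`
#'   id sets.
#' @export
montage_partition <- function(montage, n_E) {
  eng <- montage$engram_ids
  dc <- montage$dc_ids
  overlap <- intersect(eng, dc)
  rest <- setdiff(eng, dc)
  dc_only <- setdiff(dc, eng)
  bg <- setdiff(seq_len(n_E), union(eng, dc))
  labels <- integer(n_E)
  labels[overlap] <- 1L; labels[rest] <- 2L
  labels[dc_only] <- 3L; labels[bg] <- 4L
  list(labels = labels,
       groups = list(engram_overlap = overlap, engram_rest = rest,
                     dc_only = dc_only, background_E = bg))
}

partition_group_names <- c("engram_overlap", "engram_rest", "dc_only",
                           "background_E")

#' Run one experiment
#'
#' Executes the schedule on a grown network with structural plasticity
#' active throughout, recording population rates per window, block
#' connectivities on the montage partition, and connectivity snapshots at
#' the plan's snapshot times.
#'
#' @param net A grown `hsp_network` (see [grow_network()]); the run
#'   continues from the network's state and time.
#' @param cfg The `hsp_config` used to grow the network.
#' @param plan An `hsp_plan` whose `growth_s` matches the network time.
#' @param montage An `hsp_montage`.
#' @param seed Seed for this run's input and rewiring streams (defaults to
#'   the plan seed).
#' @param record_spikes Keep the full spike record.
#' @return An `hsp_result` with elements `rates` (long data frame:
#'   `window_start_s`, `group`, `rate_hz`), `gamma` (long data frame of
#'   ordered block connectivities over time), `gamma_engram` (engram
#'   readout time series), `snapshots`, `partition`, `net` (final state),
#'   and the plan/montage echo.
#' @export
run_experiment <- function(net, cfg, plan, montage, seed = plan$seed,
                           record_spikes = FALSE) {
  stopifnot(inherits(net, "hsp_network"), inherits(plan, "hsp_plan"))
  if (abs(net$state$t0_s - plan$growth_s) > 1e-9) {
    stop("plan growth_s (", plan$growth_s, ") does not match the network ",
         "time (", net$state$t0_s, "); pass the grown network this plan is for")
  }
  part <- montage_partition(montage, net$n_E)
  segments <- build_schedule(plan, montage)
  sim <- simulate_network(net, cfg,
                          duration_s = plan$t_end_s - plan$growth_s,
                          seed = seed, segments = segments, hsp = TRUE,
                          partition = part$labels,
                          snapshot_s = plan$snapshot_s,
                          record_spikes = record_spikes)
  out <- list(net = sim$net,
              rates = rates_long(sim, part, net$n_E, net$n_I, cfg$window_s),
              gamma = gamma_long(sim, part),
              snapshots = sim$snapshots,
              partition = part,
              plan = plan, montage = montage, seed = seed)
  out$gamma_engram <- group_union_gamma(sim, part,
                                        c("engram_overlap", "engram_rest"))
  if (record_spikes) out$spikes <- sim$spikes
  class(out) <- "hsp_result"
  out
}

# Long-format per-group mean rates from the engine's window counts.
rates_long <- function(sim, part, n_E, n_I, window_s) {
  counts <- sim$win_counts
  if (nrow(counts) == 0) {
    return(data.frame(window_start_s = numeric(0), group = character(0),
                      rate_hz = numeric(0)))
  }
  groups <- c(part$groups, list(I = n_E + seq_len(n_I)))
  res <- lapply(names(groups), function(gn) {
    ids <- groups[[gn]]
    if (length(ids) == 0) return(NULL)
    data.frame(window_start_s = sim$win_t0, group = gn,
               rate_hz = rowMeans(counts[, ids, drop = FALSE]) / window_s)
  })
  do.call(rbind, res)
}

# Long-format ordered block connectivities from the engine's block sums.
gamma_long <- function(sim, part) {
  sizes <- vapply(part$groups, length, integer(1))
  G <- sim$n_groups
  if (G == 0 || length(sim$gamma_t) == 0) {
    return(data.frame(time_s = numeric(0), pre_group = character(0),
                      post_group = character(0), gamma = numeric(0)))
  }
  res <- list()
  for (q in seq_len(G)) {        # post
    for (p in seq_len(G)) {      # pre
      if (sizes[p] == 0 || sizes[q] == 0) next  # empty groups omitted
      col <- (q - 1) * G + p     # engine layout: S[q][p] row-major
      res[[length(res) + 1L]] <- data.frame(
        time_s = sim$gamma_t,
        pre_group = partition_group_names[p],
        post_group = partition_group_names[q],
        gamma = sim$gamma_sums[, col] / (sizes[p] * sizes[q]))
    }
  }
  do.call(rbind, res)
}

# Within-group connectivity of a union of partition groups, over time.
group_union_gamma <- function(sim, part, group_names) {
  idx <- match(group_names, partition_group_names)
  sizes <- vapply(part$groups, length, integer(1))
  n_u <- sum(sizes[idx])
  if (n_u == 0) {
    return(data.frame(time_s = sim$gamma_t, gamma = rep(NA_real_,
                                                        length(sim$gamma_t))))
  }
  G <- sim$n_groups
  tot <- numeric(length(sim$gamma_t))
  for (q in idx) for (p in idx) {
    if (q <= G && p <= G) tot <- tot + sim$gamma_sums[, (q - 1) * G + p]
  }
  data.frame(time_s = sim$gamma_t, gamma = tot / n_u^2)
}

#' Final engram connectivity readout
#'
#' The scalar readout used throughout the protocol comparisons: the mean of
#' the last `k` recorded within-engram connectivity values (default 10
#' windows), suppressing fluctuation noise around the structural
#' equilibrium.
#'
#' @param result An `hsp_result`.
#' @param k Number of final recorded windows to average.
#' @param what Which time series: `"engram"` (default), or a
#'   `data.frame(time_s, gamma)` as produced by the result object.
#' @return A single connectivity value.
#' @export
final_gamma <- function(result, k = 10L, what = "engram") {
  ts <- if (is.data.frame(what)) what else result$gamma_engram
  v <- ts$gamma
  k <- min(k, length(v))
  mean(v[seq.int(length(v) - k + 1L, length(v))])
}

#' @export
#' @method print hsp_result
print.hsp_result <- function(x, ...) {
  cat(sprintf("hsp_result: montage '%s', timing '%s', dVm %+0.2f mV, seed %d\n",
              x$montage$kind, x$plan$timing, x$plan$delta_vm_mv, x$seed))
  cat(sprintf("  final engram connectivity: %.4f\n", final_gamma(x)))
  invisible(x)
}

#' Protocol sweep
#'
#' Runs the full experiment grid (montage x timing x DC amplitude x seed)
#' against per-seed grown networks and tabulates the final readouts. The
#' grown network for each seed is computed once and reused across grid
#' points.
#'
#' @param cfg An `hsp_config`.
#' @param grid Data frame with columns `montage`, `timing`, `delta_vm_mv`
#'   (for example from `expand.grid`). A column `learn_on` may be added for
#'   DC-only rows.
#' @param seeds Integer vector of master seeds.
#' @param grown Optional named list of pre-grown networks (names =
#'   seeds as character) to reuse.
#' @param verbose Print one line per run.
#' @return Data frame with one row per grid point per seed: `montage`,
#'   `timing`, `delta_vm_mv`, `seed`, `gamma_engram`, `gamma_overlap`,
#'   `gamma_nonoverlap`, `gamma_network`, `rate_engram_final_hz`.
#' @export
run_sweep <- function(cfg, grid, seeds = 1:3, grown = NULL, verbose = FALSE) {
  validate_config(cfg)
  sz <- config_sizes(cfg)
  if (is.null(grid$learn_on)) grid$learn_on <- TRUE
  rows <- list()
  for (seed in seeds) {
    key <- as.character(seed)
    net <- if (!is.null(grown[[key]])) grown[[key]] else grow_network(cfg, seed)
    engram_ids <- seq_len(sz$n_engram)
    for (r in seq_len(nrow(grid))) {
      montage <- build_montage(as.character(grid$montage[r]), engram_ids,
                               sz$n_E, seed = seed,
                               overlap = cfg$unfocused_overlap)
      plan <- experiment_plan(cfg, timing = as.character(grid$timing[r]),
                              delta_vm_mv = grid$delta_vm_mv[r],
                              learn_on = grid$learn_on[r], seed = seed)
      res <- run_experiment(net, cfg, plan, montage)
      gO <- group_union_gamma_result(res, "engram_overlap")
      gN <- group_union_gamma_result(res, "engram_rest")
      eng_rate <- subset_rates(res$rates, c("engram_overlap", "engram_rest"))
      rows[[length(rows) + 1L]] <- data.frame(
        montage = montage$kind, timing = plan$timing,
        delta_vm_mv = plan$delta_vm_mv, seed = seed,
        gamma_engram = final_gamma(res),
        gamma_overlap = gO, gamma_nonoverlap = gN,
        gamma_network = final_gamma(res, what = network_gamma(res)),
        rate_engram_final_hz = eng_rate)
      if (verbose) {
        message(sprintf("seed %d %s/%s dVm %+0.2f -> gamma_engram %.4f",
                        seed, montage$kind, plan$timing, plan$delta_vm_mv,
                        rows[[length(rows)]]$gamma_engram))
      }
    }
  }
  do.call(rbind, rows)
}

group_union_gamma_result <- function(res, groups) {
  sizes <- vapply(res$partition$groups, length, integer(1))
  if (sum(sizes[match(groups, partition_group_names)]) == 0) return(NA_real_)
  sub <- res$gamma[res$gamma$pre_group %in% groups &
                   res$gamma$post_group %in% groups, ]
  if (nrow(sub) == 0) return(NA_real_)
  # union gamma over possibly several blocks needs the raw sums; for a
  # single group this is just its within-block series
  if (length(groups) == 1) {
    ts <- sub[order(sub$time_s), c("time_s", "gamma")]
    return(final_gamma(NULL, what = ts))
  }
  stop("union readout across several groups requires gamma_engram")
}

network_gamma <- function(res) {
  sizes <- vapply(res$partition$groups, length, integer(1))
  G <- length(sizes)
  tms <- sort(unique(res$gamma$time_s))
  tot <- numeric(length(tms))
  for (p in seq_len(G)) for (q in seq_len(G)) {
    if (sizes[p] == 0 || sizes[q] == 0) next
    sub <- res$gamma[res$gamma$pre_group == partition_group_names[p] &
                     res$gamma$post_group == partition_group_names[q], ]
    tot <- tot + sub$gamma[order(sub$time_s)] * sizes[p] * sizes[q]
  }
  data.frame(time_s = tms, gamma = tot / sum(sizes)^2)
}

subset_rates <- function(rates, groups, k = 10L) {
  sub <- rates[rates$group %in% groups, ]
  if (nrow(sub) == 0) return(NA_real_)
  agg <- stats::aggregate(rate_hz ~ window_start_s, data = sub, FUN = mean)
  v <- agg$rate_hz[order(agg$window_start_s)]
  k <- min(k, length(v))
  mean(v[seq.int(length(v) - k + 1L, length(v))])
}
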