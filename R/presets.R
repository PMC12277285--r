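#' Experiment presets
#'
#' Returns the run grid reproducing each of the package's canonical
#' simulation sets at the configured scale:
#' \describe{
#'   \item{`fig1`}{Motor learning alone (engram formation control).}
#'   \item{`fig2`}{Targeted weak DC alone, both polarities (cell assembly
#'     formed by tDCS without learning).}
#'   \item{`fig3`}{Uniform tDCS before/during/after learning, both
#'     polarities and three intensities.}
#'   \item{`fig4`}{Targeted tDCS before/during/after learning, both
#'     polarities and three intensities.}
#'   \item{`fig5`}{Unfocused depolarizing tDCS before/after learning.}
#'   \item{`fig6`}{Unfocused tDCS, full timing x polarity x intensity grid.}
#'   \item{`fig7`}{Strong unfocused tDCS (+-2.8 mV) before/after learning.}
#'   \item{`fig8`}{The full summary sweep: three montages x three timings x
#'     the DC amplitude grid.}
#' }
#'
#' @param name Preset name (`"fig1"` .. `"fig8"`).
#' @param cfg Base configuration (defaults to the `test` profile, which is
#'   tuned for protocol studies); `fig7` presets enable `allow_strong`.
#' @return List with the (possibly adjusted) `cfg` and a `grid` data frame
#'   for [run_sweep()].
#' @export
preset <- function(name, cfg = default_config("test")) {
  valid <- paste0("fig", 1:8)
  if (!name %in% valid) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(valid, collapse = ", "))
  }
  dvms <- c(0.2, 0.4, 0.6)
  grid <- switch(name,
    fig1 = data.frame(montage = "none", timing = "none", delta_vm_mv = 0),
    fig2 = data.frame(montage = "targeted", timing = "during",
                      delta_vm_mv = c(0.4, -0.4), learn_on = FALSE),
    fig3 = expand.grid(montage = "uniform",
                       timing = c("before", "during", "after"),
                       delta_vm_mv = c(dvms, -dvms)),
    fig4 = expand.grid(montage = "targeted",
                       timing = c("before", "during", "after"),
                       delta_vm_mv = c(dvms, -dvms)),
    fig5 = data.frame(montage = "unfocused", timing = c("before", "after"),
                      delta_vm_mv = 0.4),
    fig6 = expand.grid(montage = "unfocused",
                       timing = c("before", "during", "after"),
                       delta_vm_mv = c(dvms, -dvms)),
    fig7 = expand.grid(montage = "unfocused", timing = c("before", "after"),
                       delta_vm_mv = c(-2.8, 2.8)),
    fig8 = expand.grid(montage = c("uniform", "targeted", "unfocused"),
                       timing = c("before", "during", "after"),
                       delta_vm_mv = c(-dvms, 0, dvms)))
  if (name == "fig7") cfg$allow_strong <- TRUE
  grid$montage <- as.character(grid$montage)
  grid$timing <- as.character(grid$timing)
  list(cfg = cfg, grid = grid)
}
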