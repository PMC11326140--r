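#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions of a thrombin-stimulation western-blot experiment:
#' 28 measured proteins on a nine-point grid over six hours, three biological
#' replicates, and a 29-compound kinase-inhibitor screen.
#'
#' @param n_proteins Number of proteins in the background interactome.
#' @param n_kinases Number of those proteins flagged as kinases
#'   (`2 <= n_kinases <= n_proteins`).
#' @param time_grid Sampling times in minutes; strictly increasing, starting
#'   at 0. Default [phospho_time_grid()].
#' @param n_replicates Biological replicates per condition (>= 2).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise on fold changes (>= 0). Default 0.1, a typical
#'   densitometry replicate CV.
#' @param n_compounds Number of kinase inhibitors in the simulated screens.
#' @param n_measured Number of proteins with time-course measurements (the
#'   planted cascade proteins plus unresponsive bystanders).
#' @param cascade_size Number of nodes (source included) in the planted
#'   signaling cascade.
#' @param activation_amplitude Plateau fold change of an activated cascade
#'   protein (> 1).
#' @param inhibition_amplitude Plateau fold change of an inhibited cascade
#'   protein (in (0, 1)).
#' @param frac_inhibitory Probability that a cascade edge carries a negative
#'   sign when the interactome provides no signed prior for it.
#' @param barrier_effect Fractional permeability AUC shift contributed by each
#'   barrier kinase that a compound inhibits by at least 50%.
#' @param assay_cv Replicate CV of the permeability AUC readout.
#' @param n_clusters Number of kinase clusters in the functional
#'   (TREKING-style) model fixture; default 36, the SOM neuron count used by
#'   that pipeline.
#' @param seed Integer seed making all generators deterministic.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 60,
                       n_kinases = 30,
                       time_grid = phospho_time_grid(),
                       n_replicates = 3,
                       noise_cv = 0.1,
                       n_compounds = 29,
                       n_measured = 28,
                       cascade_size = 12,
                       activation_amplitude = 2.5,
                       inhibition_amplitude = 0.4,
                       frac_inhibitory = 0.25,
                       barrier_effect = 0.05,
                       assay_cv = 0.03,
                       n_clusters = 36,
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_kinases = as.integer(n_kinases),
    time_grid = as.numeric(time_grid),
    n_replicates = as.integer(n_replicates),
    noise_cv = as.numeric(noise_cv),
    n_compounds = as.integer(n_compounds),
    n_measured = as.integer(n_measured),
    cascade_size = as.integer(cascade_size),
    activation_amplitude = as.numeric(activation_amplitude),
    inhibition_amplitude = as.numeric(inhibition_amplitude),
    frac_inhibitory = as.numeric(frac_inhibitory),
    barrier_effect = as.numeric(barrier_effect),
    assay_cv = as.numeric(assay_cv),
    n_clusters = as.integer(n_clusters),
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  tg <- cfg$time_grid
  if (length(tg) < 2 || tg[1] != 0 || any(diff(tg) <= 0)) {
    phosnet_stop("time_grid must be strictly increasing and start at 0",
                 "phosnet_config_error")
  }
  if (cfg$n_replicates < 2) {
    phosnet_stop("n_replicates must be >= 2", "phosnet_config_error")
  }
  if (cfg$noise_cv < 0) {
    phosnet_stop("noise_cv must be >= 0", "phosnet_config_error")
  }
  if (cfg$n_kinases < 2 || cfg$n_proteins < cfg$n_kinases) {
    phosnet_stop("need n_proteins >= n_kinases >= 2", "phosnet_config_error")
  }
  if (cfg$cascade_size < 2 || cfg$cascade_size > min(20L, cfg$n_proteins)) {
    phosnet_stop("cascade_size must be in [2, min(20, n_proteins)]",
                 "phosnet_config_error")
  }
  if (cfg$n_measured < 1 || cfg$n_measured > cfg$n_proteins - 1) {
    phosnet_stop("n_measured must be in [1, n_proteins - 1]",
                 "phosnet_config_error")
  }
  if (cfg$activation_amplitude <= 1 || cfg$inhibition_amplitude <= 0 ||
      cfg$inhibition_amplitude >= 1) {
    phosnet_stop(
      "activation_amplitude must be > 1 and inhibition_amplitude in (0, 1)",
      "phosnet_config_error"
    )
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d proteins (%d kinases), cascade of %d, %d measured\n",
              x$n_proteins, x$n_kinases, x$cascade_size, x$n_measured))
  cat(sprintf("  grid: %s min; %d replicates; noise CV %.2f\n",
              paste(x$time_grid, collapse = ","), x$n_replicates, x$noise_cv))
  cat(sprintf("  %d compounds; seed %d\n", x$n_compounds, x$seed))
  invisible(x)
}
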