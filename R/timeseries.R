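#' Replicate fold-change trajectories for one protein
#'
#' @param protein Protein id.
#' @param time_grid Sampling times in minutes.
#' @param values Numeric replicate-by-time matrix of fold changes. Values
#'   must be positive, the column at time 0 must equal 1 in every replicate
#'   (normalization to baseline), and at least two replicates are required.
#'
#' @return An object of class `phospho_timeseries`.
#' @export
phospho_timeseries <- function(protein, time_grid, values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) {
    phosnet_stop(sprintf("%s: need at least 2 replicates", protein),
                 "phosnet_data_error")
  }
  if (ncol(values) != length(time_grid)) {
    phosnet_stop(sprintf("%s: %d columns for %d time points", protein,
                         ncol(values), length(time_grid)),
                 "phosnet_data_error")
  }
  if (any(values <= 0)) {
    phosnet_stop(sprintf("%s: fold changes must be positive", protein),
                 "phosnet_data_error")
  }
  if (any(values[, 1] != 1)) {
    phosnet_stop(sprintf("%s: fold change at t = 0 must be exactly 1",
                         protein), "phosnet_data_error")
  }
  dimnames(values) <- list(NULL, paste0("t", time_grid))
  structure(list(protein = protein, time_grid = as.numeric(time_grid),
                 values = values),
            class = "phospho_timeseries")
}

#' @export
print.phospho_timeseries <- function(x, ...) {
  cat(sprintf("<phospho_timeseries> %s: %d replicates x %d time points\n",
              x$protein, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# lognormal multiplier with unit mean and the requested CV
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate replicate phosphorylation time series from a planted cascade
#'
#' Cascade proteins follow a sustained step profile: fold change 1 before
#' their activation time, then a plateau at `cfg$activation_amplitude`
#' (upward, when the cumulative sign of the source-to-protein path is
#' positive) or `cfg$inhibition_amplitude` (downward, negative cumulative
#' sign). Off-cascade proteins fluctuate around 1 with no drift. Replicates
#' carry multiplicative lognormal noise with unit mean and coefficient of
#' variation `cfg$noise_cv`; the value at time 0 is exactly 1 in every
#' replicate, as after normalization to baseline.
#'
#' The measured set comprises every cascade protein (source excluded) plus
#' unresponsive off-cascade bystanders up to `cfg$n_measured` (see
#' [measured_proteins()]): about half of the bystanders are kinases outside
#' the cascade (a realistic panel includes candidate kinases that turn out
#' unresponsive), the rest emulate effector and junction proteins monitored
#' alongside them.
#'
#' @param truth A `ground_truth` from [plant_cascade()].
#' @param net The [interactome()] the cascade was planted in.
#' @param cfg A [sim_config()].
#' @return A named list of [phospho_timeseries()] objects (class
#'   `phospho_dataset`).
#' @export
generate_timeseries <- function(truth, net, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  measured <- measured_proteins(truth, net, cfg)
  set.seed(cfg$seed + 2L)
  tg <- cfg$time_grid
  cascade <- setdiff(names(truth$activation_times), truth$source_node)

  out <- lapply(measured, function(p) {
    if (p %in% cascade) {
      amp <- if (truth$cum_sign[[p]] > 0) cfg$activation_amplitude
             else cfg$inhibition_amplitude
      mu <- ifelse(tg >= truth$activation_times[[p]], amp, 1)
    } else {
      mu <- rep(1, length(tg))
    }
    vals <- t(vapply(seq_len(cfg$n_replicates), function(r) {
      mu * lnorm_noise(length(tg), cfg$noise_cv)
    }, numeric(length(tg))))
    vals[, 1] <- 1  # baseline-normalized by definition
    phospho_timeseries(p, tg, vals)
  })
  names(out) <- measured
  structure(out, class = "phospho_dataset")
}

#' The measured protein panel of a synthetic study
#'
#' Deterministically selects the proteins with time-course measurements:
#' every cascade protein (source excluded), then off-cascade bystander
#' kinases (up to 8), then off-cascade non-kinase proteins, up to
#' `cfg$n_measured` in total. The same panel is used by the time-series
#' generator and by the assay generators, so inhibitor liabilities can
#' reference the measured panel.
#'
#' @param truth A `ground_truth`.
#' @param net The [interactome()].
#' @param cfg A [sim_config()].
#' @return Character vector of protein ids.
#' @export
measured_proteins <- function(truth, net, cfg) {
  set.seed(cfg$seed + 20L)
  cascade <- setdiff(names(truth$activation_times), truth$source_node)
  kin_pool <- setdiff(net$nodes$id[net$nodes$is_kinase], cascade)
  oth_pool <- setdiff(net$nodes$id[!net$nodes$is_kinase],
                      c(truth$source_node, cascade))
  n_extra <- max(0L, cfg$n_measured - length(cascade))
  n_bk <- min(8L, n_extra, length(kin_pool))
  bystander <- c(sample(kin_pool, n_bk),
                 sample(oth_pool, min(n_extra - n_bk, length(oth_pool))))
  c(cascade, bystander)
}

#' @export
print.phospho_dataset <- function(x, ...) {
  cat(sprintf("<phospho_dataset> %d proteins x %d time points x %d replicates\n",
              length(x), length(x[[1]]$time_grid), nrow(x[[1]]$values)))
  invisible(x)
}
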