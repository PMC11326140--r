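#' Validation configuration
#'
#' Thresholds and conventions for scoring a reconstructed network against
#' independent inhibitor and permeability data.
#'
#' @param inhibition_threshold Percent inhibition counting a kinase as
#'   inhibited (default 50).
#' @param network_fraction Fraction of network kinases entering the
#'   perturbation cutoff (default 0.25).
#' @param p_threshold t-test significance level (default 0.05).
#' @param auc_change_threshold Percent AUC change every replicate must
#'   exceed for the effect-size clause of [permeability_differs()]
#'   (default 10).
#' @param fold_change_threshold Percent fold change for the effect-size
#'   clause of [phospho_differs()] (default 20).
#' @param window Width in minutes of the time window centered on a query
#'   time in [treking_predict_active()] (default 10).
#' @param clamp_negative Clamp per-kinase inhibition below at 0 in
#'   [cumulative_inhibition()] (default FALSE: the literal sum, so residual
#'   activity above 100 contributes negatively).
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(inhibition_threshold = 50,
                              network_fraction = 0.25,
                              p_threshold = 0.05,
                              auc_change_threshold = 10,
                              fold_change_threshold = 20,
                              window = 10,
                              clamp_negative = FALSE) {
  if (inhibition_threshold <= 0 || p_threshold <= 0 ||
      auc_change_threshold <= 0 || fold_change_threshold <= 0 ||
      window <= 0 || network_fraction <= 0 || network_fraction > 1) {
    phosnet_stop("validation thresholds must be positive (fractions in (0, 1])",
                 "phosnet_config_error")
  }
  structure(
    list(inhibition_threshold = inhibition_threshold,
         network_fraction = network_fraction,
         p_threshold = p_threshold,
         auc_change_threshold = auc_change_threshold,
         fold_change_threshold = fold_change_threshold,
         window = window,
         clamp_negative = clamp_negative),
    class = "validation_config"
  )
}

#' Cumulative inhibition of a network by one compound
#'
#' Sums the percent inhibition (`100 - residual activity`) of a compound
#' over the network kinases present in the biochemical matrix; kinases
#' absent from the matrix are skipped. By default the literal sum is
#' reported (no clamping: residual activity above 100 contributes
#' negatively); `cfg$clamp_negative` clamps each term below at 0.
#'
#' @param network_kinases Character vector of kinases in the network.
#' @param matrix An `inhibition_matrix` (kinases x compounds, residual %).
#' @param compound Compound id (must be a column of `matrix`).
#' @param cfg A [validation_config()].
#' @return Cumulative inhibition in percentage points.
#' @export
cumulative_inhibition <- function(network_kinases, matrix, compound,
                                  cfg = validation_config()) {
  if (!compound %in% colnames(matrix)) {
    phosnet_stop(sprintf("compound '%s' absent from inhibition matrix",
                         compound), "phosnet_data_error")
  }
  present <- intersect(network_kinases, rownames(matrix))
  res <- matrix[present, compound]
  res <- res[!is.na(res)]
  inh <- 100 - res
  if (isTRUE(cfg$clamp_negative)) inh <- pmax(inh, 0)
  sum(inh)
}

#' Cumulative-inhibition cutoff for calling a network perturbed
#'
#' The cutoff equals `network_fraction * n * inhibition_threshold`
#' percentage points — under the defaults, the cumulative inhibition
#' reached when 25% of the network's kinases are inhibited by 50%. A
#' compound is predicted to perturb the network only when its cumulative
#' inhibition strictly exceeds the cutoff.
#'
#' @param n_network_kinases Number of kinases in the network (>= 1).
#' @param cfg A [validation_config()].
#' @return Cutoff in percentage points.
#' @export
perturbation_cutoff <- function(n_network_kinases, cfg = validation_config()) {
  if (n_network_kinases < 1) {
    phosnet_stop("need at least one network kinase", "phosnet_data_error")
  }
  cfg$network_fraction * n_network_kinases * cfg$inhibition_threshold
}

#' Does a compound change barrier permeability relative to DMSO?
#'
#' Dual detection rule: TRUE when a two-sample Student's t-test between the
#' compound and DMSO AUC replicates gives p below `cfg$p_threshold`, or when
#' every replicate's percent change relative to the mean DMSO AUC exceeds
#' `+auc_change_threshold` (all of them) or falls below
#' `-auc_change_threshold` (all of them); replicates changing in mixed
#' directions never satisfy the effect-size clause. With degenerate
#' variance the t-test is skipped (flagged by a warning) and only the
#' effect-size clause applies.
#'
#' @param compound_auc Numeric AUC replicates for the compound (>= 2).
#' @param dmso_auc Numeric AUC replicates for the DMSO control (>= 2).
#' @param cfg A [validation_config()].
#' @return TRUE or FALSE.
#' @export
permeability_differs <- function(compound_auc, dmso_auc,
                                 cfg = validation_config()) {
  if (length(compound_auc) < 2 || length(dmso_auc) < 2) {
    phosnet_stop("need at least two replicates per condition",
                 "phosnet_data_error")
  }
  p <- tryCatch(
    t.test(compound_auc, dmso_auc, var.equal = TRUE)$p.value,
    error = function(e) {
      warning("degenerate variance; falling back to the effect-size clause")
      NA_real_
    }
  )
  if (!is.na(p) && p < cfg$p_threshold) return(TRUE)
  change <- 100 * (compound_auc - mean(dmso_auc)) / mean(dmso_auc)
  all(change > cfg$auc_change_threshold) ||
    all(change < -cfg$auc_change_threshold)
}

#' Does a kinase's phosphorylation differ from the untreated baseline?
#'
#' Dual detection rule on replicate fold changes relative to non-treated
#' cells: TRUE when a t-test against the no-change value 1 gives p below
#' `cfg$p_threshold`, or when every replicate's fold change is at least
#' `1 + fold_change_threshold/100` (all increasing) or at most
#' `1 - fold_change_threshold/100` (all decreasing); both bounds inclusive.
#'
#' @param folds Numeric replicate fold changes at one time point.
#' @param cfg A [validation_config()].
#' @return TRUE or FALSE.
#' @export
phospho_differs <- function(folds, cfg = validation_config()) {
  if (length(folds) < 2) {
    phosnet_stop("need at least two replicates", "phosnet_data_error")
  }
  up <- 1 + cfg$fold_change_threshold / 100
  dn <- 1 - cfg$fold_change_threshold / 100
  if (all(folds >= up) || all(folds <= dn)) return(TRUE)
  if (sd(folds) == 0) {
    # degenerate-variance convention as in paired_ttest: p = 0 for a nonzero
    # shift with zero spread, p = 1 for no shift
    return(mean(folds) != 1)
  }
  t.test(folds, mu = 1)$p.value < cfg$p_threshold
}

#' Does a functional kinase model predict a kinase active at a time point?
#'
#' TRUE when any pathway activity interval associated with the kinase
#' intersects the closed window of `cfg$window` minutes centered at `t`
#' (default `[t - 5, t + 5]`). Kinases absent from the model yield FALSE
#' with a warning.
#'
#' @param model A [treking_model()].
#' @param kinase Kinase id.
#' @param t Query time in minutes (on the analysis grid).
#' @param cfg A [validation_config()].
#' @return TRUE or FALSE.
#' @export
treking_predict_active <- function(model, kinase, t,
                                   cfg = validation_config()) {
  stopifnot(inherits(model, "treking_model"))
  if (!kinase %in% names(model$intervals)) {
    warning(sprintf("kinase '%s' absent from the functional model", kinase))
    return(FALSE)
  }
  iv <- model$intervals[[kinase]]
  if (nrow(iv) == 0) return(FALSE)
  half <- cfg$window / 2
  any(iv[, "start"] <= t + half & iv[, "end"] >= t - half)
}

#' Agreement of positive predictions with measurements
#'
#' Accuracy is the precision over positive predictions — the fraction of
#' predicted-positive instances confirmed by measurement. Instances neither
#' predicted nor measured do not enter; an empty predicted set gives
#' undefined (NA) accuracy with counts still reported. The full confusion
#' count against the measured set is included for transparency.
#'
#' @param predicted_positive Character vector (or set) of predicted-positive
#'   instance ids.
#' @param measured_positive Character vector of measured-positive ids.
#' @return List with `n_predicted`, `n_agree`, `accuracy` (percent, one
#'   decimal) and `confusion` (true/false positives, missed positives).
#' @export
prediction_accuracy <- function(predicted_positive, measured_positive) {
  predicted_positive <- unique(predicted_positive)
  measured_positive <- unique(measured_positive)
  n_pred <- length(predicted_positive)
  n_agree <- length(intersect(predicted_positive, measured_positive))
  list(
    n_predicted = n_pred,
    n_agree = n_agree,
    accuracy = if (n_pred == 0) NA_real_ else round(100 * n_agree / n_pred, 1),
    confusion = c(
      true_positive = n_agree,
      false_positive = n_pred - n_agree,
      missed_positive = length(setdiff(measured_positive, predicted_positive))
    )
  )
}

#' Score a summary network against inhibitor and permeability screens
#'
#' The phosphoproteomics-arm validation: for every screened compound,
#' computes its cumulative inhibition over the network's kinases, predicts
#' a permeability perturbation when that exceeds the [perturbation_cutoff()]
#' of the network, calls the measured outcome with
#' [permeability_differs()], and reports the precision of the positive
#' predictions via [prediction_accuracy()].
#'
#' @param network_kinases Kinases of the reconstructed network.
#' @param matrix An `inhibition_matrix`.
#' @param screen A `permeability_screen`.
#' @param cfg A [validation_config()].
#' @return List with `per_compound` (data.frame: compound, cumulative
#'   inhibition, cutoff, predicted, measured) and the
#'   [prediction_accuracy()] fields.
#' @export
score_network_inhibition <- function(network_kinases, matrix, screen,
                                     cfg = validation_config()) {
  kin <- intersect(network_kinases, rownames(matrix))
  compounds <- colnames(matrix)
  dmso <- screen$auc$auc[screen$auc$compound == screen$control]
  cutoff <- if (length(kin) >= 1) perturbation_cutoff(length(kin), cfg) else NA
  rows <- lapply(compounds, function(cp) {
    ci <- cumulative_inhibition(network_kinases, matrix, cp, cfg)
    auc <- screen$auc$auc[screen$auc$compound == cp]
    data.frame(compound = cp, cumulative_inhibition = ci, cutoff = cutoff,
               predicted = !is.na(cutoff) && ci > cutoff,
               measured = permeability_differs(auc, dmso, cfg),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  acc <- prediction_accuracy(tab$compound[tab$predicted],
                             tab$compound[tab$measured])
  c(list(per_compound = tab, n_network_kinases = length(kin)), acc)
}

#' Score a functional kinase model against phosphorylation time courses
#'
#' The functional-arm validation: over every measured kinase and every
#' post-baseline time point, compares the model's activity prediction
#' ([treking_predict_active()]) with the measured phosphorylation call
#' ([phospho_differs()]), and reports the precision of the positive
#' predictions. Instances the model does not predict active are abstentions.
#'
#' @param model A [treking_model()].
#' @param dataset A `phospho_dataset` of measured kinases (non-kinase
#'   proteins are ignored unless listed in `model$kinases`).
#' @param cfg A [validation_config()].
#' @return List with `per_instance` (data.frame: kinase, time, predicted,
#'   measured) and the [prediction_accuracy()] fields.
#' @export
score_treking_model <- function(model, dataset, cfg = validation_config()) {
  stopifnot(inherits(model, "treking_model"))
  kin <- intersect(names(dataset), model$kinases)
  tg <- model$time_grid
  rows <- list()
  for (k in kin) {
    ts <- dataset[[k]]
    for (j in seq(2, length(tg))) {
      t <- tg[j]
      rows[[length(rows) + 1]] <- data.frame(
        kinase = k, time = t,
        predicted = treking_predict_active(model, k, t, cfg),
        measured = phospho_differs(ts$values[, j], cfg),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  key <- paste(tab$kinase, tab$time)
  acc <- prediction_accuracy(key[tab$predicted], key[tab$measured])
  c(list(per_instance = tab), acc)
}
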