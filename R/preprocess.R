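#' Normalize raw blot signals to loading control and baseline
#'
#' Densitometry normalization: background-corrected signals are divided by
#' the background-corrected loading-control signal at the same time point,
#' then by the resulting ratio at time 0, so the output is a fold change
#' from baseline with value exactly 1 at time 0:
#' `out[t] = ((raw[t] - bg) / (loading[t] - bg)) /
#'           ((raw[0] - bg) / (loading[0] - bg))`.
#'
#' @param raw Replicate-by-time matrix of raw band intensities for the
#'   protein of interest.
#' @param loading Replicate-by-time matrix of loading-control intensities on
#'   the same grid.
#' @param time_grid Sampling times in minutes.
#' @param protein Protein id for the output object.
#' @param background Per-band background, either a scalar or a matrix shaped
#'   like `raw`; already-corrected signals use the default 0.
#' @return A [phospho_timeseries()].
#' @export
normalize_blots <- function(raw, loading, time_grid, protein = "protein",
                            background = 0) {
  raw <- as.matrix(raw); loading <- as.matrix(loading)
  if (!all(dim(raw) == dim(loading))) {
    phosnet_stop("raw and loading-control series must share replicate and time structure",
                 "phosnet_data_error")
  }
  r <- raw - background
  l <- loading - background
  bad <- which(r <= 0 | l <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    phosnet_stop(
      sprintf("%s: non-positive background-corrected signal at replicate %d, time %s min",
              protein, bad[1, 1], time_grid[bad[1, 2]]),
      "phosnet_data_error"
    )
  }
  ratio <- r / l
  fold <- ratio / ratio[, 1]
  phospho_timeseries(protein, time_grid, fold)
}

#' Paired Student's t-test p-value
#'
#' Two-sided paired t-test on the replicate differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and the
#' sample (n-1) standard deviation. Degenerate inputs follow fixed
#' conventions: all differences zero gives p = 1, zero spread around a
#' nonzero mean gives p = 0; both are flagged via the `"flag"` attribute
#' (`"zero_diff"` / `"zero_sd"`).
#'
#' @param x,y Equal-length replicate vectors, `n >= 2`.
#' @return The two-sided p-value, with attributes `statistic` (the t value,
#'   NA in degenerate cases) and, when degenerate, `flag`.
#' @export
paired_ttest <- function(x, y) {
  n <- length(x)
  if (n < 2 || length(y) != n) {
    phosnet_stop("paired_ttest needs two replicate vectors of equal length >= 2",
                 "phosnet_data_error")
  }
  d <- x - y
  if (all(d == 0)) {
    return(structure(1, statistic = NA_real_, flag = "zero_diff"))
  }
  s <- sd(d)
  if (s == 0) {
    return(structure(0, statistic = NA_real_, flag = "zero_sd"))
  }
  tstat <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  structure(p, statistic = tstat)
}

#' Per-time-point significance scores for a phosphorylation profile
#'
#' For each time point after baseline, computes two paired t-test p-values:
#' `firstscores[k]`, comparing replicate fold changes at time k against time
#' 0, and `prevscores[k]`, comparing against the preceding time point. A
#' measurement is called significant when the score is at or below the
#' threshold (default 0.05).
#'
#' @param ts A [phospho_timeseries()].
#' @param threshold Significance threshold on the p-values.
#' @return An object of class `significance_scores` with fields `protein`,
#'   `firstscores`, `prevscores` (each of length `T - 1`) and `threshold`.
#' @export
compute_significance <- function(ts, threshold = 0.05) {
  stopifnot(inherits(ts, "phospho_timeseries"))
  v <- ts$values
  k <- seq(2, ncol(v))
  firstscores <- vapply(k, function(j) as.numeric(paired_ttest(v[, j], v[, 1])),
                        numeric(1))
  prevscores <- vapply(k, function(j) as.numeric(paired_ttest(v[, j], v[, j - 1])),
                       numeric(1))
  names(firstscores) <- names(prevscores) <- colnames(v)[k]
  structure(
    list(protein = ts$protein, firstscores = firstscores,
         prevscores = prevscores, threshold = threshold,
         time_grid = ts$time_grid),
    class = "significance_scores"
  )
}

#' Discretize a phosphorylation profile into temporal activity states
#'
#' Assigns each time point one of three states. Time 0 is always
#' `"inactive"`. A later time point is `"activated"` when either score
#' (against baseline or against the previous point) is at or below the
#' threshold and the mean fold change exceeds the reference point's mean
#' (the reference of whichever test fired; baseline takes precedence when
#' both fire), `"inhibited"` when significant and lower, and `"inactive"`
#' otherwise.
#'
#' @param ts A [phospho_timeseries()].
#' @param scores Matching [compute_significance()] output.
#' @return An object of class `activity_profile` with fields `protein`,
#'   `time_grid` and `states`.
#' @export
discretize_activity <- function(ts, scores) {
  stopifnot(inherits(ts, "phospho_timeseries"),
            inherits(scores, "significance_scores"))
  v <- ts$values
  m <- colMeans(v)
  thr <- scores$threshold
  states <- character(ncol(v))
  states[1] <- "inactive"
  for (j in seq(2, ncol(v))) {
    pf <- scores$firstscores[j - 1]
    pp <- scores$prevscores[j - 1]
    if (min(pf, pp) > thr) {
      states[j] <- "inactive"
      next
    }
    ref <- if (pf <= thr) 1L else j - 1L
    states[j] <- if (m[j] > m[ref]) "activated"
                 else if (m[j] < m[ref]) "inhibited"
                 else "inactive"
  }
  structure(list(protein = ts$protein, time_grid = ts$time_grid,
                 states = stats::setNames(states, colnames(v))),
            class = "activity_profile")
}

#' Derive protein prizes from significance scores
#'
#' The prize of a measured protein is `-log10` of its smallest p-value over
#' all time points and both score types, floored at 0 and capped at `cap`
#' (reached when some p-value is exactly 0). Proteins without measurements
#' implicitly have prize 0; evidence can only raise a prize, never lower it.
#'
#' @param scores A single [compute_significance()] result or a list of them.
#' @param cap Prize assigned when the minimum p-value is 0 (default 10).
#' @return Named numeric vector of prizes (>= 0), one per scored protein.
#' @export
compute_prizes <- function(scores, cap = 10) {
  if (inherits(scores, "significance_scores")) scores <- list(scores)
  out <- vapply(scores, function(s) {
    p <- min(c(s$firstscores, s$prevscores))
    if (p <= 0) return(cap)
    min(cap, max(0, -log10(p)))
  }, numeric(1))
  names(out) <- vapply(scores, `[[`, "", "protein")
  out
}

#' Compute significance scores, activity profiles and prizes for a dataset
#'
#' Convenience wrapper applying [compute_significance()],
#' [discretize_activity()] and [compute_prizes()] to every protein of a
#' `phospho_dataset`.
#'
#' @param dataset A named list of [phospho_timeseries()] objects.
#' @param threshold Significance threshold.
#' @param prize_cap Cap passed to [compute_prizes()].
#' @return List with `scores`, `profiles` (named lists) and `prizes` (named
#'   numeric).
#' @export
preprocess_dataset <- function(dataset, threshold = 0.05, prize_cap = 10) {
  scores <- lapply(dataset, compute_significance, threshold = threshold)
  profiles <- Map(discretize_activity, dataset, scores)
  list(scores = scores, profiles = profiles,
       prizes = compute_prizes(scores, cap = prize_cap))
}

#' First-change summary of activity profiles
#'
#' For each profile, the earliest time with a non-inactive state and the
#' direction of that first change (+1 activated, -1 inhibited). Proteins
#' that never change get time `Inf` and direction 0.
#'
#' @param profiles Named list of [discretize_activity()] results.
#' @return data.frame with columns `protein`, `first_change`, `direction`.
#' @export
first_changes <- function(profiles) {
  out <- lapply(profiles, function(pr) {
    idx <- which(pr$states != "inactive")
    if (length(idx) == 0) {
      data.frame(protein = pr$protein, first_change = Inf, direction = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein = pr$protein,
                 first_change = pr$time_grid[idx[1]],
                 direction = if (pr$states[idx[1]] == "activated") 1L else -1L,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
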