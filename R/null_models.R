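#' Shuffle node labels of a network
#'
#' Applies a uniformly random permutation to the node labels of a network,
#' leaving the edge structure (edge count, degree sequence, connectivity
#' pattern) exactly unchanged. Works on a [subnetwork()], a
#' [partial_model()], or a plain edge data.frame.
#'
#' @param net The network to relabel.
#' @param seed Integer seed.
#' @param perm Optional explicit permutation (named character vector mapping
#'   old to new labels); overrides `seed`.
#' @return An object of the same class with permuted labels.
#' @export
shuffle_network_nodes <- function(net, seed = 1L, perm = NULL) {
  edges <- if (is.data.frame(net)) net else net$edges
  if (nrow(edges) == 0) {
    phosnet_stop("cannot shuffle an empty network", "phosnet_data_error")
  }
  cols <- intersect(c("from", "to", "kinase", "substrate"), names(edges))
  ids <- sort(unique(unlist(edges[cols], use.names = FALSE)))
  if (!is.data.frame(net) && !is.null(net$source)) {
    ids <- sort(unique(c(ids, net$source)))
  }
  if (is.null(perm)) {
    set.seed(seed)
    perm <- stats::setNames(sample(ids), ids)
  }
  for (cl in cols) edges[[cl]] <- unname(perm[edges[[cl]]])
  if (is.data.frame(net)) {
    rownames(edges) <- NULL
    return(edges)
  }
  out <- net
  out$edges <- edges
  out
}

#' Shuffle the values of a phosphorylation dataset and its scores
#'
#' The data-randomization null: all fold-change values are permuted
#' uniformly across the whole dataset (every protein, time point and
#' replicate), preserving the multiset of values and all shapes; the
#' first-point and previous-point significance scores are each permuted the
#' same way, independently of the data. Per-protein shuffling (preserving
#' each protein's value pool) is available via `granularity`.
#'
#' @param dataset A `phospho_dataset`.
#' @param scores Named list of [compute_significance()] results matching the
#'   dataset.
#' @param seed Integer seed.
#' @param granularity `"global"` (default) or `"per_protein"`.
#' @return List with `dataset` and `scores`, shuffled. The shuffled time
#'   series no longer satisfy the baseline-equals-1 invariant; they are
#'   null-model inputs, not measurements.
#' @export
shuffle_timeseries <- function(dataset, scores, seed = 1L,
                               granularity = c("global", "per_protein")) {
  granularity <- match.arg(granularity)
  set.seed(seed)
  prots <- names(dataset)
  if (granularity == "global") {
    pool <- unlist(lapply(dataset, function(ts) as.vector(ts$values)))
    pool <- sample(pool)
    k <- 0L
    for (p in prots) {
      v <- dataset[[p]]$values
      dataset[[p]]$values <- matrix(pool[k + seq_len(length(v))], nrow(v),
                                    ncol(v), dimnames = dimnames(v))
      k <- k + length(v)
    }
    for (fld in c("firstscores", "prevscores")) {
      sc <- unlist(lapply(scores, `[[`, fld))
      sc <- sample(sc)
      k <- 0L
      for (p in prots) {
        n <- length(scores[[p]][[fld]])
        scores[[p]][[fld]][] <- sc[k + seq_len(n)]
        k <- k + n
      }
    }
  } else {
    for (p in prots) {
      v <- dataset[[p]]$values
      dataset[[p]]$values[] <- sample(as.vector(v))
      scores[[p]]$firstscores[] <- sample(scores[[p]]$firstscores)
      scores[[p]]$prevscores[] <- sample(scores[[p]]$prevscores)
    }
  }
  list(dataset = dataset, scores = scores)
}

#' Degree-preserving directed configuration-model randomization
#'
#' Draws a random directed multigraph with exactly the in- and out-degree
#' sequence of the input network (the configuration model), then by default
#' collapses it to a simple graph by removing self-loops and duplicate
#' edges (which perturbs degrees slightly; the pre-collapse multigraph is
#' kept in the `"multigraph"` attribute).
#'
#' @param edges Directed edge data.frame (`from`, `to`).
#' @param seed Integer seed.
#' @param collapse Remove self-loops and multi-edges (default TRUE).
#' @return Edge data.frame of the randomized network, with attribute
#'   `multigraph` (the pre-collapse edge data.frame).
#' @export
configuration_model_network <- function(edges, seed = 1L, collapse = TRUE) {
  if (nrow(edges) == 0) {
    phosnet_stop("cannot randomize an empty network", "phosnet_data_error")
  }
  ids <- sort(unique(c(edges$from, edges$to)))
  outd <- table(factor(edges$from, levels = ids))
  ind <- table(factor(edges$to, levels = ids))
  set.seed(seed)
  g <- igraph::sample_degseq(out.deg = as.integer(outd),
                             in.deg = as.integer(ind),
                             method = "configuration")
  igraph::V(g)$name <- ids
  multi <- igraph::as_data_frame(g, what = "edges")
  multi <- data.frame(from = multi$from, to = multi$to,
                      stringsAsFactors = FALSE)
  out <- multi
  if (collapse) {
    out <- out[out$from != out$to, , drop = FALSE]
    out <- out[!duplicated(paste(out$from, out$to)), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "multigraph") <- multi
  out
}

#' Null-model configuration for the functional-model randomization
#'
#' @param n_kir_kinases Size of the kinase pool functionality labels are
#'   sampled from (default 300, the size of a typical kinase-regression
#'   panel).
#' @param n_clusters Number of clusters selected kinases are assigned to
#'   (default 36).
#' @return An object of class `treking_null_config`.
#' @export
treking_null_config <- function(n_kir_kinases = 300L, n_clusters = 36L) {
  if (n_clusters < 1 || n_kir_kinases < 1) {
    phosnet_stop("null-model counts must be positive", "phosnet_config_error")
  }
  structure(list(n_kir_kinases = as.integer(n_kir_kinases),
                 n_clusters = as.integer(n_clusters)),
            class = "treking_null_config")
}

#' Randomized functional kinase model
#'
#' Builds one null realization of a functional kinase model: the background
#' network is replaced by a configuration-model randomization with shuffled
#' node labels; at each time point, weakening and strengthening kinases are
#' sampled from the kinase pool with the same per-time probabilities as in
#' the true model; every kinase selected at any time is assigned uniformly
#' to one of `cfg$n_clusters` clusters; and per cluster a network is built
#' from all shortest paths between same-cluster selected kinases in the
#' randomized background (unreachable pairs are skipped and counted).
#'
#' @param cfg A [treking_null_config()].
#' @param true_model The fitted [treking_model()] providing per-time
#'   selection probabilities, the kinase pool and the time grid.
#' @param background Directed edge data.frame of the background network
#'   (default: the true model's).
#' @param seed Integer seed.
#' @return A [treking_model()].
#' @export
random_treking_model <- function(cfg, true_model,
                                 background = true_model$background,
                                 seed = 1L) {
  stopifnot(inherits(cfg, "treking_null_config"),
            inherits(true_model, "treking_model"))
  rb <- configuration_model_network(background, seed = seed)
  rb <- shuffle_network_nodes(rb, seed = seed + 1L)
  set.seed(seed + 2L)

  pool <- true_model$kinases
  n_pool <- min(cfg$n_kir_kinases, length(pool))
  tg <- true_model$time_grid
  func <- matrix("none", length(pool), length(tg),
                 dimnames = list(pool, paste0("t", tg)))
  intervals <- stats::setNames(
    rep(list(matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("start", "end")))), length(pool)),
    pool
  )
  for (j in seq_along(tg)) {
    truth_col <- true_model$functionality[, j]
    p_weak <- sum(truth_col %in% c("weakening", "both")) / n_pool
    p_strong <- sum(truth_col %in% c("strengthening", "both")) / n_pool
    weak <- runif(length(pool)) < p_weak
    strong <- runif(length(pool)) < p_strong
    func[weak & !strong, j] <- "weakening"
    func[strong & !weak, j] <- "strengthening"
    func[weak & strong, j] <- "both"
    for (k in pool[weak | strong]) {
      intervals[[k]] <- rbind(intervals[[k]], c(tg[j], tg[j]))
    }
  }
  selected <- pool[apply(func != "none", 1, any)]
  clusters <- stats::setNames(
    sample(seq_len(cfg$n_clusters), length(pool), replace = TRUE), pool
  )
  cluster_networks <- cluster_path_networks(selected, clusters, rb)
  treking_model(pool, tg, func, intervals, clusters, rb, cluster_networks,
                cfg$n_clusters)
}

new_null_ensemble <- function(arm, accuracies, seeds) {
  structure(list(arm = arm, accuracies = accuracies, seeds = seeds,
                 n_iterations = length(accuracies)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  ok <- x$accuracies[!is.na(x$accuracies)]
  cat(sprintf("<null_ensemble> arm %s, %d iterations (%d defined)\n",
              x$arm, x$n_iterations, length(ok)))
  if (length(ok) > 0) {
    cat(sprintf("  accuracy: mean %.1f, p95 %.1f\n", mean(ok),
                quantile(ok, 0.95)))
  }
  invisible(x)
}

#' Randomization null ensemble for the phosphoproteomics arm
#'
#' Per iteration: shuffles the node labels of the subnetwork and of the
#' partial model, shuffles the time-series values and significance scores,
#' re-runs the temporal synthesis with the original source node designation,
#' and scores the resulting summary network against the inhibitor and
#' permeability screens. Iterations whose networks make no positive
#' prediction yield NA accuracy (recorded, never dropped).
#'
#' @param sub A [subnetwork()].
#' @param pm A [partial_model()].
#' @param dataset,scores The measured `phospho_dataset` and its
#'   significance scores.
#' @param kinases Character vector of kinase ids (for scoring the
#'   synthesized network).
#' @param matrix An `inhibition_matrix`.
#' @param screen A `permeability_screen`.
#' @param n Number of iterations (default 100).
#' @param base_seed Integer; iteration i uses seeds derived from
#'   `base_seed + i`.
#' @param vcfg A [validation_config()].
#' @param max_path_len Passed to [synthesize()].
#' @return A `null_ensemble` (accuracies in percent).
#' @export
random_tps_ensemble <- function(sub, pm, dataset, scores, kinases, matrix,
                                screen, n = 100L, base_seed = 1L,
                                vcfg = validation_config(),
                                max_path_len = 8) {
  seeds <- base_seed + 7L * seq_len(n)
  acc <- vapply(seeds, function(s) {
    res <- tryCatch({
      sub_r <- shuffle_network_nodes(sub, seed = s)
      pm_r <- shuffle_network_nodes(pm, seed = s + 1L)
      shf <- shuffle_timeseries(dataset, scores, seed = s + 2L)
      profiles <- Map(discretize_activity, shf$dataset, shf$scores)
      syn <- synthesize(sub_r, pm_r, profiles, source = sub$source,
                        max_path_len = max_path_len)
      net_kin <- intersect(unique(c(syn$summary$from, syn$summary$to)),
                           kinases)
      if (length(net_kin) == 0) return(NA_real_)
      score_network_inhibition(net_kin, matrix, screen, vcfg)$accuracy
    }, error = function(e) NA_real_)
    if (is.null(res)) NA_real_ else res
  }, numeric(1))
  new_null_ensemble("tps", acc, seeds)
}

#' Randomization null ensemble for the functional arm
#'
#' Per iteration: builds a [random_treking_model()] and scores its
#' time-resolved activity predictions against the measured phosphorylation
#' dataset with [score_treking_model()].
#'
#' @param cfg A [treking_null_config()].
#' @param true_model The fitted [treking_model()].
#' @param dataset The measured `phospho_dataset`.
#' @param n Number of iterations (default 100).
#' @param base_seed Integer base seed.
#' @param vcfg A [validation_config()].
#' @return A `null_ensemble` (accuracies in percent).
#' @export
random_treking_ensemble <- function(cfg, true_model, dataset, n = 100L,
                                    base_seed = 1L,
                                    vcfg = validation_config()) {
  seeds <- base_seed + 13L * seq_len(n)
  acc <- vapply(seeds, function(s) {
    tryCatch({
      m <- random_treking_model(cfg, true_model, seed = s)
      score_treking_model(m, dataset, vcfg)$accuracy
    }, error = function(e) NA_real_)
  }, numeric(1))
  new_null_ensemble("treking", acc, seeds)
}

#' Summarize a null ensemble against the true model's accuracy
#'
#' @param ensemble A `null_ensemble`.
#' @param true_accuracy Accuracy (percent) of the true model under the same
#'   scoring.
#' @return List with mean, sd, percentiles (50/95/99), `n_defined`,
#'   `true_accuracy` and the empirical p-value (fraction of defined null
#'   accuracies at or above the true one).
#' @export
summarize_null <- function(ensemble, true_accuracy) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  ok <- ensemble$accuracies[!is.na(ensemble$accuracies)]
  qs <- if (length(ok) > 0) quantile(ok, c(0.5, 0.95, 0.99)) else
    rep(NA_real_, 3)
  list(
    arm = ensemble$arm,
    n_iterations = ensemble$n_iterations,
    n_defined = length(ok),
    mean = if (length(ok) > 0) mean(ok) else NA_real_,
    sd = if (length(ok) > 1) sd(ok) else NA_real_,
    p50 = unname(qs[1]), p95 = unname(qs[2]), p99 = unname(qs[3]),
    true_accuracy = true_accuracy,
    empirical_p = if (length(ok) > 0) mean(ok >= true_accuracy) else NA_real_
  )
}
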