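#' Generate a synthetic kinase-by-compound residual-activity matrix
#'
#' Emulates an in vitro kinase-inhibitor profiling panel. Residual activity
#' is the percent of catalytic activity remaining in the presence of a
#' compound (100 = untouched, 0 = fully inhibited). Compounds fall into
#' three classes, cycled in order: *barrier-targeted* compounds strongly
#' inhibit most barrier (cascade) kinases; *off-target* compounds strongly
#' inhibit a random subset of kinases outside the measured panel and,
#' reflecting typical inhibitor polypharmacology, also carry sub-threshold
#' liabilities (always below 50% inhibition, so they never engage the
#' barrier machinery): two moderate (38.5-40%) and one mild (14-15%) hits
#' on barrier kinases, plus occasional mild hits (26-28%, probability 0.15)
#' on the measured bystander kinases; *inactive* compounds inhibit nothing
#' substantially. With 29 compounds this yields 10 barrier-targeted, 10
#' off-target and 9 inactive compounds, mirroring the shape of a typical
#' small kinase-inhibitor screen.
#'
#' @param truth A `ground_truth` from [plant_cascade()].
#' @param net The [interactome()] providing the kinase universe.
#' @param cfg A [sim_config()].
#' @return A numeric kinase-by-compound matrix of residual activities in
#'   \[0, 100\], class `inhibition_matrix`, with attribute `compound_class`.
#' @export
generate_inhibition_matrix <- function(truth, net, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  measured <- measured_proteins(truth, net, cfg)
  set.seed(cfg$seed + 3L)
  kinases <- net$nodes$id[net$nodes$is_kinase]
  barrier <- truth$barrier_kinases
  bystander_kin <- setdiff(intersect(measured, kinases), barrier)
  free_kin <- setdiff(kinases, c(barrier, bystander_kin))
  compounds <- sprintf("C%02d", seq_len(cfg$n_compounds))
  cls <- rep(c("barrier", "offtarget", "inactive"),
             length.out = cfg$n_compounds)

  mat <- matrix(NA_real_, length(kinases), cfg$n_compounds,
                dimnames = list(kinases, compounds))
  for (j in seq_along(compounds)) {
    res <- stats::setNames(round(runif(length(kinases), 99.5, 100), 1),
                           kinases)
    if (cls[j] == "barrier") {
      hit <- barrier[runif(length(barrier)) < 0.75]
      res[hit] <- round(runif(length(hit), 5, 30), 1)
    } else if (cls[j] == "offtarget") {
      hit <- free_kin[runif(length(free_kin)) < 0.4]
      res[hit] <- round(runif(length(hit), 5, 30), 1)
      bhit <- bystander_kin[runif(length(bystander_kin)) < 0.5]
      res[bhit] <- round(runif(length(bhit), 72, 74), 1)  # 26-28% inhibition
      # sub-threshold barrier liabilities: never at or past 50% inhibition
      if (length(barrier) >= 3) {
        sub <- sample(barrier, 3L)
        res[sub[1:2]] <- round(runif(2, 60.5, 61.5), 1)  # 38.5-39.5% inhibition
        res[sub[3]] <- round(runif(1, 85, 86), 1)        # 14-15% inhibition
      }
    } else {
      res[] <- round(runif(length(kinases), 90, 100), 1)
    }
    mat[, j] <- res
  }
  structure(mat, class = c("inhibition_matrix", class(mat)),
            compound_class = stats::setNames(cls, compounds))
}

#' Generate a synthetic barrier-permeability screen
#'
#' Emulates a six-hour barrier permeability assay (normalized area under the
#' permeability curve, AUC) run for every compound and a DMSO vehicle
#' control. Each barrier kinase that a compound inhibits by at least 50%
#' (residual activity at or below 50) shifts the compound's expected AUC by
#' the fraction `cfg$barrier_effect`, mirroring cumulative-inhibition logic:
#' hitting more of the barrier machinery perturbs the phenotype more.
#' Replicates carry multiplicative lognormal noise with CV `cfg$assay_cv`.
#'
#' @param truth A `ground_truth`; its `barrier_kinases` couple inhibition to
#'   the phenotype. If empty, a warning is raised and the screen is
#'   unperturbed.
#' @param matrix An `inhibition_matrix` from [generate_inhibition_matrix()].
#' @param cfg A [sim_config()].
#' @return An object of class `permeability_screen`: a list with `auc`
#'   (data.frame `compound`, `replicate`, `auc`; the vehicle control rows
#'   have compound `"DMSO"`) and `control` (`"DMSO"`).
#' @export
generate_permeability_screen <- function(truth, matrix, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  barrier <- intersect(truth$barrier_kinases, rownames(matrix))
  if (length(truth$barrier_kinases) == 0) {
    warning("ground truth has no barrier kinases; screen is unperturbed")
  }
  compounds <- colnames(matrix)
  rows <- lapply(c("DMSO", compounds), function(cp) {
    shift <- 0
    if (cp != "DMSO" && length(barrier) > 0) {
      n_hit <- sum(matrix[barrier, cp] <= 50, na.rm = TRUE)
      shift <- cfg$barrier_effect * n_hit
    }
    data.frame(compound = cp, replicate = seq_len(cfg$n_replicates),
               auc = (1 + shift) * lnorm_noise(cfg$n_replicates, cfg$assay_cv),
               stringsAsFactors = FALSE)
  })
  structure(list(auc = do.call(rbind, rows), control = "DMSO"),
            class = "permeability_screen")
}

#' Generate a synthetic functional kinase model fixture
#'
#' Emulates a TREKING-style model: per-kinase temporal barrier
#' functionality, pathway activity intervals, cluster assignments, and a
#' background kinase-substrate network (reused from the interactome's
#' directed layer). Barrier kinases are labeled functional from their
#' planted activation time to the end of the time course (`"weakening"` when
#' the cumulative cascade sign is positive, `"strengthening"` when
#' negative); all other kinases are `"none"` throughout. Barrier kinases are
#' spread over the first three clusters so that same-cluster pairs exist;
#' the remaining kinases are assigned uniformly over all `cfg$n_clusters`
#' clusters. Per cluster, a local network is built from all shortest paths
#' between same-cluster functional kinases in the background network.
#'
#' @param truth A `ground_truth` from [plant_cascade()].
#' @param net The [interactome()] whose kinase-substrate layer becomes the
#'   background network.
#' @param cfg A [sim_config()].
#' @return An object of class `treking_model`.
#' @export
generate_treking_fixture <- function(truth, net, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 5L)
  tg <- cfg$time_grid
  kinases <- net$nodes$id[net$nodes$is_kinase]
  barrier <- truth$barrier_kinases

  func <- matrix("none", length(kinases), length(tg),
                 dimnames = list(kinases, paste0("t", tg)))
  intervals <- stats::setNames(vector("list", length(kinases)), kinases)
  for (k in kinases) {
    if (k %in% barrier) {
      t0 <- truth$activation_times[[k]]
      lab <- if (truth$cum_sign[[k]] > 0) "weakening" else "strengthening"
      func[k, tg >= t0] <- lab
      intervals[[k]] <- matrix(c(t0, max(tg)), 1,
                               dimnames = list(NULL, c("start", "end")))
    } else {
      intervals[[k]] <- matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("start", "end")))
    }
  }

  clusters <- stats::setNames(integer(length(kinases)), kinases)
  clusters[barrier] <- sample(seq_len(min(3L, cfg$n_clusters)),
                              length(barrier), replace = TRUE)
  rest <- setdiff(kinases, barrier)
  clusters[rest] <- sample(seq_len(cfg$n_clusters), length(rest),
                           replace = TRUE)

  background <- data.frame(from = net$ks$kinase, to = net$ks$substrate,
                           stringsAsFactors = FALSE)
  functional <- kinases[apply(func != "none", 1, any)]
  cluster_networks <- cluster_path_networks(functional, clusters, background)

  treking_model(kinases, tg, func, intervals, clusters, background,
                cluster_networks, cfg$n_clusters)
}

#' Construct a functional kinase model
#'
#' @param kinases Character vector of kinase ids.
#' @param time_grid Analysis time grid in minutes.
#' @param functionality Kinase-by-time character matrix with entries in
#'   `weakening`, `strengthening`, `both`, `none`.
#' @param intervals Named list of two-column (`start`, `end`) matrices of
#'   pathway activity intervals, minutes.
#' @param clusters Named integer vector of cluster assignments.
#' @param background data.frame (`from`, `to`) of directed kinase-substrate
#'   edges.
#' @param cluster_networks Named list (by cluster id) of edge data.frames.
#' @param n_clusters Total number of clusters.
#' @return An object of class `treking_model`.
#' @export
treking_model <- function(kinases, time_grid, functionality, intervals,
                          clusters, background, cluster_networks,
                          n_clusters = 36L) {
  stopifnot(all(rownames(functionality) == kinases),
            all(functionality %in% c("weakening", "strengthening", "both",
                                     "none")))
  if (any(clusters < 1L | clusters > n_clusters)) {
    phosnet_stop("cluster assignments must lie in 1..n_clusters",
                 "phosnet_data_error")
  }
  structure(
    list(kinases = kinases, time_grid = as.numeric(time_grid),
         functionality = functionality, intervals = intervals,
         clusters = clusters, background = background,
         cluster_networks = cluster_networks,
         n_clusters = as.integer(n_clusters)),
    class = "treking_model"
  )
}

#' @export
print.treking_model <- function(x, ...) {
  cat(sprintf(
    "<treking_model> %d kinases, %d functional, %d clusters, %d bg edges\n",
    length(x$kinases), sum(apply(x$functionality != "none", 1, any)),
    x$n_clusters, nrow(x$background)))
  invisible(x)
}

# per-cluster union of all shortest paths between same-cluster functional
# kinases in a directed background network (unreachable pairs skipped)
cluster_path_networks <- function(functional, clusters, background) {
  g <- igraph::graph_from_data_frame(background, directed = TRUE)
  present <- intersect(functional, igraph::V(g)$name)
  out <- list()
  skipped <- 0L
  for (cl in sort(unique(clusters[present]))) {
    members <- present[clusters[present] == cl]
    ef <- character(0); et <- character(0)
    if (length(members) >= 2) {
      for (a in members) for (b in setdiff(members, a)) {
        sp <- suppressWarnings(
          igraph::all_shortest_paths(g, from = a, to = b, mode = "out")$vpaths
        )
        if (length(sp) == 0) { skipped <- skipped + 1L; next }
        for (p in sp) {
          nm <- names(p)
          ef <- c(ef, nm[-length(nm)]); et <- c(et, nm[-1])
        }
      }
    }
    edges <- unique(data.frame(from = ef, to = et, stringsAsFactors = FALSE))
    rownames(edges) <- NULL
    out[[as.character(cl)]] <- edges
  }
  attr(out, "unreachable_pairs") <- skipped
  out
}

#' Union kinase network of a functional kinase model
#'
#' Collapses a model's per-cluster shortest-path networks into a single
#' directed kinase network with per-edge functionality labels (the union of
#' the endpoint kinases' labels over the time course; `both` when weakening
#' and strengthening co-occur). Path segments through non-kinase
#' intermediates are dropped: the functional model describes
#' kinase-to-kinase connectivity only.
#'
#' @param model A [treking_model()].
#' @return A `kinase_network` (see [kinase_subnetwork()]).
#' @export
treking_network <- function(model) {
  stopifnot(inherits(model, "treking_model"))
  edges <- unique(do.call(rbind, c(model$cluster_networks,
                                   make.row.names = FALSE)))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[edges$from %in% model$kinases & edges$to %in% model$kinases, ,
                 drop = FALSE]
  node_label <- function(k) {
    if (!k %in% rownames(model$functionality)) return("none")
    f <- unique(model$functionality[k, ])
    f <- setdiff(f, "none")
    if (length(f) == 0) return("none")
    if (all(c("weakening", "strengthening") %in% f) || "both" %in% f) {
      return("both")
    }
    f[1]
  }
  lab <- vapply(seq_len(nrow(edges)), function(i) {
    fu <- node_label(edges$from[i]); fv <- node_label(edges$to[i])
    u <- setdiff(unique(c(fu, fv)), "none")
    if (length(u) == 0) "none"
    else if (length(u) == 1) u
    else "both"
  }, character(1))
  edges$functionality <- if (nrow(edges)) lab else character(0)
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = unique(c(edges$from, edges$to))),
            class = "kinase_network")
}
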