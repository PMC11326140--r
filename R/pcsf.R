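#' Parameters for prize-based subnetwork extraction
#'
#' Mirrors the Omics-Integrator-style parameterization of the
#' prize-collecting Steiner forest (PCSF) problem: `dummy_edge_weight`
#' (weight of the edge tying the artificial root to the source; with a
#' single source and a single tree it offsets every candidate equally and
#' never changes the optimum), `edge_reliability` (beta, the weight on
#' excluded-node prizes), `degree_penalty` (g; 0 disables the degree term)
#' and `n_randomizations` (number of noisy-prize runs whose trees are
#' aggregated). `inclusion_frequency` is the fraction of runs an edge must
#' appear in to be kept; `noise_scale` is the half-width of the uniform
#' multiplicative prize jitter applied per run.
#'
#' @param dummy_edge_weight Positive; default 10.
#' @param edge_reliability Positive; default 10.
#' @param degree_penalty Non-negative; default 0.
#' @param n_randomizations At least 1; default 100.
#' @param inclusion_frequency In (0, 1]; default 0.5.
#' @param noise_scale In \[0, 1); default 0.1.
#' @return An object of class `pcsf_params`.
#' @export
pcsf_params <- function(dummy_edge_weight = 10, edge_reliability = 10,
                        degree_penalty = 0, n_randomizations = 100,
                        inclusion_frequency = 0.5, noise_scale = 0.1) {
  if (dummy_edge_weight <= 0 || edge_reliability <= 0 || degree_penalty < 0 ||
      n_randomizations < 1 || inclusion_frequency <= 0 ||
      inclusion_frequency > 1 || noise_scale < 0 || noise_scale >= 1) {
    phosnet_stop("invalid PCSF parameters", "phosnet_config_error")
  }
  structure(
    list(dummy_edge_weight = dummy_edge_weight,
         edge_reliability = edge_reliability,
         degree_penalty = degree_penalty,
         n_randomizations = as.integer(n_randomizations),
         inclusion_frequency = inclusion_frequency,
         noise_scale = noise_scale),
    class = "pcsf_params"
  )
}

# undirected extraction graph: PPI edges plus undirected projections of
# kinase-substrate edges, deduplicated keeping the highest confidence
build_extraction_graph <- function(net) {
  e <- rbind(
    data.frame(from = net$ppi$from, to = net$ppi$to,
               confidence = net$ppi$confidence, stringsAsFactors = FALSE),
    data.frame(from = net$ks$kinase, to = net$ks$substrate,
               confidence = net$ks$confidence, stringsAsFactors = FALSE)
  )
  u <- pmin(e$from, e$to); v <- pmax(e$from, e$to)
  key <- paste(u, v)
  ord <- order(key, -e$confidence)
  e <- data.frame(from = u[ord], to = v[ord], confidence = e$confidence[ord],
                  stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$from, e$to)), , drop = FALSE]
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

edge_igraph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::E(g)$cost <- 1 - edges$confidence
  g
}

#' Prize-collecting Steiner objective
#'
#' Scores a candidate tree (or forest): the sum of `edge_reliability * prize`
#' over prized nodes left out, plus the cost `1 - confidence` of every
#' included edge, plus `degree_penalty` times the total degree of included
#' nodes (zero under the default parameterization). Lower is better.
#'
#' @param edges data.frame of included edges with columns `from`, `to`,
#'   `confidence`.
#' @param nodes Character vector of included node ids.
#' @param prizes Named numeric vector of node prizes.
#' @param params A [pcsf_params()].
#' @return The objective value (numeric scalar).
#' @export
pcsf_objective <- function(edges, nodes, prizes, params = pcsf_params()) {
  excluded <- setdiff(names(prizes)[prizes > 0], nodes)
  score <- params$edge_reliability * sum(prizes[excluded]) +
    sum(1 - edges$confidence)
  if (params$degree_penalty > 0 && nrow(edges) > 0) {
    deg <- table(c(edges$from, edges$to))
    score <- score + params$degree_penalty * sum(deg[names(deg) %in% nodes])
  }
  score
}

#' Exact PCSF optimum by exhaustive enumeration
#'
#' Enumerates every node subset containing the source; for each connected
#' induced subgraph the cheapest spanning tree (minimum spanning tree of the
#' induced subgraph) is scored with [pcsf_objective()]. Only feasible for
#' instances of at most 12 nodes; larger inputs raise an error.
#'
#' @param edges Undirected edge data.frame (`from`, `to`, `confidence`).
#' @param prizes Named numeric prizes.
#' @param source Source node id.
#' @param params A [pcsf_params()].
#' @return List with `score`, `nodes` and `edges` of the optimum.
#' @export
pcsf_exhaustive <- function(edges, prizes, source, params = pcsf_params()) {
  ids <- sort(unique(c(edges$from, edges$to, source, names(prizes))))
  if (length(ids) > 12) {
    phosnet_stop("exhaustive PCSF limited to instances of <= 12 nodes",
                 "phosnet_config_error")
  }
  others <- setdiff(ids, source)
  g <- edge_igraph(edges, nodes = data.frame(id = ids))
  best <- NULL
  for (mask in 0:(2^length(others) - 1)) {
    nodes <- c(source, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    sub <- igraph::induced_subgraph(g, nodes)
    if (length(nodes) > 1 && !igraph::is_connected(sub)) next
    tr <- igraph::mst(sub, weights = igraph::E(sub)$cost)
    te <- igraph::as_data_frame(tr, what = "edges")
    te <- data.frame(from = te$from, to = te$to, confidence = te$confidence,
                     stringsAsFactors = FALSE)
    sc <- pcsf_objective(te, nodes, prizes, params)
    if (is.null(best) || sc < best$score) {
      best <- list(score = sc, nodes = nodes, edges = te)
    }
  }
  best
}

# minimum spanning tree cost of a symmetric distance matrix (Prim); the
# deterministic tie-break is the lowest column index
prim_cost <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(list(cost = 0, edges = NULL))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[, 1]; parent <- rep(1L, n)
  total <- 0
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    total <- total + best[j]
    edges[k, ] <- c(parent[j], j)
    in_tree[j] <- TRUE
    upd <- !in_tree & D[, j] < best
    best[upd] <- D[upd, j]; parent[upd] <- j
  }
  list(cost = total, edges = edges)
}

# one randomized prize-collecting construction over the metric closure:
# greedy terminal selection by (beta * prize - distance-to-selected) gain,
# then a hill climb that adds/removes single terminals while the objective
# (beta * excluded prizes + closure-MST cost) improves, then expansion of
# the closure MST back to graph edges with a Steiner refinement (minimum
# spanning tree of the induced subgraph, non-terminal leaves pruned)
greedy_pcst <- function(D, prizes, source, beta, expand_edges, g) {
  prized <- sort(intersect(names(prizes)[prizes > 0], rownames(D)))
  chosen <- character(0)
  sel <- source
  repeat {
    cands <- setdiff(prized, chosen)
    if (length(cands) == 0) break
    dmin <- apply(D[cands, sel, drop = FALSE], 1, min)
    gain <- beta * prizes[cands] - dmin
    if (max(gain) <= 0) break
    best <- cands[which.max(gain)]
    chosen <- c(chosen, best); sel <- c(sel, best)
  }
  objective <- function(set) {
    beta * sum(prizes[setdiff(prized, set)]) +
      prim_cost(D[c(source, set), c(source, set), drop = FALSE])$cost
  }
  cur <- objective(chosen)
  repeat {
    improved <- FALSE
    for (v in chosen) {
      alt <- objective(setdiff(chosen, v))
      if (alt < cur - 1e-12) {
        chosen <- setdiff(chosen, v); cur <- alt; improved <- TRUE
      }
    }
    for (v in setdiff(prized, chosen)) {
      alt <- objective(c(chosen, v))
      if (alt < cur - 1e-12) {
        chosen <- c(chosen, v); cur <- alt; improved <- TRUE
      }
    }
    if (!improved) break
  }
  if (length(chosen) == 0) return(integer(0))
  term <- c(source, sort(chosen))
  mst <- prim_cost(D[term, term, drop = FALSE])
  eids <- integer(0)
  for (k in seq_len(nrow(mst$edges))) {
    eids <- union(eids, expand_edges(term[mst$edges[k, 1]],
                                     term[mst$edges[k, 2]]))
  }
  # Steiner refinement: MST of the subgraph induced by all touched nodes,
  # then repeated pruning of non-terminal leaves
  used <- unique(as.vector(igraph::ends(g, eids)))
  sub <- igraph::induced_subgraph(g, used)
  tr <- igraph::mst(sub, weights = igraph::E(sub)$cost)
  repeat {
    leaf <- setdiff(names(which(igraph::degree(tr) <= 1)), term)
    if (length(leaf) == 0) break
    tr <- igraph::delete_vertices(tr, leaf)
  }
  igraph::E(tr)$.eid
}

#' Extract a source-connected subnetwork by randomized prize-collecting runs
#'
#' Runs `params$n_randomizations` greedy rooted prize-collecting
#' constructions, each with prizes jittered multiplicatively by a uniform
#' factor in `1 +/- noise_scale`, and keeps the edges appearing in at least
#' `params$inclusion_frequency` of the runs, pruned to the component
#' containing the source. Each construction selects prized terminals
#' greedily by `edge_reliability * prize - cheapest path cost`, improves the
#' selection by single-terminal exchanges against the objective of
#' [pcsf_objective()] evaluated on the shortest-path metric closure, and
#' realizes the selection as a closure minimum spanning tree expanded back
#' to graph edges. It is a documented heuristic, not an exact solver.
#'
#' @param net An [interactome()].
#' @param prizes Named numeric protein prizes (see [compute_prizes()]).
#' @param source Source node id.
#' @param params A [pcsf_params()].
#' @param seed Integer seed for the prize jitter.
#' @return An object of class `subnetwork`: list with `edges` (undirected
#'   data.frame `from`, `to`, `confidence`, plus `frequency`, the fraction
#'   of runs containing the edge) and `source`.
#' @export
extract_subnetwork <- function(net, prizes, source, params = pcsf_params(),
                               seed = 1L) {
  stopifnot(inherits(net, "interactome"))
  edges <- build_extraction_graph(net)
  ids <- unique(c(edges$from, edges$to))
  if (!source %in% c(ids, net$nodes$id)) {
    phosnet_stop(sprintf("source node '%s' absent from interactome", source),
                 "phosnet_data_error")
  }
  prizes <- prizes[prizes > 0]
  if (length(prizes) == 0) {
    return(subnetwork(edges[0, , drop = FALSE], source))
  }
  g <- edge_igraph(edges, nodes = data.frame(id = union(ids, source)))
  comp <- igraph::components(g)
  src_comp <- comp$membership[source]
  reach <- names(comp$membership)[comp$membership == src_comp]
  unreachable <- setdiff(names(prizes), reach)
  if (length(unreachable) == length(prizes)) {
    phosnet_stop(sprintf("no prized protein reachable from %s: %s", source,
                         paste(sort(unreachable), collapse = ", ")),
                 "phosnet_data_error")
  }
  if (length(unreachable) > 0) {
    warning(sprintf("prized proteins unreachable from %s dropped: %s", source,
                    paste(sort(unreachable), collapse = ", ")))
    prizes <- prizes[setdiff(names(prizes), unreachable)]
  }

  igraph::E(g)$.eid <- seq_len(igraph::ecount(g))
  terminals <- unique(c(source, sort(names(prizes))))
  D <- igraph::distances(g, v = terminals, to = terminals,
                         weights = igraph::E(g)$cost)
  path_cache <- new.env(parent = emptyenv())
  expand_edges <- function(u, v) {
    key <- paste(min(u, v), max(u, v))
    hit <- path_cache[[key]]
    if (!is.null(hit)) return(hit)
    sp <- igraph::shortest_paths(g, from = u, to = v,
                                 weights = igraph::E(g)$cost,
                                 output = "epath")
    ids <- as.integer(sp$epath[[1]])
    path_cache[[key]] <- ids
    ids
  }

  set.seed(seed)
  counts <- integer(igraph::ecount(g))
  for (run in seq_len(params$n_randomizations)) {
    jit <- runif(length(prizes), 1 - params$noise_scale,
                 1 + params$noise_scale)
    eids <- greedy_pcst(D, prizes * jit, source, params$edge_reliability,
                        expand_edges, g)
    counts[eids] <- counts[eids] + 1L
  }
  keep <- which(counts >= params$inclusion_frequency * params$n_randomizations)
  kept <- igraph::ends(g, keep)
  kdf <- data.frame(from = pmin(kept[, 1], kept[, 2]),
                    to = pmax(kept[, 1], kept[, 2]),
                    confidence = 1 - igraph::E(g)$cost[keep],
                    frequency = counts[keep] / params$n_randomizations,
                    stringsAsFactors = FALSE)
  # prune to the source-connected component of the kept edges
  if (nrow(kdf) > 0) {
    gk <- igraph::graph_from_data_frame(kdf, directed = FALSE)
    if (source %in% igraph::V(gk)$name) {
      ck <- igraph::components(gk)
      in_src <- names(ck$membership)[ck$membership == ck$membership[source]]
      kdf <- kdf[kdf$from %in% in_src & kdf$to %in% in_src, , drop = FALSE]
    } else {
      kdf <- kdf[0, , drop = FALSE]
    }
  }
  kdf <- kdf[order(kdf$from, kdf$to), , drop = FALSE]
  rownames(kdf) <- NULL
  subnetwork(kdf, source)
}

#' Construct a subnetwork object
#'
#' @param edges Undirected edge data.frame with columns `from`, `to` and
#'   optionally `confidence`.
#' @param source Designated source node id.
#' @return An object of class `subnetwork`. Every node must be reachable
#'   from the source within the edge set.
#' @export
subnetwork <- function(edges, source) {
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  obj <- structure(list(edges = edges, source = source), class = "subnetwork")
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    if (!source %in% igraph::V(g)$name) {
      phosnet_stop("subnetwork edges do not touch the source node",
                   "phosnet_data_error")
    }
    comp <- igraph::components(g)
    if (length(unique(comp$membership)) > 1) {
      phosnet_stop("subnetwork must be connected to the source",
                   "phosnet_data_error")
    }
  }
  obj
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> source %s, %d undirected edges, %d nodes\n",
              x$source, nrow(x$edges),
              length(unique(c(x$edges$from, x$edges$to, x$source)))))
  invisible(x)
}
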