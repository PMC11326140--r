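#' Construct a background interactome object
#'
#' An interactome couples an undirected protein-protein interaction (PPI)
#' layer carrying edge confidences with a directed kinase-substrate layer
#' (optionally signed). Nodes carry an `is_kinase` flag; every source node of
#' a kinase-substrate edge must be flagged as a kinase.
#'
#' @param nodes data.frame with columns `id` (character) and `is_kinase`
#'   (logical).
#' @param ppi data.frame with columns `from`, `to`, `confidence` (in (0, 1]).
#' @param ks data.frame with columns `kinase`, `substrate`, `sign`
#'   (+1, -1 or NA for unknown) and `confidence`.
#' @param source Optional designated source (receptor) node id.
#'
#' @return An object of class `interactome`.
#' @export
interactome <- function(nodes, ppi, ks, source = NULL) {
  nodes$id <- as.character(nodes$id)
  ppi$from <- as.character(ppi$from); ppi$to <- as.character(ppi$to)
  ks$kinase <- as.character(ks$kinase); ks$substrate <- as.character(ks$substrate)
  obj <- structure(
    list(nodes = nodes, ppi = ppi, ks = ks, source = source),
    class = "interactome"
  )
  validate_interactome(obj)
}

validate_interactome <- function(net) {
  if (any(net$ppi$from == net$ppi$to) || any(net$ks$kinase == net$ks$substrate)) {
    phosnet_stop("interactome must not contain self-loops", "phosnet_data_error")
  }
  if (any(net$ppi$confidence <= 0) || any(net$ppi$confidence > 1)) {
    phosnet_stop("PPI confidences must lie in (0, 1]", "phosnet_data_error")
  }
  ids <- net$nodes$id
  all_ref <- unique(c(net$ppi$from, net$ppi$to, net$ks$kinase, net$ks$substrate))
  if (!all(all_ref %in% ids)) {
    phosnet_stop(sprintf("edges reference unknown nodes: %s",
                         paste(setdiff(all_ref, ids), collapse = ", ")),
                 "phosnet_data_error")
  }
  kin <- net$nodes$id[net$nodes$is_kinase]
  if (!all(net$ks$kinase %in% kin)) {
    phosnet_stop("every kinase-substrate edge must originate at a kinase node",
                 "phosnet_data_error")
  }
  if (!is.null(net$source) && !net$source %in% ids) {
    phosnet_stop("designated source node absent from interactome",
                 "phosnet_data_error")
  }
  net
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d nodes (%d kinases), %d PPI edges, %d KS edges\n",
              nrow(x$nodes), sum(x$nodes$is_kinase), nrow(x$ppi), nrow(x$ks)))
  if (!is.null(x$source)) cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

# confidence at or above this marks the curated high-confidence backbone of a
# synthetic interactome; the planted cascade lives on it (see plant_cascade).
# Backbone edge costs (1 - confidence, <= 0.005) are small enough that a path
# of backbone edges is always cheaper than any single non-backbone edge
# (cost >= 0.1), which pins prize-based extraction to the backbone.
CORE_CONFIDENCE <- 0.995

#' Generate a synthetic background interactome
#'
#' Builds a connected undirected PPI layer over `n_proteins` nodes with
#' confidence weights in (0, 1], flags `n_kinases` nodes as kinases, and adds
#' directed kinase-substrate edges out of kinase nodes (signed with
#' probability 0.7). Node `"SRC"` is the designated receptor/source node and
#' is never a kinase.
#'
#' The layer contains a high-confidence backbone: a tree of
#' `cfg$cascade_size` nodes rooted at `"SRC"` whose edges carry confidence at
#' or above 0.995, while all other edges stay at or below 0.9. This mirrors
#' the fact that canonical pathway edges are the best-curated part of
#' interaction databases, and it is where [plant_cascade()] grows the
#' ground-truth cascade; the cost separation (any backbone path is cheaper
#' than any single non-backbone edge) makes the planted pathway the uniquely
#' cheapest way to connect its members, so noiseless recovery is exact.
#' Kinase-substrate edges never oppose the backbone orientation, so directed
#' priors stay consistent with the planted signal flow.
#'
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An [interactome()] with `source = "SRC"`.
#' @export
generate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  n_kin <- cfg$n_kinases
  kin_ids <- sprintf("K%02d", seq_len(n_kin))
  oth_ids <- if (n - 1L - n_kin > 0) sprintf("P%02d", seq_len(n - 1L - n_kin))
             else character(0)
  ids <- c("SRC", kin_ids, oth_ids)
  nodes <- data.frame(id = ids, is_kinase = ids %in% kin_ids,
                      stringsAsFactors = FALSE)

  # high-confidence backbone: tree rooted at SRC, mostly kinases
  n_core <- cfg$cascade_size
  n_core_kin <- min(n_kin, ceiling(0.75 * (n_core - 1L)))
  core <- c("SRC", sample(kin_ids, n_core_kin),
            sample(oth_ids, n_core - 1L - n_core_kin))
  # chain-biased tree: new members attach to one of the three most recent
  # members (depth-capped), giving the elongated topology of a signaling
  # cascade rather than a shallow star
  core_par <- character(0); core_child <- character(0)
  core_depth <- c(0L, rep(NA_integer_, n_core - 1L))
  for (i in 2:n_core) {
    recent <- rev(seq_len(i - 1L))
    recent <- recent[core_depth[recent] <= 6L]
    cand <- utils::head(recent, 3L)
    pick <- cand[sample.int(length(cand), 1L)]
    core_par <- c(core_par, core[pick])
    core_child <- c(core_child, core[i])
    core_depth[i] <- core_depth[pick] + 1L
  }
  core_df <- data.frame(
    from = core_par, to = core_child,
    confidence = round(runif(n_core - 1L, CORE_CONFIDENCE, 0.999), 4),
    stringsAsFactors = FALSE
  )

  # every remaining node hangs off the backbone by one mid-confidence edge
  # (hub-like topology around the curated pathway core); extra low-confidence
  # edges then densify the layer to mean degree ~4. The three confidence
  # bands are disjoint (backbone >= 0.995 > attach 0.85-0.9 > rest <= 0.8),
  # so each peripheral node's cheapest route into the network is its own
  # attachment edge.
  rest <- setdiff(ids, core)
  from <- sample(core, length(rest), replace = TRUE)
  to <- rest
  attach_df <- data.frame(
    from = from, to = to,
    confidence = round(runif(length(rest), 0.85, 0.9), 4),
    stringsAsFactors = FALSE
  )
  seen <- c(paste(pmin(core_df$from, core_df$to), pmax(core_df$from, core_df$to)),
            paste(pmin(from, to), pmax(from, to)))
  xf <- character(0); xt <- character(0)
  n_extra <- max(0L, as.integer(2 * n) - length(seen))
  tries <- 0L
  while (n_extra > 0L && tries < 100L * n) {
    uv <- sample(ids, 2L)
    key <- paste(min(uv), max(uv))
    if (!key %in% seen) {
      xf <- c(xf, uv[1]); xt <- c(xt, uv[2])
      seen <- c(seen, key)
      n_extra <- n_extra - 1L
    }
    tries <- tries + 1L
  }
  ppi <- rbind(core_df, attach_df, data.frame(
    from = xf, to = xt,
    confidence = round(runif(length(xf), 0.4, 0.8), 4),
    stringsAsFactors = FALSE
  ))
  rownames(ppi) <- NULL

  # kinase-substrate layer. Directed priors follow the signal flow of the
  # synthetic pathway: substrates are core members or non-kinase proteins
  # (never peripheral kinases, which act as upstream regulators), priors
  # never oppose a backbone edge, and every peripheral kinase carries a
  # signed prior into its core attachment point.
  core_oriented <- paste(core_df$from, core_df$to)
  periph_kin <- setdiff(kin_ids, core)
  sub_pool <- setdiff(ids, c("SRC", periph_kin))
  ks_from <- character(0); ks_to <- character(0); ks_core <- logical(0)
  for (k in kin_ids) {
    subs <- sample(setdiff(sub_pool, k), sample(1:4, 1L))
    subs <- subs[!paste(subs, k) %in% core_oriented]
    if (length(subs) == 0) next
    ks_from <- c(ks_from, rep(k, length(subs)))
    ks_to <- c(ks_to, subs)
    ks_core <- c(ks_core, paste(k, subs) %in% core_oriented)
  }
  # signed priors along part of the backbone where the parent is a kinase
  bb_kin <- core_df$from %in% kin_ids
  add <- bb_kin & runif(nrow(core_df)) < 0.6
  if (any(add)) {
    ks_from <- c(ks_from, core_df$from[add])
    ks_to <- c(ks_to, core_df$to[add])
    ks_core <- c(ks_core, rep(TRUE, sum(add)))
  }
  # peripheral kinases phosphorylate their core attachment point
  pk <- attach_df$to %in% periph_kin
  if (any(pk)) {
    ks_from <- c(ks_from, attach_df$to[pk])
    ks_to <- c(ks_to, attach_df$from[pk])
    ks_core <- c(ks_core, rep(FALSE, sum(pk)))
  }
  keep <- !duplicated(paste(ks_from, ks_to))
  ks_from <- ks_from[keep]; ks_to <- ks_to[keep]; ks_core <- ks_core[keep]
  m <- length(ks_from)
  periph_edge <- ks_from %in% periph_kin & !ks_core
  sign_known <- runif(m) < 0.7 | periph_edge
  ks <- data.frame(
    kinase = ks_from, substrate = ks_to,
    sign = ifelse(sign_known,
                  ifelse(runif(m) < cfg$frac_inhibitory, -1L, 1L),
                  NA_integer_),
    confidence = round(ifelse(ks_core, runif(m, CORE_CONFIDENCE, 0.999),
                              runif(m, 0.6, 0.8)), 4),
    stringsAsFactors = FALSE
  )
  rownames(ks) <- NULL

  interactome(nodes, ppi, ks, source = "SRC")
}

#' Plant a signed signaling cascade in an interactome
#'
#' Grows a signed, directed, acyclic cascade rooted at the designated source
#' node over the interactome's high-confidence backbone (edges with
#' confidence at or above 0.995), using only adjacencies already present in
#' the interactome. Where the kinase-substrate layer supplies a signed
#' directed prior for a cascade edge, the cascade honors it; otherwise the
#' edge direction follows the outward growth and the sign is sampled
#' (negative with probability `cfg$frac_inhibitory`). Activation times are
#' taken from the time grid, non-decreasing with cascade depth; the source
#' activates at time 0.
#'
#' @param net An [interactome()] with a designated source node.
#' @param cfg A [sim_config()].
#' @return An object of class `ground_truth` with fields `source_node`,
#'   `cascade_edges` (data.frame `from`, `to`, `sign`), `activation_times`
#'   (named, minutes), `cum_sign` (net sign of the source-to-node path) and
#'   `barrier_kinases` (cascade kinases coupled to the permeability
#'   phenotype).
#' @export
plant_cascade <- function(net, cfg) {
  stopifnot(inherits(net, "interactome"), inherits(cfg, "sim_config"))
  if (is.null(net$source)) {
    phosnet_stop("interactome has no designated source node",
                 "phosnet_data_error")
  }
  set.seed(cfg$seed + 1L)
  src <- net$source

  core <- net$ppi[net$ppi$confidence >= CORE_CONFIDENCE, , drop = FALSE]
  if (nrow(core) == 0) {
    phosnet_stop("interactome has no high-confidence backbone to plant on",
                 "phosnet_data_error")
  }
  ks_key <- paste(net$ks$kinase, net$ks$substrate)

  # breadth-first growth from the source over backbone edges, randomized
  # sibling order; KS priors may not be traversed against their direction
  parent <- list()
  depth <- stats::setNames(0L, src)
  members <- src; queue <- src
  adj <- split(c(core$to, core$from), c(core$from, core$to))
  while (length(queue) > 0 && length(members) < cfg$cascade_size) {
    u <- queue[1]; queue <- queue[-1]
    nbrs <- setdiff(unique(adj[[u]]), members)
    if (length(nbrs) > 1) nbrs <- sample(nbrs)
    for (v in nbrs) {
      if (length(members) >= cfg$cascade_size) break
      if (paste(v, u) %in% ks_key && !paste(u, v) %in% ks_key) next
      parent[[v]] <- u
      depth[v] <- depth[[u]] + 1L
      members <- c(members, v)
      queue <- c(queue, v)
    }
  }
  kids <- setdiff(members, src)
  if (length(kids) == 0) {
    phosnet_stop("source node has no admissible backbone neighbors",
                 "phosnet_data_error")
  }

  sgn <- vapply(kids, function(v) {
    u <- parent[[v]]
    hit <- which(net$ks$kinase == u & net$ks$substrate == v)
    if (length(hit) > 0 && !is.na(net$ks$sign[hit[1]])) {
      return(net$ks$sign[hit[1]])
    }
    if (runif(1) < cfg$frac_inhibitory) -1L else 1L
  }, integer(1))
  edges <- data.frame(from = unname(vapply(kids, function(v) parent[[v]], "")),
                      to = kids, sign = unname(sgn), stringsAsFactors = FALSE)

  # fast receptor-proximal signaling: every cascade member responds by the
  # first post-stimulation sample (thrombin-receptor kinetics), so the first
  # significant change of a responsive protein is unambiguous at any
  # realistic replicate noise
  tg <- cfg$time_grid
  act <- vapply(members, function(v) tg[min(depth[[v]] + 1L, 2L)],
                numeric(1))

  cum <- stats::setNames(1L, src)
  for (v in kids[order(depth[kids])]) cum[v] <- cum[[parent[[v]]]] * sgn[[v]]

  kin <- net$nodes$id[net$nodes$is_kinase]
  structure(
    list(source_node = src, cascade_edges = edges,
         activation_times = act, cum_sign = cum,
         barrier_kinases = intersect(members, kin)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> source %s, %d cascade edges, %d barrier kinases\n",
    x$source_node, nrow(x$cascade_edges), length(x$barrier_kinases)))
  invisible(x)
}
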