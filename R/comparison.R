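#' Kinase-kinase subnetwork of a directed network
#'
#' Keeps the directed edges whose endpoints are both kinases; the node set
#' is the set of endpoints of surviving edges. Idempotent.
#'
#' @param net A `summary_network`, `kinase_network`, or any data.frame (or
#'   list with an `edges` data.frame) with `from`/`to` columns.
#' @param kinases Nonempty character vector of kinase ids.
#' @return An object of class `kinase_network`: list with `edges`
#'   (data.frame `from`, `to`, plus any label columns carried over) and
#'   `nodes`.
#' @export
kinase_subnetwork <- function(net, kinases) {
  edges <- if (is.data.frame(net)) net else net$edges
  if (length(kinases) == 0) {
    edges <- edges[0, , drop = FALSE]
  } else {
    edges <- edges[edges$from %in% kinases & edges$to %in% kinases, ,
                   drop = FALSE]
  }
  edges <- as.data.frame(edges)
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = unique(c(edges$from, edges$to))),
            class = "kinase_network")
}

#' @export
print.kinase_network <- function(x, ...) {
  cat(sprintf("<kinase_network> %d kinases, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node and edge overlap between two kinase networks
#'
#' Counts shared kinases and shared directed edges. The percentage
#' conventions are asymmetric by design: node overlap is expressed relative
#' to the node count of `b` (how many of the second model's kinases the
#' first also finds), edge overlap relative to the edge count of `a` (how
#' many of the first network's edges the second supports). Edge identity is
#' the ordered `(from, to)` pair; signs and labels are ignored. Percentages
#' are rounded to one decimal; an empty denominator yields NA (undefined),
#' never 0.
#'
#' @param a,b `kinase_network` objects (see [kinase_subnetwork()]).
#' @return List with `node_overlap_count`, `node_overlap_pct_of_b`,
#'   `edge_overlap_count`, `edge_overlap_pct_of_a`.
#' @export
overlap_stats <- function(a, b) {
  stopifnot(inherits(a, "kinase_network"), inherits(b, "kinase_network"))
  node_ov <- length(intersect(a$nodes, b$nodes))
  ea <- unique(paste(a$edges$from, a$edges$to))
  eb <- unique(paste(b$edges$from, b$edges$to))
  edge_ov <- length(intersect(ea, eb))
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)
  list(
    node_overlap_count = node_ov,
    node_overlap_pct_of_b = pct(node_ov, length(b$nodes)),
    edge_overlap_count = edge_ov,
    edge_overlap_pct_of_a = pct(edge_ov, length(ea))
  )
}
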