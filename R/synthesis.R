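#' Construct a partial model of directed kinase-substrate priors
#'
#' A partial model constrains edge orientation during pathway synthesis: a
#' directed edge `u -> v` present here (and its reverse absent) forbids the
#' orientation `v -> u`, and a known sign forbids the opposite sign for that
#' direction.
#'
#' @param edges data.frame with columns `from`, `to` and `sign` (+1, -1, or
#'   NA when the direction is known but the sign is not).
#' @param nodes Optional node universe; edges with endpoints outside it are
#'   dropped with a warning.
#' @return An object of class `partial_model`.
#' @export
partial_model <- function(edges, nodes = NULL) {
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (!"sign" %in% names(edges)) edges$sign <- NA_integer_
  if (!is.null(nodes)) {
    keep <- edges$from %in% nodes & edges$to %in% nodes
    if (any(!keep)) {
      warning(sprintf("%d partial-model edges with endpoints outside the node set dropped",
                      sum(!keep)))
    }
    edges <- edges[keep, , drop = FALSE]
  }
  edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "partial_model")
}

#' Partial model from an interactome's kinase-substrate layer
#'
#' @param net An [interactome()].
#' @return A [partial_model()] carrying the directed kinase-substrate edges
#'   and their signs.
#' @export
ks_partial_model <- function(net) {
  stopifnot(inherits(net, "interactome"))
  partial_model(data.frame(from = net$ks$kinase, to = net$ks$substrate,
                           sign = net$ks$sign, stringsAsFactors = FALSE))
}

#' Enumerate signed, directed edge candidates for a subnetwork
#'
#' Every undirected subnetwork edge `{u, v}` yields up to four candidates
#' (two orientations times two signs), restricted by the partial model: when
#' the model contains `u -> v` but not `v -> u`, the `v -> u` orientation is
#' dropped; when it assigns a sign to a direction, the opposite sign for
#' that direction is dropped. Partial-model edges whose endpoints are not
#' both in the subnetwork are ignored.
#'
#' @param sub A [subnetwork()].
#' @param pm A [partial_model()] (or NULL for no restriction).
#' @return data.frame with columns `from`, `to`, `sign` (+1/-1).
#' @export
candidate_events <- function(sub, pm = NULL) {
  stopifnot(inherits(sub, "subnetwork"))
  nodes <- unique(c(sub$edges$from, sub$edges$to, sub$source))
  pme <- if (is.null(pm)) {
    data.frame(from = character(0), to = character(0), sign = integer(0))
  } else {
    pm$edges[pm$edges$from %in% nodes & pm$edges$to %in% nodes, , drop = FALSE]
  }
  pm_key <- paste(pme$from, pme$to)
  out_from <- character(0); out_to <- character(0); out_sign <- integer(0)
  for (i in seq_len(nrow(sub$edges))) {
    u <- sub$edges$from[i]; v <- sub$edges$to[i]
    for (d in list(c(u, v), c(v, u))) {
      fwd <- paste(d[1], d[2]); rev <- paste(d[2], d[1])
      if (!fwd %in% pm_key && rev %in% pm_key) next  # orientation forbidden
      signs <- c(1L, -1L)
      if (fwd %in% pm_key) {
        s <- pme$sign[match(fwd, pm_key)]
        if (!is.na(s)) signs <- s
      }
      out_from <- c(out_from, rep(d[1], length(signs)))
      out_to <- c(out_to, rep(d[2], length(signs)))
      out_sign <- c(out_sign, signs)
    }
  }
  res <- data.frame(from = out_from, to = out_to, sign = out_sign,
                    stringsAsFactors = FALSE)
  res <- res[order(res$from, res$to, res$sign), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# first-change lookup tables from activity profiles
fc_tables <- function(profiles) {
  fc <- first_changes(profiles)
  list(time = stats::setNames(fc$first_change, fc$protein),
       dir = stats::setNames(fc$direction, fc$protein),
       measured = fc$protein)
}

#' Is a signed, source-rooted path consistent with the temporal data?
#'
#' A simple directed signed path starting at the source is valid when
#' (i) the first-change times of its measured nodes are non-decreasing along
#' the path, (ii) its terminal node is measured and changes, and (iii) at
#' every measured node the cumulative sign product from the source matches
#' the direction of that node's first observed change (activated = +1,
#' inhibited = -1). Unmeasured intermediates impose no timing constraint but
#' contribute their edge sign to the product; measured nodes that never
#' change cannot lie on a valid path (they have no change direction for the
#' sign product to match).
#'
#' @param nodes Character vector of path nodes, starting at the source.
#' @param signs Integer vector of edge signs (+1/-1), one per consecutive
#'   node pair.
#' @param profiles Named list of [discretize_activity()] profiles for the
#'   measured nodes.
#' @param source Source node id; the path must start here.
#' @return TRUE or FALSE.
#' @export
is_valid_path <- function(nodes, signs, profiles, source) {
  if (length(nodes) < 2 || nodes[1] != source) {
    phosnet_stop("path must start at the source node", "phosnet_data_error")
  }
  if (length(signs) != length(nodes) - 1 || anyDuplicated(nodes) > 0) {
    return(FALSE)
  }
  fc <- fc_tables(profiles)
  cum <- 1L
  last_t <- -Inf
  for (i in seq(2, length(nodes))) {
    v <- nodes[i]
    cum <- cum * signs[i - 1]
    if (v %in% fc$measured) {
      tv <- fc$time[[v]]
      if (!is.finite(tv)) return(FALSE)           # measured but never changes
      if (tv < last_t) return(FALSE)              # timing order violated
      if (fc$dir[[v]] != cum) return(FALSE)       # sign inconsistent
      last_t <- tv
    }
  }
  nodes[length(nodes)] %in% fc$measured &&
    is.finite(fc$time[[nodes[length(nodes)]]])
}

#' Synthesize a temporal summary network from a subnetwork
#'
#' The synthesis core: enumerates (by depth-first search with incremental
#' pruning) every valid simple signed directed path of at most
#' `max_path_len` edges from the source, under the constraints of
#' [is_valid_path()], and consolidates them into a single summary network.
#' Each edge used by at least one valid path is emitted with its direction;
#' it additionally carries a sign (`activation`/`inhibition`) only when all
#' valid paths through that node pair agree on one (direction, sign)
#' combination, and `unknown` otherwise. When both orientations of a pair
#' occur in valid paths, both directed edges are emitted, each unsigned.
#'
#' Per-node activity windows are also produced: measured nodes take the
#' states of their activity profiles; the source is activated at time 0;
#' unmeasured nodes are admissible as activated (or inhibited) from the
#' onset implied by any valid path routing signal through them with positive
#' (or negative) cumulative sign, and inactive is always admissible for
#' them.
#'
#' @param sub A [subnetwork()].
#' @param pm A [partial_model()] or NULL.
#' @param profiles Named list of [discretize_activity()] profiles.
#' @param source Source node id (default: the subnetwork's).
#' @param max_path_len Maximum number of edges per path (default 8).
#' @return List with `summary` (a `summary_network` data.frame: `from`,
#'   `to`, `sign`, `n_paths`, with attribute `unexplained` naming measured
#'   changing nodes no valid path reaches) and `windows` (an
#'   `activity_windows` object).
#' @export
synthesize <- function(sub, pm, profiles, source = sub$source,
                       max_path_len = 8) {
  stopifnot(inherits(sub, "subnetwork"))
  cands <- candidate_events(sub, pm)
  fc <- fc_tables(profiles)
  tg <- profiles[[1]]$time_grid

  # adjacency: per from-node, candidate (to, sign) pairs
  adj <- split(seq_len(nrow(cands)), cands$from)

  acc <- new.env(parent = emptyenv())
  acc$counts <- list()       # "u>v|s" -> number of valid paths using the edge
  acc$explained <- character(0)
  acc$windows <- list()      # node -> list of c(sign, onset)

  record_path <- function(path_nodes, path_signs, path_cum) {
    n <- length(path_nodes)
    keys <- paste0(path_nodes[-n], ">", path_nodes[-1], "|", path_signs)
    for (k in keys) {
      acc$counts[[k]] <- (acc$counts[[k]] %||% 0L) + 1L
    }
    acc$explained <- union(acc$explained, path_nodes[n])
    # unmeasured intermediates: admissible as signal relays from the change
    # time of the last measured node upstream of them
    last_t <- 0
    for (i in seq(2, n)) {
      v <- path_nodes[i]
      if (v %in% fc$measured) {
        last_t <- fc$time[[v]]
      } else {
        acc$windows[[v]] <- c(acc$windows[[v]],
                              list(c(path_cum[i - 1], last_t)))
      }
    }
  }

  recurse <- function(node, visited, cum, last_t, path_nodes, path_signs,
                      path_cum, depth) {
    if (depth >= max_path_len) return(invisible())
    for (i in adj[[node]]) {
      w <- cands$to[i]
      if (w %in% visited) next
      s <- cands$sign[i]
      cum2 <- cum * s
      if (w %in% fc$measured) {
        tw <- fc$time[[w]]
        if (!is.finite(tw) || tw < last_t || fc$dir[[w]] != cum2) next
        np <- c(path_nodes, w); ns <- c(path_signs, s); nc <- c(path_cum, cum2)
        record_path(np, ns, nc)
        recurse(w, c(visited, w), cum2, tw, np, ns, nc, depth + 1)
      } else {
        recurse(w, c(visited, w), cum2, last_t,
                c(path_nodes, w), c(path_signs, s), c(path_cum, cum2),
                depth + 1)
      }
    }
    invisible()
  }
  if (source %in% names(adj)) {
    recurse(source, source, 1L, 0, source, integer(0), integer(0), 0L)
  }

  summary <- consolidate_counts(acc$counts)
  changing <- fc$measured[is.finite(fc$time[fc$measured])]
  attr(summary, "unexplained") <- setdiff(changing, acc$explained)
  attr(summary, "source") <- source

  windows <- build_activity_windows(sub, profiles, source, tg, acc$windows)
  list(summary = summary, windows = windows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared consolidation of "u>v|s" path counts into a summary network
consolidate_counts <- function(counts) {
  if (length(counts) == 0) {
    return(summary_network(data.frame(from = character(0), to = character(0),
                                      sign = character(0),
                                      n_paths = integer(0),
                                      stringsAsFactors = FALSE)))
  }
  keys <- names(counts)
  parts <- do.call(rbind, strsplit(keys, "[>|]"))
  df <- data.frame(from = parts[, 1], to = parts[, 2],
                   sign = as.integer(parts[, 3]),
                   n = unlist(counts, use.names = FALSE),
                   stringsAsFactors = FALSE)
  df$pair <- paste(pmin(df$from, df$to), pmax(df$from, df$to))
  out <- lapply(split(df, df$pair), function(d) {
    dirs <- unique(paste(d$from, d$to))
    unique_combo <- nrow(d) == 1
    res <- lapply(dirs, function(dd) {
      dd_rows <- d[paste(d$from, d$to) == dd, , drop = FALSE]
      sign_lab <- if (unique_combo) {
        if (dd_rows$sign[1] > 0) "activation" else "inhibition"
      } else "unknown"
      data.frame(from = dd_rows$from[1], to = dd_rows$to[1], sign = sign_lab,
                 n_paths = sum(dd_rows$n), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$from, res$to), , drop = FALSE]
  rownames(res) <- NULL
  summary_network(res)
}

#' Construct a summary network
#'
#' @param edges data.frame with columns `from`, `to`, `sign` (one of
#'   `activation`, `inhibition`, `unknown`) and `n_paths` (count of valid
#'   paths using the edge).
#' @return The data.frame with class `summary_network`.
#' @export
summary_network <- function(edges) {
  stopifnot(all(c("from", "to", "sign", "n_paths") %in% names(edges)),
            all(edges$sign %in% c("activation", "inhibition", "unknown")))
  if (anyDuplicated(paste(edges$from, edges$to)) > 0) {
    phosnet_stop("duplicate directed edges in summary network",
                 "phosnet_data_error")
  }
  class(edges) <- c("summary_network", "data.frame")
  edges
}

#' @export
print.summary_network <- function(x, ...) {
  cat(sprintf("<summary_network> %d directed edges, %d signed\n",
              nrow(x), sum(x$sign != "unknown")))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  invisible(x)
}

# activity windows: per node a T x 3 logical matrix of admissible states
build_activity_windows <- function(sub, profiles, source, tg, relay) {
  nodes <- unique(c(sub$edges$from, sub$edges$to, source))
  states <- c("activated", "inhibited", "inactive")
  win <- lapply(nodes, function(v) {
    m <- matrix(TRUE, length(tg), 3, dimnames = list(paste0("t", tg), states))
    if (v %in% names(profiles)) {
      m[] <- FALSE
      st <- profiles[[v]]$states
      m[cbind(seq_along(tg), match(st, states))] <- TRUE
    } else if (v == source) {
      m[1, ] <- c(TRUE, FALSE, FALSE)
    } else if (v %in% names(relay)) {
      m[, c("activated", "inhibited")] <- FALSE
      for (wnd in relay[[v]]) {
        lab <- if (wnd[1] > 0) "activated" else "inhibited"
        m[tg >= wnd[2], lab] <- TRUE
      }
    }
    m
  })
  names(win) <- nodes
  structure(list(time_grid = tg, states = win), class = "activity_windows")
}

#' Exhaustive oracle for the synthesis step
#'
#' Independently recomputes the summary network by brute force: enumerates
#' every simple directed path from the source in the candidate digraph, then
#' every sign assignment over the per-edge allowed signs, keeps the
#' combinations [is_valid_path()] accepts, and consolidates them under the
#' same rule as [synthesize()]. Limited to subnetworks of at most 12 nodes.
#'
#' @inheritParams synthesize
#' @return A `summary_network`.
#' @export
brute_force_summary <- function(sub, pm, profiles, source = sub$source) {
  stopifnot(inherits(sub, "subnetwork"))
  nodes <- unique(c(sub$edges$from, sub$edges$to, source))
  if (length(nodes) > 12) {
    phosnet_stop("brute_force_summary limited to instances of <= 12 nodes",
                 "phosnet_config_error")
  }
  cands <- candidate_events(sub, pm)
  dirs <- unique(cands[, c("from", "to")])
  adj <- split(dirs$to, dirs$from)
  allowed_signs <- function(u, v) {
    cands$sign[cands$from == u & cands$to == v]
  }

  paths <- list()
  walk <- function(node, visited, path) {
    for (w in setdiff(adj[[node]] %||% character(0), visited)) {
      p <- c(path, w)
      paths[[length(paths) + 1]] <<- p
      walk(w, c(visited, w), p)
    }
  }
  walk(source, source, source)

  counts <- list()
  for (p in paths) {
    n <- length(p)
    sign_sets <- lapply(seq_len(n - 1), function(i) allowed_signs(p[i], p[i + 1]))
    if (any(vapply(sign_sets, length, 1L) == 0)) next
    combos <- as.matrix(expand.grid(sign_sets))
    for (r in seq_len(nrow(combos))) {
      sg <- as.integer(combos[r, ])
      if (is_valid_path(p, sg, profiles, source)) {
        keys <- paste0(p[-n], ">", p[-1], "|", sg)
        for (k in keys) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    }
  }
  consolidate_counts(counts)
}
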