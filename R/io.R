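#' @name phosnet-io
#' @title Readers and writers for the pipeline's tabular formats
#'
#' @description All pipeline artifacts are plain TSV (or JSON) files.
#' Writers accept a `header` character vector emitted as `#`-prefixed
#' comment lines (stage, parameters, seed); readers skip comments but keep
#' them in the `"header"` attribute, so `write(read(x))` reproduces a
#' canonical file byte for byte. Malformed rows and duplicate edges are
#' rejected with the offending line named.
NULL

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  attr(df, "header") <- sub("^# ?", "", hdr)
  attr(df, "first_data_line") <- length(hdr) + 2L  # after the column header
  df
}

grid_from_columns <- function(cols, path) {
  if (!all(grepl("^t[0-9]+$", cols))) {
    phosnet_stop(sprintf("%s: time columns must be named t<minutes>", path),
                 "phosnet_data_error")
  }
  as.numeric(sub("^t", "", cols))
}

#' Write/read a phosphorylation time-series dataset
#'
#' One row per protein and replicate; columns `protein`, `replicate`, then
#' one `t<minutes>` column per grid point. The reader enforces the expected
#' time grid (by default the canonical nine-point grid of
#' [phospho_time_grid()]): files on a different grid are rejected.
#'
#' @param dataset A `phospho_dataset`.
#' @param path File path.
#' @param header Optional comment lines.
#' @return `write_timeseries_tsv` the path, invisibly;
#'   `read_timeseries_tsv` a `phospho_dataset`.
#' @export
write_timeseries_tsv <- function(dataset, path, header = NULL) {
  rows <- lapply(dataset, function(ts) {
    data.frame(protein = ts$protein, replicate = seq_len(nrow(ts$values)),
               ts$values, check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (is.null(header)) header <- attr(dataset, "header")
  write_tsv_with_header(df, path, header)
}

#' @rdname write_timeseries_tsv
#' @param expected_grid Time grid (minutes) the file must match; NULL
#'   disables the check.
#' @export
read_timeseries_tsv <- function(path, expected_grid = phospho_time_grid()) {
  df <- read_tsv_with_header(path)
  if (!all(c("protein", "replicate") %in% names(df))) {
    phosnet_stop(sprintf("%s: expected columns protein, replicate, t<minutes>...",
                         path), "phosnet_data_error")
  }
  tcols <- setdiff(names(df), c("protein", "replicate"))
  grid <- grid_from_columns(tcols, path)
  if (!is.null(expected_grid) &&
      !(length(grid) == length(expected_grid) && all(grid == expected_grid))) {
    phosnet_stop(
      sprintf("%s: time grid (%s) does not match the expected grid (%s)",
              path, paste(grid, collapse = ","),
              paste(expected_grid, collapse = ",")),
      "phosnet_data_error"
    )
  }
  out <- lapply(split(df, df$protein), function(d) {
    d <- d[order(d$replicate), , drop = FALSE]
    phospho_timeseries(d$protein[1], grid, as.matrix(d[tcols]))
  })
  out <- out[unique(df$protein)]
  structure(out, class = "phospho_dataset",
            header = attr(df, "header"))
}

#' Write/read per-protein significance scores
#'
#' One score type per file (first-point or previous-point p-values):
#' columns `protein` then one `t<minutes>` column per post-baseline time
#' point.
#'
#' @param scores Named list of [compute_significance()] results.
#' @param path File path.
#' @param type Which score vector to write.
#' @param header Optional comment lines.
#' @export
write_scores_tsv <- function(scores, path,
                             type = c("firstscores", "prevscores"),
                             header = NULL) {
  type <- match.arg(type)
  rows <- lapply(scores, function(s) {
    data.frame(protein = s$protein, t(s[[type]]), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  write_tsv_with_header(df, path, header)
}

#' @rdname write_scores_tsv
#' @return `read_scores_tsv`: named list with per-protein score vectors and
#'   the grid implied by the columns.
#' @export
read_scores_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  tcols <- setdiff(names(df), "protein")
  grid <- grid_from_columns(tcols, path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    stats::setNames(as.numeric(df[i, tcols]), tcols)
  })
  names(out) <- df$protein
  if (any(unlist(out) < 0 | unlist(out) > 1, na.rm = TRUE)) {
    phosnet_stop(sprintf("%s: p-values outside [0, 1]", path),
                 "phosnet_data_error")
  }
  structure(out, grid = grid, header = attr(df, "header"))
}

#' Write/read an interactome in SIF-like TSV form
#'
#' Columns `node1`, `interaction` (`pp` for undirected PPI, `ks` for a
#' directed kinase-substrate edge), `node2`, `confidence`, `sign`
#' (`+`/`-`/`?`; `?` for PPI edges and unsigned priors). Kinase flags are
#' implied by appearing as the source of a `ks` edge.
#'
#' @param net An [interactome()].
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_interactome_sif <- function(net, path, header = NULL) {
  pp <- data.frame(node1 = net$ppi$from, interaction = "pp",
                   node2 = net$ppi$to, confidence = net$ppi$confidence,
                   sign = "?", stringsAsFactors = FALSE)
  ks <- data.frame(node1 = net$ks$kinase, interaction = "ks",
                   node2 = net$ks$substrate, confidence = net$ks$confidence,
                   sign = ifelse(is.na(net$ks$sign), "?",
                                 ifelse(net$ks$sign > 0, "+", "-")),
                   stringsAsFactors = FALSE)
  df <- rbind(pp, ks)
  df <- df[order(df$interaction, df$node1, df$node2), , drop = FALSE]
  if (is.null(header)) header <- attr(net, "header")
  write_tsv_with_header(df, path, header)
}

#' @rdname write_interactome_sif
#' @param source Designated source node id (default `"SRC"` when present in
#'   the file, otherwise NULL).
#' @export
read_interactome_sif <- function(path, source = NULL) {
  df <- read_tsv_with_header(path)
  need <- c("node1", "interaction", "node2", "confidence", "sign")
  if (!all(need %in% names(df))) {
    phosnet_stop(sprintf("%s: expected columns %s", path,
                         paste(need, collapse = ", ")),
                 "phosnet_data_error")
  }
  bad <- which(!df$interaction %in% c("pp", "ks"))
  if (length(bad) > 0) {
    phosnet_stop(sprintf("%s: unknown interaction type '%s' on line %d", path,
                         df$interaction[bad[1]],
                         attr(df, "first_data_line") + bad[1] - 1L),
                 "phosnet_data_error")
  }
  key <- ifelse(df$interaction == "pp",
                paste(pmin(df$node1, df$node2), pmax(df$node1, df$node2), "pp"),
                paste(df$node1, df$node2, "ks"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    phosnet_stop(sprintf("%s: duplicate edge on line %d", path,
                         attr(df, "first_data_line") + dup[1] - 1L),
                 "phosnet_data_error")
  }
  pp <- df[df$interaction == "pp", , drop = FALSE]
  ks <- df[df$interaction == "ks", , drop = FALSE]
  ids <- unique(c(df$node1, df$node2, source))
  nodes <- data.frame(id = ids, is_kinase = ids %in% ks$node1,
                      stringsAsFactors = FALSE)
  if (is.null(source) && "SRC" %in% ids) source <- "SRC"
  net <- interactome(
    nodes,
    data.frame(from = pp$node1, to = pp$node2, confidence = pp$confidence,
               stringsAsFactors = FALSE),
    data.frame(kinase = ks$node1, substrate = ks$node2,
               sign = ifelse(ks$sign == "?", NA_integer_,
                             ifelse(ks$sign == "+", 1L, -1L)),
               confidence = ks$confidence, stringsAsFactors = FALSE),
    source = source
  )
  attr(net, "header") <- attr(df, "header")
  net
}

#' Write/read a subnetwork as a two-column undirected edge list
#'
#' Columns `node1`, `node2`. The designated source node is recorded in a
#' header comment (`source=<id>`), where the reader recovers it.
#'
#' @param sub A [subnetwork()].
#' @param path File path.
#' @param header Optional extra comment lines, written before the source
#'   line.
#' @export
write_subnetwork_tsv <- function(sub, path, header = NULL) {
  df <- data.frame(node1 = sub$edges$from, node2 = sub$edges$to,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, c(header, paste0("source=", sub$source)))
}

#' @rdname write_subnetwork_tsv
#' @export
read_subnetwork_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  hdr <- attr(df, "header")
  src_line <- grep("^source=", hdr, value = TRUE)
  if (length(src_line) == 0) {
    phosnet_stop(sprintf("%s: missing 'source=' header comment", path),
                 "phosnet_data_error")
  }
  key <- paste(pmin(df$node1, df$node2), pmax(df$node1, df$node2))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    phosnet_stop(sprintf("%s: duplicate edge on line %d", path,
                         attr(df, "first_data_line") + dup[1] - 1L),
                 "phosnet_data_error")
  }
  sub <- subnetwork(data.frame(from = df$node1, to = df$node2,
                               stringsAsFactors = FALSE),
                    sub("^source=", "", src_line[1]))
  attr(sub, "header") <- setdiff(hdr, src_line[1])
  sub
}

#' Write/read a partial model (directed signed priors)
#'
#' Columns `kinase`, `substrate`, `sign` (`+`/`-`/`?`).
#'
#' @param pm A [partial_model()].
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_partial_model_tsv <- function(pm, path, header = NULL) {
  df <- data.frame(kinase = pm$edges$from, substrate = pm$edges$to,
                   sign = ifelse(is.na(pm$edges$sign), "?",
                                 ifelse(pm$edges$sign > 0, "+", "-")),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}

#' @rdname write_partial_model_tsv
#' @export
read_partial_model_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  dup <- which(duplicated(paste(df$kinase, df$substrate)))
  if (length(dup) > 0) {
    phosnet_stop(sprintf("%s: duplicate directed edge on line %d", path,
                         attr(df, "first_data_line") + dup[1] - 1L),
                 "phosnet_data_error")
  }
  pm <- partial_model(data.frame(
    from = df$kinase, to = df$substrate,
    sign = ifelse(df$sign == "?", NA_integer_,
                  ifelse(df$sign == "+", 1L, -1L)),
    stringsAsFactors = FALSE
  ))
  attr(pm, "header") <- attr(df, "header")
  pm
}

#' Write/read a summary network
#'
#' Columns `source`, `target`, `directed` (always `TRUE` for emitted
#' edges), `sign` (`activation`/`inhibition`/`unknown`) and `n_paths`.
#'
#' @param net A `summary_network`.
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_summary_tsv <- function(net, path, header = NULL) {
  df <- data.frame(source = net$from, target = net$to, directed = TRUE,
                   sign = net$sign, n_paths = net$n_paths,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  need <- c("source", "target", "directed", "sign", "n_paths")
  if (!all(need %in% names(df))) {
    phosnet_stop(sprintf("%s: expected columns %s", path,
                         paste(need, collapse = ", ")),
                 "phosnet_data_error")
  }
  dup <- which(duplicated(paste(df$source, df$target)))
  if (length(dup) > 0) {
    phosnet_stop(sprintf("%s: duplicate directed edge on line %d", path,
                         attr(df, "first_data_line") + dup[1] - 1L),
                 "phosnet_data_error")
  }
  net <- summary_network(data.frame(from = df$source, to = df$target,
                                    sign = df$sign, n_paths = df$n_paths,
                                    stringsAsFactors = FALSE))
  attr(net, "header") <- attr(df, "header")
  net
}

#' Write/read a kinase-kinase network
#'
#' Columns `kinase1`, `kinase2`, `functionality` (`weakening`,
#' `strengthening`, `both`, `none`).
#'
#' @param net A `kinase_network`.
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_kinase_network_tsv <- function(net, path, header = NULL) {
  fun <- if ("functionality" %in% names(net$edges)) net$edges$functionality
         else rep("none", nrow(net$edges))
  df <- data.frame(kinase1 = net$edges$from, kinase2 = net$edges$to,
                   functionality = fun, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}

#' @rdname write_kinase_network_tsv
#' @export
read_kinase_network_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  dup <- which(duplicated(paste(df$kinase1, df$kinase2)))
  if (length(dup) > 0) {
    phosnet_stop(sprintf("%s: duplicate directed edge on line %d", path,
                         attr(df, "first_data_line") + dup[1] - 1L),
                 "phosnet_data_error")
  }
  edges <- data.frame(from = df$kinase1, to = df$kinase2,
                      functionality = df$functionality,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = unique(c(edges$from, edges$to)),
                 header = attr(df, "header")),
            class = "kinase_network")
}

#' Write/read a kinase-by-compound residual-activity matrix
#'
#' Wide TSV: first column `kinase`, one column per compound, residual
#' activity in percent.
#'
#' @param mat An `inhibition_matrix`.
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_inhibition_tsv <- function(mat, path, header = NULL) {
  df <- data.frame(kinase = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, header)
}

#' @rdname write_inhibition_tsv
#' @export
read_inhibition_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  m <- as.matrix(df[setdiff(names(df), "kinase")])
  rownames(m) <- df$kinase
  if (any(m < 0, na.rm = TRUE)) {
    phosnet_stop(sprintf("%s: negative residual activity", path),
                 "phosnet_data_error")
  }
  structure(m, class = c("inhibition_matrix", class(m)),
            header = attr(df, "header"))
}

#' Write/read a permeability screen
#'
#' Long TSV with columns `compound`, `replicate`, `auc`; the vehicle
#' control appears as compound `DMSO`.
#'
#' @param screen A `permeability_screen`.
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_screen_tsv <- function(screen, path, header = NULL) {
  write_tsv_with_header(screen$auc, path, header)
}

#' @rdname write_screen_tsv
#' @export
read_screen_tsv <- function(path, control = "DMSO") {
  df <- read_tsv_with_header(path)
  if (any(df$auc <= 0)) {
    phosnet_stop(sprintf("%s: AUC values must be positive", path),
                 "phosnet_data_error")
  }
  if (!control %in% df$compound) {
    phosnet_stop(sprintf("%s: control condition '%s' missing", path, control),
                 "phosnet_data_error")
  }
  structure(list(auc = df, control = control), class = "permeability_screen",
            header = attr(df, "header"))
}

#' Write/read a functional kinase model as JSON
#'
#' @param model A [treking_model()].
#' @param path File path.
#' @export
write_treking_json <- function(model, path) {
  func_df <- as.data.frame(model$functionality)
  rownames(func_df) <- NULL  # kinase order is carried by the kinases field
  obj <- list(
    kinases = model$kinases,
    time_grid = model$time_grid,
    functionality = func_df,
    intervals = lapply(model$intervals, function(iv) {
      as.data.frame(iv)
    }),
    clusters = as.list(model$clusters),
    background = model$background,
    cluster_networks = lapply(model$cluster_networks, identity),
    n_clusters = model$n_clusters
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_treking_json
#' @export
read_treking_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  func <- as.matrix(as.data.frame(obj$functionality,
                                  stringsAsFactors = FALSE))
  rownames(func) <- obj$kinases
  intervals <- lapply(obj$intervals, function(iv) {
    if (is.null(iv$start) || length(iv$start) == 0) {
      return(matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    matrix(c(iv$start, iv$end), ncol = 2,
           dimnames = list(NULL, c("start", "end")))
  })
  cn <- lapply(obj$cluster_networks, function(e) {
    as.data.frame(e, stringsAsFactors = FALSE)
  })
  treking_model(obj$kinases, obj$time_grid, func, intervals,
                unlist(obj$clusters),
                as.data.frame(obj$background, stringsAsFactors = FALSE),
                cn, obj$n_clusters)
}
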