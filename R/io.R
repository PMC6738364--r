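#' Read a probes x samples expression matrix
#'
#' Expects delimited text with a header row of sample ids and probe ids in
#' the first column.  Values must be numeric (normalized, log2-scale
#' expression).  Probes with any missing value are dropped with a warning;
#' duplicate probe ids and fewer than 5 samples are errors.  Orientation is
#' never auto-detected: the file must be probes x samples.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @return Numeric matrix, probes x samples.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) stop("expected probe ids plus at least one sample column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate probe ids in ", path)
  body <- df[, -1L, drop = FALSE]
  num <- vapply(body, is.numeric, TRUE)
  if (!all(num))
    stop("non-numeric expression values in column(s): ",
         paste(names(body)[!num], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  .check_expression_matrix(m)
}

#' @rdname read_expression_matrix
#' @param data Numeric matrix, probes x samples.
#' @export
write_expression_matrix <- function(data, path, sep = "\t") {
  df <- data.frame(probe_id = rownames(data), data, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- role tables -----------------------------------------------------------

.check_role_table <- function(rt) {
  stopifnot(is.data.frame(rt),
            all(c("probe_id", "source_capable", "target_capable") %in% names(rt)))
  if (anyDuplicated(rt$probe_id)) stop("duplicate probe ids in role table")
  if (any(!rt$source_capable & !rt$target_capable))
    stop("every probe must be source- and/or target-capable")
  invisible(rt)
}

.capable <- function(rt, what) {
  rt$probe_id[rt[[paste0(what, "_capable")]]]
}

#' Build or read a source/target role table
#'
#' A role table designates which probes may act as regulation sources
#' (e.g. annotated G-box binders) and which may be targets (e.g. probes with
#' a G-box in their promoter).  Probes may hold both roles.
#'
#' @param probe_id Character vector of probe ids.
#' @param source_capable,target_capable Logical vectors.
#' @return Validated role-table data frame.
#' @export
role_table <- function(probe_id, source_capable, target_capable) {
  .check_role_table(data.frame(probe_id = as.character(probe_id),
                               source_capable = as.logical(source_capable),
                               target_capable = as.logical(target_capable),
                               stringsAsFactors = FALSE))
}

#' @rdname role_table
#' @param path File path of a tab-delimited role table with the three
#'   columns above.
#' @export
read_role_table <- function(path) {
  .check_role_table(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' @rdname role_table
#' @param rt Role-table data frame.
#' @export
write_role_table <- function(rt, path) {
  utils::write.table(.check_role_table(rt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- promoter motif scanning -----------------------------------------------

#' Scan promoter sequences for a cis-element motif
#'
#' Marks sequences containing the motif on either strand as target-capable.
#' The default motif is the canonical G-box `CACGTG`, which is its own
#' reverse complement, so a single-strand scan suffices; for non-palindromic
#' IUPAC motifs both strands are scanned.
#'
#' @param promoters A `Biostrings::DNAStringSet`, or the path of a FASTA
#'   file of promoter sequences whose names are probe ids.
#' @param motif IUPAC motif string (default `"CACGTG"`).
#' @return Data frame: `probe_id`, `target_capable`, `n_hits`.
#' @export
scan_gbox <- function(promoters, motif = "CACGTG") {
  if (is.character(promoters) && length(promoters) == 1L)
    promoters <- Biostrings::readDNAStringSet(promoters)
  if (!methods::is(promoters, "DNAStringSet"))
    stop("promoters must be a DNAStringSet or FASTA path")
  if (any(Biostrings::width(promoters) == 0L)) stop("empty promoter sequence")
  motif <- Biostrings::DNAString(motif)
  fwd <- Biostrings::vcountPattern(motif, promoters, fixed = FALSE)
  rc <- Biostrings::reverseComplement(motif)
  hits <- if (as.character(rc) == as.character(motif)) fwd
          else fwd + Biostrings::vcountPattern(rc, promoters, fixed = FALSE)
  data.frame(probe_id = names(promoters),
             target_capable = hits > 0L,
             n_hits = as.integer(hits),
             stringsAsFactors = FALSE)
}

# ---- network spec files ----------------------------------------------------

#' Read / write a simulator network specification
#'
#' Plain-text declarative format, one directive per line:
#' `root <id>`, `independent <id>`, or `edge <source> <target> <b>`.
#' Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return For the reader, a [network_spec()].
#' @export
read_network_spec <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  roots <- character(); indep <- character()
  es <- list()
  for (tk in toks) {
    switch(tk[1L],
      root = { roots <- c(roots, tk[2L]) },
      independent = { indep <- c(indep, tk[2L]) },
      edge = {
        if (length(tk) != 4L) stop("malformed edge line: ", paste(tk, collapse = " "))
        es[[length(es) + 1L]] <- data.frame(source = tk[2L], target = tk[3L],
                                            b = as.numeric(tk[4L]),
                                            stringsAsFactors = FALSE)
      },
      stop("unknown directive: ", tk[1L]))
  }
  if (!length(es)) stop("no edges in network spec file")
  network_spec(do.call(rbind, es), roots = roots, independent = indep)
}

#' @rdname read_network_spec
#' @param spec A [network_spec()].
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  lines <- c(paste("root", spec$roots),
             if (length(spec$independent)) paste("independent", spec$independent),
             sprintf("edge %s %s %g", spec$edges$source, spec$edges$target,
                     spec$edges$b))
  writeLines(lines, path)
  invisible(path)
}

# ---- network writers -------------------------------------------------------

#' Write and read directed networks
#'
#' `write_edge_list()` emits a tab-delimited table with columns `source`,
#' `target`, `step`, `statistic_kind`, `value`, `p_value`, `forward_p`,
#' `reverse_p`; `read_edge_list()` parses it back into a `cid_network`.
#' `write_sif()` emits Cytoscape SIF (`source  regulates  target`) and
#' `write_graphml()` GraphML via igraph.  `write_degree_table()` writes the
#' per-node degree table, with `NA` rows for probes in `universe` that ended
#' up isolated.
#'
#' @param net A `cid_network`.
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "cid_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("source", "target", "step", "statistic_kind", "value",
            "p_value", "forward_p", "reverse_p")
  if (!all(need %in% names(edges)))
    stop("edge list is missing column(s): ",
         paste(setdiff(need, names(edges)), collapse = ", "))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  .new_network(unique(c(edges$source, edges$target)), edges[, need],
               "assembled")
}

#' @rdname write_edge_list
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "cid_network"))
  writeLines(paste(net$edges$source, "regulates", net$edges$target,
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "cid_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_list
#' @param universe Optional character vector of all probe ids considered;
#'   isolated ones get `NA` degrees, mirroring supplementary degree tables.
#' @export
write_degree_table <- function(net, path, universe = NULL) {
  deg <- network_summaries(net)$degrees
  if (!is.null(universe)) {
    iso <- setdiff(universe, deg$probe_id)
    if (length(iso))
      deg <- rbind(deg, data.frame(probe_id = iso, in.degree = NA,
                                   out.degree = NA, total.degree = NA))
  }
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
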