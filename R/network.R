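#' @title Stepwise construction of a directed gene regulatory network
#' @description
#' The construction has three steps: (1) identification of a significantly
#' associated seed pair by CID, (2) regulation-path elongation by pCID, and
#' (3) assembly of all sub-networks.  At every step the "most significant"
#' statistic wins: smallest permutation p-value first, ties broken by larger
#' statistic value, remaining ties by lexicographic probe id.  Direction is
#' assigned to the more significant of the two orientations of the winning
#' pair, using the same ordering.
#' @name network_builder
NULL

# ---- statistic engines -----------------------------------------------------

# An engine maps (response, predictor, conditioning, step) to a list with
# $value and $p_value.  The default engine runs permutation tests on an
# expression matrix; a table engine replays precomputed statistics, which is
# how printed CID/pCID tables can be pushed through the selection logic.

.perm_engine <- function(data, plan, cfg) {
  data <- .check_expression_matrix(data)
  function(response, predictor, conditioning, step) {
    pcid_test(data, response, predictor, conditioning, plan, cfg, step)
  }
}

# df needs columns response, predictor, conditioning (comma-joined, order
# ignored), value, p_value.
.table_engine <- function(df) {
  norm_cond <- function(s) {
    vapply(s, function(z) {
      parts <- trimws(strsplit(as.character(z), ",")[[1]])
      paste(sort(parts[nzchar(parts)]), collapse = ",")
    }, "", USE.NAMES = FALSE)
  }
  df$.key <- paste(df$response, df$predictor, norm_cond(df$conditioning), sep = "|")
  function(response, predictor, conditioning, step) {
    key <- paste(response, predictor,
                 paste(sort(conditioning), collapse = ","), sep = "|")
    i <- match(key, df$.key)
    if (is.na(i)) stop("statistic not present in table: ", key)
    list(value = df$value[i], p_value = df$p_value[i])
  }
}

# TRUE if statistic a is strictly more significant than b; NA on a full tie.
.more_significant <- function(a, b) {
  if (a$p_value != b$p_value) return(a$p_value < b$p_value)
  if (a$value != b$value) return(a$value > b$value)
  NA
}

.edge_row <- function(source, target, step, kind, value, p_value,
                      forward_p, reverse_p) {
  data.frame(source = source, target = target, step = step,
             statistic_kind = kind, value = value, p_value = p_value,
             forward_p = forward_p, reverse_p = reverse_p,
             stringsAsFactors = FALSE)
}

# Resolve the direction of a newly accepted association between `resp`
# (the winning response S) and `pred` (the new node T).  The edge points
# from the response of the more significant orientation to the other node;
# on a complete tie the lexicographically smaller id is the source.
.directed_edge <- function(resp, pred, fwd, rev, step, kind) {
  ms <- .more_significant(fwd, rev)
  src_is_resp <- if (is.na(ms)) resp < pred else ms
  if (src_is_resp) {
    .edge_row(resp, pred, step, kind, fwd$value, fwd$p_value,
              fwd$p_value, rev$p_value)
  } else {
    .edge_row(pred, resp, step, kind, rev$value, rev$p_value,
              fwd$p_value, rev$p_value)
  }
}

# ---- step operations -------------------------------------------------------

#' Select the first target of a regulation path
#'
#' Computes `CID(T0|Ti)` for every candidate target, picks the most
#' significant one, and orients the seed edge by comparing the two
#' orientations' p-values.  Returns `NULL` ("discarded") when no candidate
#' reaches significance.
#'
#' @param T0 Source probe id.
#' @param candidates Candidate target probe ids (must not contain `T0`).
#' @param data Probes x samples expression matrix (ignored when `engine` is
#'   supplied).
#' @param plan A [permutation_plan()].
#' @param alpha Significance level (default 0.05).
#' @param cfg A [kernel_config()].
#' @param engine Optional statistic engine (internal use / replay).
#' @return A one-row edge data frame with an `all_results` attribute holding
#'   every candidate's CID and p-value, or `NULL` if all are insignificant.
#' @export
select_first_target <- function(T0, candidates, data = NULL,
                                plan = permutation_plan(), alpha = 0.05,
                                cfg = kernel_config(), engine = NULL) {
  if (!length(candidates)) stop("empty candidate list")
  if (T0 %in% candidates) stop("T0 must not be among the candidates")
  if (is.null(engine)) engine <- .perm_engine(data, plan, cfg)
  res <- lapply(candidates, function(ti) engine(T0, ti, character(), 0L))
  tab <- data.frame(candidate = candidates,
                    value = vapply(res, `[[`, 0, "value"),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  ord <- order(tab$p_value, -tab$value, tab$candidate)
  best <- tab[ord[1L], ]
  if (best$p_value > alpha) return(NULL)
  fwd <- list(value = best$value, p_value = best$p_value)
  rev <- engine(best$candidate, T0, character(), 0L)
  edge <- .directed_edge(T0, best$candidate, fwd, rev, 0L, "CID")
  attr(edge, "all_results") <- tab
  edge
}

#' One pCID elongation step
#'
#' For every eligible path member `S` and every remaining candidate `Tj`,
#' computes `pCID(S|Tj; current \ S)`; if the most significant value is
#' significant at `alpha`, the corresponding pair is connected (direction by
#' comparing the two orientations under the same conditioning set),
#' otherwise the path stops.
#'
#' @param current Ordered probe ids already on the path.
#' @param candidates Remaining candidate probe ids (disjoint from
#'   `current`).
#' @param allowed_sources Subset of `current` allowed to act as `S`
#'   (everything in `current` in unsupervised mode; the designated source
#'   list in supervised mode).
#' @param step Elongation step index (k >= 1).
#' @inheritParams select_first_target
#' @return A one-row edge data frame, or `NULL` ("stop").
#' @export
elongation_step <- function(current, candidates, allowed_sources = current,
                            data = NULL, plan = permutation_plan(),
                            alpha = 0.05, cfg = kernel_config(),
                            step = 1L, engine = NULL) {
  if (!length(candidates)) return(NULL)
  if (length(intersect(current, candidates)))
    stop("candidates must be disjoint from the current path")
  srcs <- intersect(current, allowed_sources)
  if (!length(srcs)) return(NULL)
  if (is.null(engine)) engine <- .perm_engine(data, plan, cfg)

  grid <- expand.grid(S = srcs, Tj = candidates,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cond <- setdiff(current, grid$S[i])
    engine(grid$S[i], grid$Tj[i], cond, step)
  })
  grid$value <- vapply(res, `[[`, 0, "value")
  grid$p_value <- vapply(res, `[[`, 0, "p_value")
  ord <- order(grid$p_value, -grid$value, grid$S, grid$Tj)
  best <- grid[ord[1L], ]
  if (best$p_value > alpha) return(NULL)
  cond <- setdiff(current, best$S)
  fwd <- list(value = best$value, p_value = best$p_value)
  rev <- engine(best$Tj, best$S, cond, step)
  .directed_edge(best$S, best$Tj, fwd, rev, step, "pCID")
}

# ---- sub-network construction and assembly ---------------------------------

.new_network <- function(nodes, edges, origin, discarded = FALSE) {
  structure(list(nodes = nodes, edges = edges, origin = origin,
                 discarded = discarded),
            class = "cid_network")
}

.empty_edges <- function() {
  .edge_row(character(), character(), integer(), character(),
            numeric(), numeric(), numeric(), numeric())
}

#' @export
print.cid_network <- function(x, ...) {
  cat(sprintf("cid_network (origin: %s): %d node(s), %d edge(s)%s\n",
              x$origin, length(x$nodes), nrow(x$edges),
              if (x$discarded) " [discarded]" else ""))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$source, " -> ", x$edges$target,
               sprintf("  (step %d, %s = %.4f, p = %.4f)", x$edges$step,
                       x$edges$statistic_kind, x$edges$value,
                       x$edges$p_value), collapse = "\n"), "\n")
  invisible(x)
}

#' Build one regulation sub-network from a source gene
#'
#' Runs [select_first_target()] and then repeated [elongation_step()]s until
#' all remaining pCID values are insignificant, the candidate pool is empty,
#' or (with `stop_on_target_only`) a target-only gene is reached.
#'
#' @param T0 Seed source probe id.
#' @param data Probes x samples expression matrix.
#' @param plan A [permutation_plan()].
#' @param alpha Significance level.
#' @param cfg A [kernel_config()].
#' @param role_table Optional data frame (`probe_id`, `source_capable`,
#'   `target_capable`); restricts candidates to target-capable probes and,
#'   in unsupervised mode, path members acting as `S` to source-capable
#'   ones.
#' @param mode `"unsupervised"` (any eligible path member may act as source)
#'   or `"supervised"` (only `sources` may).
#' @param sources Designated source probe ids for supervised mode.
#' @param stop_on_target_only Halt elongation right after adding a node that
#'   is target-capable but not source-capable.
#' @param prefilter Drop candidates whose seed-step CID p-value exceeds
#'   `alpha` from all later steps (off by default).
#' @param max_steps Safety cap on elongation steps (default: number of
#'   candidates).
#' @param engine Optional statistic engine (replay/testing).
#' @param candidates Optional explicit candidate pool (default: every other
#'   probe, filtered by `role_table` if given).
#' @return A `cid_network`; `$discarded` is `TRUE` when the seed produced no
#'   significant first edge.
#' @export
build_subnetwork <- function(T0, data = NULL, plan = permutation_plan(),
                             alpha = 0.05, cfg = kernel_config(),
                             role_table = NULL,
                             mode = c("unsupervised", "supervised"),
                             sources = NULL, stop_on_target_only = FALSE,
                             prefilter = FALSE, max_steps = NULL,
                             engine = NULL, candidates = NULL) {
  mode <- match.arg(mode)
  if (mode == "supervised" && is.null(sources))
    stop("supervised mode requires a source list")
  if (!is.null(role_table)) .check_role_table(role_table)

  if (is.null(candidates)) {
    if (!is.null(data)) candidates <- setdiff(rownames(data), T0)
    else stop("either data or candidates must be supplied")
    if (!is.null(role_table))
      candidates <- intersect(candidates, .capable(role_table, "target"))
  }
  if (!is.null(role_table) && !T0 %in% .capable(role_table, "source"))
    stop(sprintf("seed probe %s is not source-capable", T0))
  if (is.null(engine)) engine <- .perm_engine(data, plan, cfg)
  if (is.null(max_steps)) max_steps <- length(candidates)

  seed_edge <- select_first_target(T0, candidates, plan = plan, alpha = alpha,
                                   cfg = cfg, engine = engine)
  if (is.null(seed_edge))
    return(.new_network(T0, .empty_edges(), T0, discarded = TRUE))

  if (prefilter) {
    tab <- attr(seed_edge, "all_results")
    candidates <- tab$candidate[tab$p_value <= alpha]
  }
  first <- setdiff(c(seed_edge$source, seed_edge$target), T0)
  current <- c(T0, first)
  candidates <- setdiff(candidates, current)
  edges <- seed_edge
  attr(edges, "all_results") <- NULL

  halt <- stop_on_target_only && .target_only(role_table, first)
  step <- 1L
  while (!halt && length(candidates) && step <= max_steps) {
    allowed <- if (mode == "supervised") sources
               else if (!is.null(role_table))
                 intersect(current, .capable(role_table, "source"))
               else current
    e <- elongation_step(current, candidates, allowed, plan = plan,
                         alpha = alpha, cfg = cfg, step = step,
                         engine = engine)
    if (is.null(e)) break
    newnode <- setdiff(c(e$source, e$target), current)
    edges <- rbind(edges, e)
    current <- c(current, newnode)
    candidates <- setdiff(candidates, newnode)
    halt <- stop_on_target_only && .target_only(role_table, newnode)
    step <- step + 1L
  }
  .new_network(current, edges, T0)
}

.target_only <- function(role_table, id) {
  if (is.null(role_table)) return(FALSE)
  i <- match(id, role_table$probe_id)
  !is.na(i) && role_table$target_capable[i] && !role_table$source_capable[i]
}

#' Assemble sub-networks into one directed network
#'
#' Takes the union of nodes and edges over all (non-discarded) sub-networks.
#' Duplicate `(source, target)` edges are merged keeping the smallest
#' p-value; pairs connected in both directions are kept as two edges and
#' reported with a message.  Probes without any edge are excluded.
#'
#' @param subnetworks List of `cid_network` objects.
#' @return A `cid_network` with `origin = "assembled"`.
#' @export
assemble_networks <- function(subnetworks) {
  subnetworks <- Filter(function(n) !n$discarded && nrow(n$edges) > 0,
                        subnetworks)
  if (!length(subnetworks))
    return(.new_network(character(), .empty_edges(), "assembled"))
  edges <- do.call(rbind, lapply(subnetworks, `[[`, "edges"))
  edges <- edges[order(edges$p_value, -edges$value), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
  und <- apply(edges[, c("source", "target")], 1L,
               function(r) paste(sort(r), collapse = "~"))
  both <- und[duplicated(und)]
  if (length(both))
    message("conflicting directions retained for pair(s): ",
            paste(unique(both), collapse = ", "))
  rownames(edges) <- NULL
  nodes <- unique(c(edges$source, edges$target))
  .new_network(nodes, edges, "assembled")
}

#' Degree table and power-law diagnostic
#'
#' Per-node in/out/total degrees, the average total degree `2|E|/|V|`, and a
#' least-squares slope of log(frequency) against log(total degree) as a
#' scale-free (power-law) diagnostic; a clearly negative slope indicates
#' that most nodes have few connections while a few hubs dominate.
#'
#' @param net A `cid_network` with at least one edge.
#' @return List with `degrees` (data frame: `probe_id`, `in.degree`,
#'   `out.degree`, `total.degree`), `average_degree`, `power_law` (data
#'   frame of degree/frequency) and `power_law_slope`.
#' @export
network_summaries <- function(net) {
  stopifnot(inherits(net, "cid_network"))
  if (!nrow(net$edges)) stop("empty network")
  nodes <- unique(c(net$edges$source, net$edges$target))
  indeg <- vapply(nodes, function(n) sum(net$edges$target == n), 0L)
  outdeg <- vapply(nodes, function(n) sum(net$edges$source == n), 0L)
  deg <- data.frame(probe_id = nodes, in.degree = indeg, out.degree = outdeg,
                    total.degree = indeg + outdeg, stringsAsFactors = FALSE,
                    row.names = NULL)
  freq <- as.data.frame(table(deg$total.degree), stringsAsFactors = FALSE)
  names(freq) <- c("total.degree", "frequency")
  freq$total.degree <- as.numeric(freq$total.degree)
  slope <- if (nrow(freq) >= 2L) {
    unname(stats::coef(stats::lm(log(frequency) ~ log(total.degree),
                                 data = freq))[2L])
  } else NA_real_
  list(degrees = deg,
       average_degree = 2 * nrow(net$edges) / length(nodes),
       power_law = freq,
       power_law_slope = slope)
}
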