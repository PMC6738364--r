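#' Normal-mixture network specification
#'
#' Describes a pseudo gene network whose expression values are generated
#' from a normal mixture: root and independent nodes are drawn from
#' `Normal(root_mean, root_sd)`; each target node either escapes regulation
#' (probability `1 - b`, drawn from `Normal(off_mean, off_sd_unregulated)`)
#' or, with probability `b` (the binding efficiency), follows its direct
#' source `s`: `Normal(s, regulated_sd)` when `s > 0`, else
#' `Normal(off_mean, regulated_sd)` (the source is not expressed).  All
#' normal parameters are (mean, sd).
#'
#' Each target must have exactly one direct source and the edge graph must
#' be acyclic.
#'
#' @param edges Data frame with columns `source`, `target`, `b`
#'   (binding efficiency in (0, 1]).
#' @param roots Root node ids (sources that are not themselves targets).
#' @param independent Ids of nodes generated independently of everything
#'   (negative controls).
#' @param root_mean,root_sd Parameters of the root/independent distribution.
#' @param regulated_sd Sd around the source value on the regulated branch.
#' @param off_mean,off_sd_unregulated Parameters of the unregulated branch.
#' @return An object of class `network_spec`.
#' @seealso [fig_network_spec()] for the six-node benchmark topology.
#' @export
network_spec <- function(edges, roots = NULL, independent = character(),
                         root_mean = 1, root_sd = 1, regulated_sd = 0.25,
                         off_mean = -1, off_sd_unregulated = 1) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "b") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (any(edges$b <= 0 | edges$b > 1)) stop("binding efficiency b must be in (0, 1]")
  if (anyDuplicated(edges$target))
    stop("each target must have exactly one direct source")
  inferred_roots <- setdiff(edges$source, edges$target)
  roots <- if (is.null(roots)) inferred_roots else as.character(roots)
  if (!all(inferred_roots %in% roots))
    stop("every non-target source must be listed as a root")
  nodes <- unique(c(roots, edges$source, edges$target, independent))
  order <- .topo_order(nodes, edges)   # errors on cycles
  structure(list(nodes = nodes, roots = roots,
                 independent = as.character(independent), edges = edges,
                 root_mean = root_mean, root_sd = root_sd,
                 regulated_sd = regulated_sd, off_mean = off_mean,
                 off_sd_unregulated = off_sd_unregulated,
                 topo_order = order),
            class = "network_spec")
}

.topo_order <- function(nodes, edges) {
  indeg <- vapply(nodes, function(n) sum(edges$target == n), 0L)
  names(indeg) <- nodes
  out <- character()
  queue <- nodes[indeg == 0L]
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    out <- c(out, n)
    for (ch in edges$target[edges$source == n]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(nodes)) stop("network specification contains a cycle")
  out
}

#' Six-node benchmark network
#'
#' The standard validation topology: root A11 regulates A21 (b = 0.9) and
#' A22 (b = 0.7); A21 regulates A31 (b = 0.9) and A32 (b = 0.8); B is an
#' independent negative control.
#'
#' @return A `network_spec`.
#' @export
fig_network_spec <- function() {
  network_spec(
    edges = data.frame(source = c("A11", "A11", "A21", "A21"),
                       target = c("A21", "A22", "A31", "A32"),
                       b = c(0.9, 0.7, 0.9, 0.8),
                       stringsAsFactors = FALSE),
    roots = "A11", independent = "B")
}

#' Probability that a normally distributed source is expressed
#'
#' `P(S > 0) = 1 - Phi(-mean/sd)` for `S ~ Normal(mean, sd)`; with the
#' default root parameters (1, 1) this is `Phi(1) = 0.8413`.
#'
#' @param mean,sd Normal parameters (sd > 0).
#' @return Probability in (0, 1).
#' @export
analytic_root_positive_prob <- function(mean, sd) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive")
  1 - stats::pnorm(-mean / sd)
}

#' Simulate one expression matrix from a network specification
#'
#' Targets are generated in topological order.  Per sample and per target an
#' independent Bernoulli(b) draw decides whether regulation takes place; see
#' [network_spec()] for the branch distributions.
#'
#' @param spec A [network_spec()].
#' @param N Number of samples (>= 2).
#' @param seed Integer seed.
#' @return Numeric matrix, nodes x samples (sample ids `S1..SN`).
#' @export
simulate_dataset <- function(spec, N, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (N < 2L) stop("N must be at least 2")
  .with_seed(seed, {
    vals <- matrix(NA_real_, length(spec$nodes), N,
                   dimnames = list(spec$nodes, paste0("S", seq_len(N))))
    for (n in c(spec$roots, spec$independent))
      vals[n, ] <- stats::rnorm(N, spec$root_mean, spec$root_sd)
    for (n in spec$topo_order) {
      i <- match(n, spec$edges$target)
      if (is.na(i)) next
      s <- vals[spec$edges$source[i], ]
      b <- spec$edges$b[i]
      regulated <- stats::runif(N) < b
      x <- stats::rnorm(N, spec$off_mean, spec$off_sd_unregulated)
      on <- regulated & s > 0
      off <- regulated & s <= 0
      x[on] <- stats::rnorm(sum(on), s[on], spec$regulated_sd)
      x[off] <- stats::rnorm(sum(off), spec$off_mean, spec$regulated_sd)
      vals[n, ] <- x
    }
    vals
  })
}

#' Statistic panel summarized over simulation replicates
#'
#' The full panel of CID/pCID statistics tracked in the simulation study:
#' every CID from A11 and from B plus the pCID ladder along the elongation
#' path, 34 statistics in total.
#'
#' @return List of statistic specifications (see [parse_stat_label()]).
#' @export
benchmark_stat_panel <- function() {
  labels <- c(
    "CID(A11|A21)", "CID(A11|A22)", "CID(A11|A31)", "CID(A11|A32)",
    "CID(A11|B)", "CID(A21|A11)",
    "pCID(A11|A22; A21)", "pCID(A11|A31; A21)", "pCID(A11|A32; A21)",
    "pCID(A11|B; A21)", "pCID(A21|A22; A11)", "pCID(A22|A11; A21)",
    "pCID(A21|A31; A11, A22)", "pCID(A21|A32; A11, A22)",
    "pCID(A21|B; A11, A22)", "pCID(A11|A31; A21, A22)",
    "pCID(A22|A31; A11, A21)", "pCID(A31|A21; A11, A22)",
    "pCID(A21|A32; A11, A22, A31)", "pCID(A21|B; A11, A22, A31)",
    "pCID(A11|A32; A21, A22, A31)", "pCID(A22|A32; A11, A21, A31)",
    "pCID(A31|A32; A11, A21, A22)", "pCID(A32|A21; A11, A22, A31)",
    "pCID(A11|B; A21, A22, A31, A32)", "pCID(A21|B; A11, A22, A31, A32)",
    "pCID(A22|B; A11, A21, A31, A32)", "pCID(A31|B; A11, A21, A22, A32)",
    "pCID(A32|B; A11, A21, A22, A31)",
    "CID(B|A11)", "CID(B|A21)", "CID(B|A22)", "CID(B|A31)", "CID(B|A32)")
  specs <- lapply(labels, parse_stat_label)
  names(specs) <- labels
  specs
}

#' Replicate simulation experiment
#'
#' Simulates the network `n_reps` times, reconstructs a network from each
#' designated source with [build_subnetwork()], assembles the results, and
#' tallies edge detection, direction correctness, exact recovery of the
#' generating topology (undirected edge-set equality) and inclusion of the
#' independent negative-control node(s).  Optionally tracks a panel of
#' CID/pCID statistics per replicate.
#'
#' @param spec A [network_spec()].
#' @param N Samples per replicate.
#' @param n_reps Number of replicates.
#' @param plan A [permutation_plan()]; its seed is re-derived per replicate.
#' @param alpha Significance level for network construction.
#' @param cfg A [kernel_config()].
#' @param sources Seed sources to build from (default: roots plus
#'   independent nodes).
#' @param stat_specs Optional statistic panel (list from
#'   [parse_stat_label()] / [benchmark_stat_panel()]) evaluated on every
#'   replicate.
#' @param stat_p Whether to attach permutation p-values to the tracked panel
#'   (slower); medians/IQRs need only the values.
#' @param seed Master seed for the experiment.
#' @return A `simulation_summary` list: `edge_detection` (per true edge:
#'   detected / correct / incorrect direction counts), `exact_recovery`,
#'   `negative_control_inclusion`, `negative_source_built`, `n_reps`, `N`,
#'   and `stats` (per-panel medians, IQRs and significant proportions).
#' @export
replicate_experiment <- function(spec, N, n_reps, plan = permutation_plan(),
                                 alpha = 0.05, cfg = kernel_config(),
                                 sources = NULL, stat_specs = NULL,
                                 stat_p = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), n_reps >= 1L)
  if (is.null(sources)) sources <- c(spec$roots, spec$independent)
  true_und <- sort(paste(pmin(spec$edges$source, spec$edges$target),
                         pmax(spec$edges$source, spec$edges$target),
                         sep = "~"))
  ed <- data.frame(source = spec$edges$source, target = spec$edges$target,
                   detected = 0L, correct = 0L, incorrect = 0L,
                   stringsAsFactors = FALSE)
  exact <- 0L; neg_incl <- 0L; neg_built <- 0L
  nstat <- length(stat_specs)
  stat_vals <- if (nstat) matrix(NA_real_, n_reps, nstat,
                                 dimnames = list(NULL, names(stat_specs)))
  stat_sig <- if (nstat && stat_p) stat_vals

  for (r in seq_len(n_reps)) {
    rseed <- .substream_seed(seed, paste0("rep", r))
    dat <- simulate_dataset(spec, N, rseed)
    plan_r <- plan
    plan_r$seed <- .substream_seed(rseed, "tests")
    nets <- lapply(sources, function(s)
      build_subnetwork(s, dat, plan_r, alpha, cfg))
    net <- assemble_networks(nets)
    # recovery is judged on reconstructions rooted at genuine sources; the
    # false networks grown from negative-control seeds are tallied separately
    main <- assemble_networks(nets[!(sources %in% spec$independent)])

    if (nrow(net$edges)) {
      und <- paste(pmin(net$edges$source, net$edges$target),
                   pmax(net$edges$source, net$edges$target), sep = "~")
      for (i in seq_len(nrow(ed))) {
        u <- paste(min(ed$source[i], ed$target[i]),
                   max(ed$source[i], ed$target[i]), sep = "~")
        if (u %in% und) ed$detected[i] <- ed$detected[i] + 1L
        if (any(net$edges$source == ed$source[i] &
                net$edges$target == ed$target[i]))
          ed$correct[i] <- ed$correct[i] + 1L
        if (any(net$edges$source == ed$target[i] &
                net$edges$target == ed$source[i]))
          ed$incorrect[i] <- ed$incorrect[i] + 1L
      }
      if (any(spec$independent %in% net$nodes)) neg_incl <- neg_incl + 1L
    }
    if (nrow(main$edges)) {
      mund <- paste(pmin(main$edges$source, main$edges$target),
                    pmax(main$edges$source, main$edges$target), sep = "~")
      if (identical(sort(unique(mund)), true_und)) exact <- exact + 1L
    }
    for (s in intersect(spec$independent, sources)) {
      i <- match(s, sources)
      if (!nets[[i]]$discarded) neg_built <- neg_built + 1L
    }
    if (nstat) {
      for (j in seq_len(nstat)) {
        sp <- stat_specs[[j]]
        if (stat_p) {
          res <- pcid_test(dat, sp$response, sp$predictor, sp$conditioning,
                           plan_r, cfg)
          stat_vals[r, j] <- res$value
          stat_sig[r, j] <- res$p_value
        } else {
          stat_vals[r, j] <- if (length(sp$conditioning))
            pcid(sp$response, sp$predictor, sp$conditioning, cfg, dat)$value
          else cid(sp$response, sp$predictor, cfg, dat)$value
        }
      }
    }
  }
  stats <- NULL
  if (nstat) {
    stats <- data.frame(
      statistic = names(stat_specs),
      median = apply(stat_vals, 2, stats::median),
      iqr = apply(stat_vals, 2, stats::IQR),
      sig_prop = if (stat_p) colMeans(stat_sig <= alpha) else NA_real_,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(edge_detection = ed, exact_recovery = exact,
                 negative_control_inclusion = neg_incl,
                 negative_source_built = neg_built,
                 n_reps = n_reps, N = N, alpha = alpha, stats = stats,
                 stat_values = if (nstat) stat_vals),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("simulation_summary: %d replicate(s) at N = %d\n", x$n_reps, x$N))
  cat(sprintf("  exact recovery: %d/%d\n", x$exact_recovery, x$n_reps))
  cat(sprintf("  negative-control inclusion: %d/%d\n",
              x$negative_control_inclusion, x$n_reps))
  print(x$edge_detection)
  invisible(x)
}
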