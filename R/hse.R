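sample_counts <- function(counts, smp, universe) {
  x <- counts[counts$sample == smp, c("gene_id", "n_count", "i_count")]
  idx <- match(universe, x$gene_id)
  data.frame(gene_id = universe,
             n_count = ifelse(is.na(idx), 0L, x$n_count[idx]),
             i_count = ifelse(is.na(idx), 0L, x$i_count[idx]),
             stringsAsFactors = FALSE)
}

#' Fit the homoeolog-specific expression analysis
#'
#' The central entry point: takes a long table of per-gene allele counts
#' (one row per gene and sample) and runs the full analysis over the
#' testable gene universe — per-sample bias calls (exact binomial test
#' against 1:1 under FDR), seven-type cis/trans regulatory-divergence
#' classification per hybrid, convergent/divergent/conserved regulation
#' groups per hybrid and tetraploid, nine bias-inheritance categories, and
#' the direct hybrid-vs-tetraploid comparison isolating the effect of
#' genome doubling.
#'
#' @param counts data.frame with columns `gene_id`, `sample`, `n_count`
#'   (reads supporting the Nipponbare homoeolog), `i_count` (93-11
#'   homoeolog), e.g. from [count_gene_alleles()] or
#'   [simulate_gene_counts()].
#' @param parent_mix sample label of the in silico hybrid (the 1:1
#'   parental mix serving as the parental reference P).
#' @param hybrids labels of the true F1 hybrid samples (at least one must
#'   be present).
#' @param tetraploids labels of tetraploid samples; labels absent from
#'   `counts` are silently dropped.
#' @param wgd_pairs named character vector pairing each hybrid with its
#'   derived tetraploid for the direct genome-doubling comparison; pairs
#'   whose members are absent are skipped.
#' @param alpha FDR significance threshold used by every test (default
#'   0.05).
#' @param min_total minimum per-sample total count for a gene to enter the
#'   universe (default 10; the threshold is a coverage filter, see
#'   [filter_testable_genes()]).
#' @param pseudocount offset for log2 allelic ratios (display only; tests
#'   use raw counts).
#' @return object of class `hse`: a list with the gene `universe`, the
#'   per-sample `bias` tables, `cis_trans` tables per hybrid, `groups`
#'   and `inheritance` tables per non-parental sample, `wgd` gene sets per
#'   hybrid-tetraploid pair, the log2 `ratios` matrix, and a wide `master`
#'   table combining everything.
#' @seealso [summary.hse()], [coef.hse()], [plot.hse()]
#' @examples
#' cfg <- sim_config(n_genes = 200, depth = 200, seed = 42)
#' counts <- simulate_gene_counts(sample_truth(cfg), cfg)
#' fit <- hse(counts)
#' summary(fit)
#' @export
hse <- function(counts,
                parent_mix = "in_silico",
                hybrids = c("N9", "9N"),
                tetraploids = c("NN99", "99NN"),
                wgd_pairs = c(N9 = "NN99", `9N` = "99NN"),
                alpha = 0.05, min_total = 10, pseudocount = 0.5) {
  stopifnot(all(c("gene_id", "sample", "n_count", "i_count") %in%
                  names(counts)))
  present <- unique(counts$sample)
  hybrids <- as.character(unlist(hybrids))
  tetraploids <- as.character(unlist(tetraploids))
  wgd_pairs <- unlist(wgd_pairs)
  if (!(parent_mix %in% present))
    stop("parental-mix sample '", parent_mix, "' not found in counts")
  hybrids <- intersect(hybrids, present)
  if (!length(hybrids)) stop("no hybrid sample found in counts")
  tetraploids <- intersect(tetraploids, present)
  samples <- c(parent_mix, hybrids, tetraploids)
  universe <- filter_testable_genes(counts, min_total, samples)
  if (!length(universe)) stop("no gene passes the coverage filter")
  tabs <- lapply(stats::setNames(samples, samples), sample_counts,
                 counts = counts, universe = universe)
  bias <- lapply(tabs, call_bias, alpha = alpha)
  P <- tabs[[parent_mix]]
  cis_trans <- lapply(stats::setNames(hybrids, hybrids), function(h)
    classify_cis_trans(P, tabs[[h]], alpha))
  non_parental <- c(hybrids, tetraploids)
  groups <- lapply(stats::setNames(non_parental, non_parental), function(s)
    classify_group(P, tabs[[s]], alpha))
  inheritance <- lapply(stats::setNames(non_parental, non_parental),
                        function(s)
    classify_inheritance(bias[[parent_mix]]$call, bias[[s]]$call))
  wgd_pairs <- wgd_pairs[names(wgd_pairs) %in% hybrids &
                           wgd_pairs %in% tetraploids]
  wgd <- if (length(wgd_pairs))
    lapply(stats::setNames(names(wgd_pairs),
                           paste(names(wgd_pairs), "vs", wgd_pairs)),
           function(h) wgd_affected(tabs[[h]], tabs[[wgd_pairs[[h]]]],
                                    alpha))
  else list()
  ratios <- vapply(tabs, function(x)
    log2_allelic_ratio(x$n_count, x$i_count, pseudocount),
    numeric(length(universe)))
  rownames(ratios) <- universe
  master <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (s in samples) {
    master[[paste0("n_", s)]] <- tabs[[s]]$n_count
    master[[paste0("i_", s)]] <- tabs[[s]]$i_count
    master[[paste0("bias_", s)]] <- bias[[s]]$call
    master[[paste0("q_bias_", s)]] <- bias[[s]]$q
  }
  for (h in hybrids) master[[paste0("type_", h)]] <- cis_trans[[h]]$type
  for (s in non_parental) {
    master[[paste0("group_", s)]] <- groups[[s]]$group
    master[[paste0("inheritance_", s)]] <- inheritance[[s]]$pattern
  }
  for (w in names(wgd))
    master[[paste0("wgd_", gsub(" ", "_", w))]] <- universe %in% wgd[[w]]
  structure(list(call = match.call(),
                 samples = list(parent_mix = parent_mix, hybrids = hybrids,
                                tetraploids = tetraploids,
                                wgd_pairs = wgd_pairs),
                 alpha = alpha, min_total = min_total,
                 pseudocount = pseudocount,
                 universe = universe, counts = tabs, bias = bias,
                 cis_trans = cis_trans, groups = groups,
                 inheritance = inheritance, wgd = wgd, ratios = ratios,
                 master = master),
            class = "hse")
}

#' @export
print.hse <- function(x, ...) {
  cat("Homoeolog-specific expression analysis\n")
  cat(sprintf("  %d testable genes (min total %g per sample), alpha = %g\n",
              length(x$universe), x$min_total, x$alpha))
  cat("  parental mix:", x$samples$parent_mix,
      "| hybrids:", paste(x$samples$hybrids, collapse = ", "))
  if (length(x$samples$tetraploids))
    cat(" | tetraploids:", paste(x$samples$tetraploids, collapse = ", "))
  cat("\n")
  biased <- vapply(x$bias, function(b) sum(b$call != "EQUAL"), integer(1))
  cat("  biased genes per sample:",
      paste(sprintf("%s=%d", names(biased), biased), collapse = ", "), "\n")
  invisible(x)
}

count_pct_table <- function(v, levels, total) {
  n <- vapply(levels, function(l) sum(v == l), integer(1))
  data.frame(count = n, percent = count_percentage(n, total))
}

#' Summarise an hse fit as count-plus-percentage tables
#'
#' Produces the pipeline's standard summary tables, each pairing gene
#' counts with percentages of the testable universe: bias calls per
#' sample, cis/trans divergence types per hybrid, regulation groups per
#' sample, and the inheritance-category matrix (one column per hybrid and
#' tetraploid).
#'
#' @param object an [hse()] fit.
#' @param ... unused.
#' @return object of class `summary.hse`: a list of data.frames (`bias`,
#'   `types`, `groups`, `inheritance`, `wgd`) plus `n_genes`.
#' @export
summary.hse <- function(object, ...) {
  total <- length(object$universe)
  bias_levels <- c("EQUAL", "N_BIASED", "I_BIASED")
  type_levels <- c("CIS_ONLY", "TRANS_ONLY", "CIS_PLUS_TRANS",
                   "CIS_BY_TRANS", "COMPENSATORY", "CONSERVED", "AMBIGUOUS")
  group_levels <- c("GROUP_I_CONVERGENT", "GROUP_II_DIVERGENT",
                    "GROUP_III_CONSERVED")
  tab <- function(lst, field, levels)
    do.call(cbind, lapply(lst, function(d)
      stats::setNames(count_pct_table(d[[field]], levels, total),
                      c("count", "pct"))))
  inh_levels <- unique(classify_inheritance(
    rep(c("EQUAL", "N_BIASED", "I_BIASED"), each = 3),
    rep(c("EQUAL", "N_BIASED", "I_BIASED"), 3))$pattern)
  inh <- do.call(cbind, lapply(object$inheritance, function(d)
    stats::setNames(count_pct_table(d$pattern, inh_levels, total),
                    c("count", "pct"))))
  rownames(inh) <- inh_levels
  out <- list(n_genes = total,
              alpha = object$alpha,
              bias = tab(object$bias, "call", bias_levels),
              types = if (length(object$cis_trans))
                tab(object$cis_trans, "type", type_levels) else NULL,
              groups = if (length(object$groups))
                tab(object$groups, "group", group_levels) else NULL,
              inheritance = inh,
              wgd = data.frame(pair = names(object$wgd),
                               count = lengths(object$wgd),
                               pct = count_percentage(lengths(object$wgd),
                                                      total),
                               row.names = NULL))
  class(out) <- "summary.hse"
  out
}

#' @export
print.summary.hse <- function(x, ...) {
  cat(sprintf("%d testable genes; q < %g throughout\n\n", x$n_genes,
              x$alpha))
  cat("Bias calls (count / % of universe):\n")
  print(x$bias)
  if (!is.null(x$types)) {
    cat("\nCis/trans regulatory divergence types:\n")
    print(x$types)
  }
  if (!is.null(x$groups)) {
    cat("\nRegulation groups (vs in silico hybrid):\n")
    print(x$groups)
  }
  cat("\nBias inheritance categories:\n")
  print(x$inheritance)
  if (nrow(x$wgd)) {
    cat("\nGenes affected by genome doubling (hybrid vs tetraploid):\n")
    print(x$wgd)
  }
  invisible(x)
}

#' Log2 allelic ratios of a fit
#'
#' @param object an [hse()] fit.
#' @param ... unused.
#' @return matrix of log2(N/9) ratios, genes x samples, at the fit's
#'   pseudocount.
#' @export
coef.hse <- function(object, ...) object$ratios

#' Boxplot of homoeolog expression divergence per sample
#'
#' The classic range display: one box of per-gene log2(N/9) ratios per
#' sample, showing compression of parental divergence in hybrids and its
#' amplification in tetraploids.
#'
#' @param x an [hse()] fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.hse <- function(x, ...) {
  graphics::boxplot(x$ratios, ylab = "log2(N allele / 9 allele)",
                    las = 2, ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
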