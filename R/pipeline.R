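#' Read a pipeline configuration file
#'
#' The configuration is a single declarative YAML file.  Top-level keys:
#' `mode` (`"simulate"`, `"counts"` or `"sites"`), `alpha`, `min_total`,
#' `pseudocount`, `seed`, `out_dir`; a `samples` block naming the
#' `parent_mix`, `hybrids`, `tetraploids` and `wgd_pairs`; and one of a
#' `simulation` block (arguments to [sim_config()]), a `counts_file`, or a
#' `sites` block (`pileups`: sample -> pileup path, `genomic_vcf`,
#' `gff3`).  Optionally `annotation_file` (term/gene TSV) enables the
#' enrichment report.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  defaults <- list(mode = "simulate", alpha = 0.05, min_total = 10,
                   pseudocount = 0.5, seed = 1L, out_dir = "hse_out",
                   samples = list())
  cfg <- utils::modifyList(defaults, cfg)
  sdef <- list(parent_mix = "in_silico", hybrids = c("N9", "9N"),
               tetraploids = c("NN99", "99NN"),
               wgd_pairs = list(N9 = "NN99", `9N` = "99NN"))
  cfg$samples <- utils::modifyList(sdef, cfg$samples)
  if (!cfg$mode %in% c("simulate", "counts", "sites"))
    stop("mode must be simulate, counts or sites")
  if (length(cfg$samples$parent_mix) != 1)
    stop("exactly one parental-mix sample is required")
  if (length(cfg$samples$hybrids) < 1)
    stop("at least one hybrid sample is required")
  if (cfg$mode == "counts" && is.null(cfg$counts_file))
    stop("mode 'counts' requires counts_file")
  if (cfg$mode == "sites" &&
      (is.null(cfg$sites) || is.null(cfg$sites$pileups) ||
         is.null(cfg$sites$genomic_vcf) || is.null(cfg$sites$gff3)))
    stop("mode 'sites' requires sites: pileups, genomic_vcf, gff3")
  cfg
}

#' Run the full homoeolog-expression pipeline
#'
#' Assembles per-gene allele counts (simulated, read from a counts file,
#' or derived from site pileups via diagnostic-SNP selection), builds the
#' in silico hybrid if absent, fits [hse()], and writes all result tables
#' to the output directory: the diagnostic SNP list (sites mode), gene
#' counts, the wide master table, count-plus-percentage summary tables for
#' bias calls, divergence types, regulation groups and inheritance
#' categories, pairwise overlap (Venn) tables for the regulation groups,
#' the pairwise range-comparison (KS) report, optional enrichment tables,
#' and a run log with per-stage gene counts.
#'
#' @param config a config list or YAML path (see
#'   [read_pipeline_config()]).
#' @return the fitted [hse()] object, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("homeobias %s",
                         as.character(utils::packageVersion("homeobias"))),
                 sprintf("mode: %s  seed: %d", config$mode,
                         as.integer(config$seed)),
                 paste0("config: ", yaml::as.yaml(config[c(
                   "mode", "alpha", "min_total", "pseudocount", "seed")])))
  counts <- switch(config$mode,
    simulate = {
      sim_args <- config$simulation %||% list()
      sim_args$seed <- config$seed
      cfg <- do.call(sim_config, sim_args)
      truth <- sample_truth(cfg)
      write_tsv_table(truth, file.path(out, "simulation_truth.tsv"))
      simulate_gene_counts(truth, cfg)
    },
    counts = read_gene_counts(config$counts_file),
    sites = {
      pile <- lapply(config$sites$pileups, read_site_counts)
      cand <- select_indica_rna_snps(pile[["parent_9"]])
      excl <- select_nipponbare_exclusion_snps(pile[["parent_N"]])
      genomic <- read_minimal_vcf(config$sites$genomic_vcf)
      snps <- derive_diagnostic_snps(cand, genomic, excl)
      snps <- assign_snps_to_genes(snps, config$sites$gff3)
      write_tsv_table(snps, file.path(out, "diagnostic_snps.tsv"))
      log_lines <- c(log_lines,
                     sprintf("diagnostic SNPs: %d (assigned: %d)",
                             nrow(snps), sum(!is.na(snps$gene_id))))
      count_gene_alleles(pile, snps)
    })
  pm <- config$samples$parent_mix
  if (!(pm %in% counts$sample) &&
      all(c("parent_N", "parent_9") %in% counts$sample)) {
    insil <- build_in_silico_hybrid(
      counts[counts$sample == "parent_N", ],
      counts[counts$sample == "parent_9", ])
    insil$sample <- pm
    counts <- rbind(counts, insil[, names(counts)])
  }
  write_tsv_table(counts, file.path(out, "gene_counts.tsv"))
  fit <- hse(counts, parent_mix = pm,
             hybrids = config$samples$hybrids,
             tetraploids = config$samples$tetraploids,
             wgd_pairs = unlist(config$samples$wgd_pairs),
             alpha = config$alpha, min_total = config$min_total,
             pseudocount = config$pseudocount)
  sm <- summary(fit)
  write_tsv_table(fit$master, file.path(out, "master_table.tsv"))
  for (nm in c("bias", "types", "groups", "wgd")) {
    if (!is.null(sm[[nm]]))
      write_tsv_table(cbind(level = rownames(sm[[nm]]), sm[[nm]]),
                      file.path(out, paste0(nm, "_summary.tsv")))
  }
  write_tsv_table(cbind(pattern = rownames(sm$inheritance),
                        sm$inheritance),
                  file.path(out, "inheritance_summary.tsv"))
  group_sets <- function(level) lapply(fit$groups, function(g)
    fit$universe[g$group == level])
  non_par <- names(fit$groups)
  if (length(non_par) >= 2) {
    venn <- do.call(rbind, lapply(c("GROUP_I_CONVERGENT",
                                    "GROUP_II_DIVERGENT",
                                    "GROUP_III_CONSERVED"), function(lv) {
      ov <- overlap_summary(group_sets(lv), universe = fit$universe)
      cbind(group = lv, ov)
    }))
    write_tsv_table(venn, file.path(out, "group_overlap_venn.tsv"))
  }
  rng <- compare_ranges(lapply(seq_len(ncol(fit$ratios)), function(j)
    fit$ratios[, j]) |> stats::setNames(colnames(fit$ratios)))
  write_tsv_table(rng$ks, file.path(out, "range_comparison_ks.tsv"))
  write_tsv_table(rng$box, file.path(out, "range_boxplot_stats.tsv"))
  if (!is.null(config$annotation_file)) {
    ann <- read_annotation(config$annotation_file)
    enr <- enrichment_report(fit, ann)
    write_tsv_table(enr, file.path(out, "enrichment_report.tsv"))
  } else {
    log_lines <- c(log_lines, "enrichment: skipped (no annotation file)")
  }
  log_lines <- c(log_lines,
                 sprintf("genes in universe: %d", length(fit$universe)),
                 sprintf("biased in %s: %d", names(fit$bias),
                         vapply(fit$bias, function(b)
                           sum(b$call != "EQUAL"), integer(1))))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise range comparison of log-ratio distributions
#'
#' For every pair of samples, the two-sample KS statistic and asymptotic
#' p-value on the per-gene log2 allelic ratios, plus data-only boxplot
#' statistics per sample (quartiles, whiskers at 1.5 IQR, outlier count),
#' flagging p-values below the double-precision floor 2.2e-16.
#'
#' @param ratio_list named list (>= 2 entries) of numeric log-ratio
#'   vectors.
#' @return list with `ks` (data.frame `sample_a`, `sample_b`, `D`, `p`,
#'   `below_eps`) and `box` (per-sample summary data.frame).
#' @export
compare_ranges <- function(ratio_list) {
  if (!is.list(ratio_list) || length(ratio_list) < 2)
    stop("at least two samples are required")
  nm <- names(ratio_list)
  ratio_list <- lapply(ratio_list, function(x) x[is.finite(x)])
  pairs <- utils::combn(nm, 2)
  ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    r <- ks_two_sample(ratio_list[[a]], ratio_list[[b]])
    data.frame(sample_a = a, sample_b = b, D = r$D, p = r$p,
               below_eps = r$p < 2.2e-16, stringsAsFactors = FALSE)
  }))
  box <- do.call(rbind, lapply(nm, function(s) {
    x <- ratio_list[[s]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr]); hi <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(sample = s, n = length(x), q1 = q[1], median = q[2],
               q3 = q[3], whisker_lo = lo, whisker_hi = hi,
               n_outliers = sum(x < lo | x > hi), variance = stats::var(x),
               stringsAsFactors = FALSE)
  }))
  list(ks = ks, box = box)
}

#' Correlate two sets of allelic ratios
#'
#' Ordinary least-squares fit of `b` on `a` — the cross-platform
#' validation used to compare, e.g., pyrosequencing-derived allelic ratios
#' with RNA-seq-derived ones.
#'
#' @param a,b paired numeric ratio vectors (>= 3 finite pairs).
#' @return list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation), and `n`; all NA with a `reason` when the fit is
#'   undefined (too few points or zero variance).
#' @export
validate_ratios <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = length(a),
                reason = "fewer than 3 finite pairs"))
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = length(a),
                reason = "zero variance"))
  fit <- stats::lm.fit(cbind(1, a), b)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = stats::cor(a, b)^2, n = length(a))
}

#' Read a term-to-gene annotation table
#'
#' @param path TSV with columns `term` and `gene_id` (one pair per row).
#' @return named list term -> character vector of gene ids.
#' @export
read_annotation <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "gene_id") %in% names(x)))
  split(x$gene_id, x$term)
}

#' Per-group enrichment report
#'
#' Runs the hypergeometric enrichment test for every regulation group of
#' every hybrid/tetraploid sample of a fit, against the fit's gene
#' universe, flagging terms with q < 0.05.
#'
#' @param fit an [hse()] fit.
#' @param term_map named list term -> gene ids (see [read_annotation()]).
#' @return data.frame with `sample`, `group`, and the columns of
#'   [hypergeom_enrichment()], plus `significant`.
#' @export
enrichment_report <- function(fit, term_map) {
  levels <- c("GROUP_I_CONVERGENT", "GROUP_II_DIVERGENT",
              "GROUP_III_CONSERVED")
  rows <- list()
  for (s in names(fit$groups)) {
    for (lv in levels) {
      study <- fit$universe[fit$groups[[s]]$group == lv]
      if (!length(study)) next
      enr <- hypergeom_enrichment(study, fit$universe, term_map)
      if (nrow(enr))
        rows[[paste(s, lv)]] <- cbind(sample = s, group = lv, enr)
    }
  }
  if (!length(rows))
    return(data.frame())
  out <- do.call(rbind, rows)
  out$significant <- out$q < 0.05
  rownames(out) <- NULL
  out
}
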