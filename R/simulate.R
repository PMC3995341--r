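#' Simulation configuration for synthetic allele-count data
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Each gene is given a base expression level `mu`, a cis effect `c`, a
#' trans effect `t` (both in log2 units) and per-tetraploid ploidy
#' perturbations `w`, under one of six regulatory architectures.  Expected
#' Nipponbare-allele fractions then follow `r / (1 + r)` with
#' `r = 2^(c + t)` in the parental mix, `r = 2^c` in a hybrid (the shared
#' trans environment acts on both alleles and cancels), and
#' `r = 2^(c + w)` in a tetraploid.
#'
#' @param n_genes number of genes to simulate.
#' @param depth mean diagnostic-read total per gene.
#' @param dispersion negative-binomial dispersion `phi` (variance
#'   `m + phi * m^2`); 0 gives Poisson totals.
#' @param architecture_proportions named numeric vector over
#'   `c("conserved", "cis_only", "trans_only", "cis_plus_trans",
#'   "cis_by_trans", "compensatory")`, summing to 1.  Architectures may be
#'   omitted (treated as 0).
#' @param effect_range length-2 range for effect magnitudes `|c|`, `|t|`
#'   (log2 units), drawn uniformly with random sign.
#' @param w_sd standard deviation of the per-gene, per-tetraploid ploidy
#'   perturbation (log2 units); 0 disables it, making tetraploids
#'   distributionally identical to hybrids.
#' @param snps_per_gene diagnostic SNP sites simulated per gene.
#' @param error_rate per-base sequencing error rate for site-level pileups.
#' @param withheld_frac fraction of simulated SNP sites left out of the
#'   genomic SNP list (exercises the genomic-intersection rule).
#' @param contaminated_frac fraction of sites given a Nipponbare
#'   alternative-base fraction of 10% (exercises the >5% exclusion rule).
#' @param mu_sdlog sdlog of the lognormal base-expression distribution.
#' @param seed integer seed; all generator functions derive their random
#'   streams from it, so identical configs give identical output.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       depth = 1000,
                       dispersion = 0.05,
                       architecture_proportions = c(conserved = 1 / 6,
                                                    cis_only = 1 / 6,
                                                    trans_only = 1 / 6,
                                                    cis_plus_trans = 1 / 6,
                                                    cis_by_trans = 1 / 6,
                                                    compensatory = 1 / 6),
                       effect_range = c(0.5, 3),
                       w_sd = 0,
                       snps_per_gene = 2,
                       error_rate = 0.005,
                       withheld_frac = 0,
                       contaminated_frac = 0,
                       mu_sdlog = 1,
                       seed = 1L) {
  archs <- c("conserved", "cis_only", "trans_only", "cis_plus_trans",
             "cis_by_trans", "compensatory")
  if (is.null(names(architecture_proportions)) ||
      !all(names(architecture_proportions) %in% archs))
    stop("architecture_proportions must be named with known architectures")
  props <- stats::setNames(numeric(length(archs)), archs)
  props[names(architecture_proportions)] <- architecture_proportions
  if (abs(sum(props) - 1) > 1e-9)
    stop("architecture proportions must sum to 1")
  if (any(props < 0)) stop("architecture proportions must be >= 0")
  stopifnot(n_genes >= 1, depth > 0, dispersion >= 0,
            length(effect_range) == 2, effect_range[1] > 0,
            effect_range[2] >= effect_range[1],
            w_sd >= 0, snps_per_gene >= 1,
            error_rate >= 0, error_rate <= 1,
            withheld_frac >= 0, withheld_frac <= 1,
            contaminated_frac >= 0, contaminated_frac <= 1,
            mu_sdlog >= 0)
  structure(list(n_genes = as.integer(n_genes), depth = depth,
                 dispersion = dispersion, architecture_proportions = props,
                 effect_range = effect_range, w_sd = w_sd,
                 snps_per_gene = as.integer(snps_per_gene),
                 error_rate = error_rate, withheld_frac = withheld_frac,
                 contaminated_frac = contaminated_frac,
                 mu_sdlog = mu_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw per-gene regulatory ground truth
#'
#' Samples one architecture per gene from the configured proportions, then
#' draws effects respecting the architecture's constraints: `conserved` has
#' `c = t = 0`; `cis_only` has `t = 0`; `trans_only` has `c = 0`;
#' `cis_plus_trans` draws `c` and `t` with a shared sign;
#' `cis_by_trans` with opposite signs; `compensatory` sets `t = -c` so the
#' effects cancel exactly in the parental comparison.  Ploidy perturbations
#' `w_NN99` and `w_99NN` are independent Normal(0, `w_sd`) draws per gene.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `mu`, `c`, `t`, `w_NN99`,
#'   `w_99NN`, `architecture`.
#' @export
sample_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  archs <- names(config$architecture_proportions)
  arch <- sample(archs, n, replace = TRUE,
                 prob = config$architecture_proportions)
  mu <- stats::rlnorm(n, meanlog = 0, sdlog = config$mu_sdlog)
  mag <- function(k) stats::runif(k, config$effect_range[1],
                                  config$effect_range[2])
  sign1 <- function(k) sample(c(-1, 1), k, replace = TRUE)
  cc <- numeric(n); tt <- numeric(n)
  i <- arch == "cis_only"
  cc[i] <- sign1(sum(i)) * mag(sum(i))
  i <- arch == "trans_only"
  tt[i] <- sign1(sum(i)) * mag(sum(i))
  i <- arch == "cis_plus_trans"
  s <- sign1(sum(i)); cc[i] <- s * mag(sum(i)); tt[i] <- s * mag(sum(i))
  i <- arch == "cis_by_trans"
  s <- sign1(sum(i)); cc[i] <- s * mag(sum(i)); tt[i] <- -s * mag(sum(i))
  i <- arch == "compensatory"
  cc[i] <- sign1(sum(i)) * mag(sum(i)); tt[i] <- -cc[i]
  w1 <- w2 <- numeric(n)
  if (config$w_sd > 0) {
    w1 <- stats::rnorm(n, 0, config$w_sd)
    w2 <- stats::rnorm(n, 0, config$w_sd)
  }
  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             mu = mu, c = cc, t = tt, w_NN99 = w1, w_99NN = w2,
             architecture = arch, stringsAsFactors = FALSE)
}

#' Expected Nipponbare-allele fraction under the generative model
#'
#' @param truth a truth table from [sample_truth()] (or any data.frame with
#'   columns `c`, `t`, `w_NN99`, `w_99NN`).
#' @param sample_kind one of `"parent_mix"`, `"hybrid"`,
#'   `"tetraploid_NN99"`, `"tetraploid_99NN"`.
#' @return numeric vector of expected N fractions in (0, 1); the hybrid
#'   value depends only on the cis effect.
#' @export
expected_n_fraction <- function(truth, sample_kind) {
  kind <- match.arg(sample_kind, c("parent_mix", "hybrid",
                                   "tetraploid_NN99", "tetraploid_99NN"))
  lr <- switch(kind,
               parent_mix = truth$c + truth$t,
               hybrid = truth$c,
               tetraploid_NN99 = truth$c + truth$w_NN99,
               tetraploid_99NN = truth$c + truth$w_99NN)
  r <- 2^lr
  r / (1 + r)
}

rnbinom_disp <- function(n, mean, phi) {
  if (phi <= 0) stats::rpois(n, mean) else stats::rnbinom(n, mu = mean,
                                                          size = 1 / phi)
}

#' Simulate per-gene allele counts for all samples
#'
#' Draws, for every gene, a negative-binomial total with per-gene mean
#' `depth * mu / mean(mu)` and a binomial Nipponbare-allele count at the
#' architecture's expected fraction, for the two reciprocal hybrids (`N9`,
#' `9N`) and tetraploids (`NN99`, `99NN`).  Parental samples carry only
#' their own allele: each gene's parental-mix total is drawn once
#' (negative binomial) and split binomially at the `parent_mix` expected
#' fraction, the Nipponbare share forming the `parent_N` reads and the
#' 93-11 share the `parent_9` reads, so the 1:1 mix reflects the full
#' `c + t` divergence with binomial noise only; the `in_silico` sample is
#' then constructed from the parents with [build_in_silico_hybrid()].
#'
#' @param truth a truth table from [sample_truth()].
#' @param config the [sim_config()] used to draw the truth.
#' @return data.frame with columns `gene_id`, `sample`, `n_count`,
#'   `i_count`; samples `parent_N`, `parent_9`, `in_silico`, `N9`, `9N`,
#'   `NN99`, `99NN`.
#' @export
simulate_gene_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"),
            nrow(truth) == config$n_genes)
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  base <- config$depth * truth$mu / mean(truth$mu)
  draw <- function(frac) {
    tot <- rnbinom_disp(n, base, config$dispersion)
    nc <- stats::rbinom(n, tot, frac)
    data.frame(gene_id = truth$gene_id, n_count = as.integer(nc),
               i_count = as.integer(tot - nc), stringsAsFactors = FALSE)
  }
  mix <- draw(expected_n_fraction(truth, "parent_mix"))
  parts <- list(
    parent_N = data.frame(gene_id = truth$gene_id,
                          n_count = mix$n_count, i_count = 0L,
                          stringsAsFactors = FALSE),
    parent_9 = data.frame(gene_id = truth$gene_id, n_count = 0L,
                          i_count = mix$i_count,
                          stringsAsFactors = FALSE),
    N9   = draw(expected_n_fraction(truth, "hybrid")),
    `9N` = draw(expected_n_fraction(truth, "hybrid")),
    NN99 = draw(expected_n_fraction(truth, "tetraploid_NN99")),
    `99NN` = draw(expected_n_fraction(truth, "tetraploid_99NN")))
  parts$in_silico <- build_in_silico_hybrid(parts$parent_N, parts$parent_9)
  ord <- c("parent_N", "parent_9", "in_silico", "N9", "9N", "NN99", "99NN")
  out <- do.call(rbind, lapply(ord, function(s) {
    cbind(parts[[s]][, "gene_id", drop = FALSE], sample = s,
          parts[[s]][, c("n_count", "i_count")])
  }))
  rownames(out) <- NULL
  out
}

#' Simulate site-level pileups and a genomic SNP list
#'
#' Builds the fixture for the diagnostic-SNP stage: each gene gets
#' `snps_per_gene` SNP sites laid out on a single pseudo-chromosome.  In
#' the 93-11 RNA pileup the alternative base appears at frequency
#' `1 - error_rate`; in the Nipponbare pileup at `error_rate`, except for a
#' configurable `contaminated_frac` of sites whose Nipponbare alternative
#' fraction is raised to 10% (above the 5% exclusion threshold).  A
#' configurable `withheld_frac` of sites is left out of the genomic SNP
#' list.  Per-site depth is Poisson with mean `depth / snps_per_gene`.
#'
#' @param truth a truth table from [sample_truth()].
#' @param config the matching [sim_config()].
#' @return list with elements `sites_N` and `sites_9` (pileup data.frames:
#'   `chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`), `genomic_snps`
#'   (`chrom`, `pos`, `ref`, `alt`), `snp_truth` (all simulated sites with
#'   `gene_id`, `withheld`, `contaminated` flags) and `genes`
#'   (`gene_id`, `chrom`, `start`, `end` exon spans for GFF3 export).
#' @export
simulate_site_table <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  k <- config$snps_per_gene
  bases <- c("A", "C", "G", "T")
  gene_len <- 1000L
  gene_gap <- 1000L
  starts <- (seq_len(n) - 1L) * (gene_len + gene_gap) + 1L
  pos <- as.vector(vapply(starts, function(s)
    s + round(seq(0.2, 0.8, length.out = k) * gene_len), numeric(k)))
  gene_id <- rep(truth$gene_id, each = k)
  m <- n * k
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  withheld <- stats::runif(m) < config$withheld_frac
  contaminated <- stats::runif(m) < config$contaminated_frac
  site_depth <- stats::rpois(m, config$depth / k)
  alt9 <- stats::rbinom(m, site_depth, 1 - config$error_rate)
  depthN <- stats::rpois(m, config$depth / k)
  rateN <- ifelse(contaminated, 0.10, config$error_rate)
  altN <- stats::rbinom(m, depthN, rateN)
  pileup <- function(depth, altc) {
    counts <- matrix(0L, m, 4, dimnames = list(NULL, bases))
    counts[cbind(seq_len(m), match(ref, bases))] <- depth - altc
    counts[cbind(seq_len(m), match(alt, bases))] <-
      counts[cbind(seq_len(m), match(alt, bases))] + altc
    data.frame(chrom = "chr1", pos = pos, ref = ref, counts,
               stringsAsFactors = FALSE)
  }
  snp_truth <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                          gene_id = gene_id, withheld = withheld,
                          contaminated = contaminated,
                          stringsAsFactors = FALSE)
  list(sites_N = pileup(depthN, altN),
       sites_9 = pileup(site_depth, alt9),
       genomic_snps = snp_truth[!withheld, c("chrom", "pos", "ref", "alt")],
       snp_truth = snp_truth,
       genes = data.frame(gene_id = truth$gene_id, chrom = "chr1",
                          start = starts, end = starts + gene_len - 1L,
                          stringsAsFactors = FALSE))
}
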