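frac_n <- function(n, i) ifelse(n + i == 0, NA_real_, n / (n + i))

#' Call biased homoeolog expression per gene
#'
#' Tests every gene of one sample against the 1:1 null with the exact
#' binomial test, adjusts across the whole gene universe of the sample with
#' Benjamini-Hochberg, and calls `N_BIASED` / `I_BIASED` (towards the
#' Nipponbare / 93-11 homoeolog) when `q < alpha`, `EQUAL` otherwise.
#' Genes with zero total are called `EQUAL` with `q = 1` and flagged
#' untestable; they are not part of the FDR family.
#'
#' @param counts data.frame with `gene_id`, `n_count`, `i_count` for one
#'   sample.
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame `gene_id`, `n_count`, `i_count`, `p`, `q`, `call`,
#'   `untestable`.
#' @export
call_bias <- function(counts, alpha = 0.05) {
  stopifnot(all(c("gene_id", "n_count", "i_count") %in% names(counts)))
  n <- counts$n_count; i <- counts$i_count
  tot <- n + i
  p <- rep(NA_real_, length(tot))
  testable <- tot > 0
  if (any(testable)) p[testable] <- binom_exact_two_sided(n[testable],
                                                          tot[testable])
  q <- bh_adjust(p)
  q[!testable] <- 1
  call <- rep("EQUAL", length(tot))
  call[testable & q < alpha & n > i] <- "N_BIASED"
  call[testable & q < alpha & n < i] <- "I_BIASED"
  data.frame(gene_id = counts$gene_id, n_count = n, i_count = i,
             p = p, q = q, call = call, untestable = !testable,
             stringsAsFactors = FALSE)
}

merge_pair <- function(P, S, labels = c("P", "S")) {
  if (!setequal(P$gene_id, S$gene_id))
    stop("the two samples must share a gene universe")
  S <- S[match(P$gene_id, S$gene_id), ]
  out <- data.frame(gene_id = P$gene_id, stringsAsFactors = FALSE)
  out[[paste0("n_", labels[1])]] <- P$n_count
  out[[paste0("i_", labels[1])]] <- P$i_count
  out[[paste0("n_", labels[2])]] <- S$n_count
  out[[paste0("i_", labels[2])]] <- S$i_count
  out
}

#' Classify cis/trans regulatory divergence per gene
#'
#' Compares the parental mix (P, the in silico hybrid) with a true hybrid
#' (H).  Significant allelic imbalance in P evidences parental expression
#' divergence; in H it evidences cis divergence (the shared trans
#' environment acts on both alleles); a significant change of the allele
#' ratio between P and H (Yates-corrected 2x2 test, T) evidences trans
#' divergence.  All three test families are FDR-adjusted over the full gene
#' universe.  Types:
#' \describe{
#'   \item{CIS_ONLY}{sigP and sigH, not sigT}
#'   \item{TRANS_ONLY}{sigP and sigT, not sigH}
#'   \item{CIS_PLUS_TRANS}{sigP, sigH, sigT; same bias direction in P and H}
#'   \item{CIS_BY_TRANS}{sigP, sigH, sigT; opposite directions}
#'   \item{COMPENSATORY}{sigH and sigT, not sigP}
#'   \item{CONSERVED}{nothing significant}
#'   \item{AMBIGUOUS}{every other pattern, and genes whose T test is
#'     untestable (zero margin)}
#' }
#' Direction is the sign of `n_count - i_count` in each sample.
#'
#' @param P,H data.frames with `gene_id`, `n_count`, `i_count` over the
#'   same gene universe.
#' @param alpha FDR significance threshold.
#' @return data.frame `gene_id`, `q_P`, `q_H`, `q_T`, `sig_P`, `sig_H`,
#'   `sig_T`, `dir_P`, `dir_H`, `type`, `untestable`.
#' @export
classify_cis_trans <- function(P, H, alpha = 0.05) {
  m <- merge_pair(P, H, c("P", "H"))
  bias_P <- call_bias(m[, c(1, 2, 3)] |>
                        stats::setNames(c("gene_id", "n_count", "i_count")),
                      alpha)
  bias_H <- call_bias(stats::setNames(m[, c(1, 4, 5)],
                                      c("gene_id", "n_count", "i_count")),
                      alpha)
  tt <- yates_chi2_2x2(m$n_P, m$i_P, m$n_H, m$i_H)
  q_T <- bh_adjust(tt$p)
  sig_P <- bias_P$q < alpha & !bias_P$untestable
  sig_H <- bias_H$q < alpha & !bias_H$untestable
  sig_T <- !is.na(q_T) & q_T < alpha
  dir_P <- sign(m$n_P - m$i_P)
  dir_H <- sign(m$n_H - m$i_H)
  untestable <- is.na(tt$statistic) | bias_P$untestable | bias_H$untestable
  type <- rep("AMBIGUOUS", nrow(m))
  type[sig_P & sig_H & !sig_T] <- "CIS_ONLY"
  type[sig_P & !sig_H & sig_T] <- "TRANS_ONLY"
  type[sig_P & sig_H & sig_T & dir_P == dir_H] <- "CIS_PLUS_TRANS"
  type[sig_P & sig_H & sig_T & dir_P != dir_H] <- "CIS_BY_TRANS"
  type[!sig_P & sig_H & sig_T] <- "COMPENSATORY"
  type[!sig_P & !sig_H & !sig_T] <- "CONSERVED"
  type[untestable] <- "AMBIGUOUS"
  data.frame(gene_id = m$gene_id, q_P = bias_P$q, q_H = bias_H$q,
             q_T = q_T, sig_P = sig_P, sig_H = sig_H, sig_T = sig_T,
             dir_P = dir_P, dir_H = dir_H, type = type,
             untestable = untestable, stringsAsFactors = FALSE)
}

#' Assign convergent / divergent / conserved regulation groups
#'
#' Compares a hybrid or tetraploid sample (S) against the in silico hybrid
#' (P) with the Yates-corrected ratio-change test under FDR.  Genes without
#' a significant change are Group III (conserved regulation).  Significant
#' genes move to Group I (convergent: the homoeolog ratio is closer to 1:1
#' than in P) or Group II (divergent: farther from 1:1).  Distance is
#' `|fracN - 0.5|`; a significant gene with equal distances must have
#' flipped direction and is assigned to Group II.
#'
#' @param P,S data.frames with `gene_id`, `n_count`, `i_count` over the
#'   same gene universe.
#' @param alpha FDR significance threshold.
#' @return data.frame `gene_id`, `q`, `d_P`, `d_S`, `group`, `untestable`.
#' @export
classify_group <- function(P, S, alpha = 0.05) {
  m <- merge_pair(P, S, c("P", "S"))
  tt <- yates_chi2_2x2(m$n_P, m$i_P, m$n_S, m$i_S)
  q <- bh_adjust(tt$p)
  d_P <- abs(frac_n(m$n_P, m$i_P) - 0.5)
  d_S <- abs(frac_n(m$n_S, m$i_S) - 0.5)
  untestable <- is.na(tt$statistic)
  group <- rep("GROUP_III_CONSERVED", nrow(m))
  sig <- !is.na(q) & q < alpha
  tie <- abs(d_S - d_P) < 1e-12   # equal distance + significant = flip
  group[sig & !tie & d_S < d_P] <- "GROUP_I_CONVERGENT"
  group[sig & (tie | d_S > d_P)] <- "GROUP_II_DIVERGENT"
  data.frame(gene_id = m$gene_id, q = q, d_P = d_P, d_S = d_S,
             group = group, untestable = untestable,
             stringsAsFactors = FALSE)
}

#' Cross parental and hybrid/tetraploid bias calls into inheritance
#' categories
#'
#' Crosses the bias state in the parental mix (`=`, `>` for
#' Nipponbare-biased, `<` for 93-11-biased) with the state in a hybrid or
#' tetraploid into the exhaustive 3x3 table: three parental-condition
#' cells (state retained), two no-bias cells (parental bias lost), two
#' novel-bias cells (bias gained), two opposite-bias cells (bias
#' reversed).
#'
#' @param P_call,S_call character vectors of bias calls (`N_BIASED`,
#'   `I_BIASED`, `EQUAL`) from [call_bias()], positionally matched.
#' @return data.frame `pattern` (e.g. `"N>9 -> N=9"`) and `category`.
#' @export
classify_inheritance <- function(P_call, S_call) {
  stopifnot(length(P_call) == length(S_call))
  sym <- c(EQUAL = "N=9", N_BIASED = "N>9", I_BIASED = "N<9")
  if (!all(P_call %in% names(sym)) || !all(S_call %in% names(sym)))
    stop("calls must be N_BIASED, I_BIASED or EQUAL")
  cat_of <- function(p, s) {
    if (p == s) return("parental_condition")
    if (s == "EQUAL") return("no_bias")
    if (p == "EQUAL") return("novel_bias")
    "opposite_bias"
  }
  data.frame(pattern = paste(sym[P_call], "->", sym[S_call]),
             category = mapply(cat_of, P_call, S_call, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Genes whose homoeolog ratio is affected by genome doubling alone
#'
#' Directly compares each hybrid with its corresponding tetraploid using
#' the Yates-corrected ratio-change test under FDR, isolating the effect
#' of whole-genome duplication superimposed on hybridization.
#'
#' @param H,T4 data.frames with `gene_id`, `n_count`, `i_count` for the
#'   hybrid and its tetraploid, over the same gene universe.
#' @param alpha FDR significance threshold.
#' @return character vector of affected gene ids (`q < alpha`).
#' @export
wgd_affected <- function(H, T4, alpha = 0.05) {
  m <- merge_pair(H, T4, c("H", "T"))
  tt <- yates_chi2_2x2(m$n_H, m$i_H, m$n_T, m$i_T)
  q <- bh_adjust(tt$p)
  m$gene_id[!is.na(q) & q < alpha]
}

#' Venn-style overlap counts for gene sets
#'
#' Counts every intersection region of 2 to 4 gene sets (each gene lands in
#' exactly one region, keyed by its membership pattern).
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe optional character vector; if given, every set must be a
#'   subset of it, and genes in no set are reported under region `"none"`.
#' @return data.frame `region` (set names joined by `&`) and `count`.
#' @export
overlap_summary <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2, length(sets) <= 4,
            !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  if (!is.null(universe)) {
    if (!all(all_genes %in% universe))
      stop("sets contain genes outside the stated universe")
    all_genes <- unique(universe)
  }
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1,
                                                dimnames = list(NULL,
                                                                names(sets)))
  pattern <- apply(member, 1, function(row) {
    if (!any(row)) "none" else paste(names(sets)[row], collapse = "&")
  })
  tab <- table(pattern)
  data.frame(region = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Inherited and novel proportions between a hybrid and its tetraploid
#'
#' For a regulation group g, the inherited proportion is the fraction of
#' the hybrid's group-g genes that keep the same group membership in the
#' corresponding tetraploid; the novel proportion is the fraction of the
#' tetraploid's group-g genes absent from the hybrid's.
#'
#' @param hybrid,tetraploid character vectors of gene ids in the group.
#' @return named numeric vector with `inherited` and `novel`.
#' @export
inherited_novel_proportions <- function(hybrid, tetraploid) {
  hybrid <- unique(hybrid); tetraploid <- unique(tetraploid)
  c(inherited = if (length(hybrid))
      length(intersect(hybrid, tetraploid)) / length(hybrid) else NA_real_,
    novel = if (length(tetraploid))
      length(setdiff(tetraploid, hybrid)) / length(tetraploid) else NA_real_)
}
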