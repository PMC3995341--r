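site_summary <- function(sites) {
  bases <- c("A", "C", "G", "T")
  counts <- as.matrix(sites[, bases])
  depth <- rowSums(counts)
  refcol <- match(sites$ref, bases)
  if (anyNA(refcol)) stop("invalid reference base at row ",
                          which(is.na(refcol))[1])
  non_ref <- counts
  non_ref[cbind(seq_len(nrow(counts)), refcol)] <- -1L
  alt_idx <- max.col(non_ref, ties.method = "first")
  alt_count <- counts[cbind(seq_len(nrow(counts)), alt_idx)]
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             alt = bases[alt_idx], depth = depth, alt_count = alt_count,
             stringsAsFactors = FALSE)
}

#' Select candidate homoeolog-diagnostic SNP sites from 93-11 RNA pileups
#'
#' A site qualifies when its depth exceeds 10 reads and the dominant
#' alternative (non-reference) base accounts for more than 95% of the reads
#' — i.e. the 93-11 transcriptome is essentially fixed for a base that
#' differs from the Nipponbare reference.  Both thresholds are strict
#' inequalities.
#'
#' @param sites pileup data.frame (`chrom`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`), as from [read_site_counts()].
#' @param min_depth depth that must be exceeded (default 10).
#' @param min_alt_frac alternative-base fraction that must be exceeded
#'   (default 0.95).
#' @return data.frame of selected sites: `chrom`, `pos`, `ref`, `alt`.
#' @export
select_indica_rna_snps <- function(sites, min_depth = 10,
                                   min_alt_frac = 0.95) {
  s <- site_summary(sites)
  keep <- s$depth > min_depth & s$alt_count / s$depth > min_alt_frac
  out <- s[keep, c("chrom", "pos", "ref", "alt")]
  rownames(out) <- NULL
  out
}

#' Select the Nipponbare exclusion SNP list
#'
#' Same depth criterion as [select_indica_rna_snps()] but a site enters the
#' exclusion list as soon as its alternative-base fraction exceeds 5% —
#' such sites are polymorphic (or error-prone) in the Nipponbare material
#' itself and cannot diagnose the parental origin of a read.
#'
#' @inheritParams select_indica_rna_snps
#' @return data.frame of exclusion sites: `chrom`, `pos`, `ref`, `alt`.
#' @export
select_nipponbare_exclusion_snps <- function(sites, min_depth = 10,
                                             min_alt_frac = 0.05) {
  select_indica_rna_snps(sites, min_depth = min_depth,
                         min_alt_frac = min_alt_frac)
}

snp_key <- function(x) paste(x$chrom, x$pos, x$alt, sep = ":")

#' Derive the final homoeolog-diagnostic SNP set
#'
#' Keeps sites found both in the 93-11 RNA-derived candidate set and in the
#' genomic DNA SNP list, minus any site on the Nipponbare exclusion list;
#' all sets are keyed by (chrom, pos, alternative base).  Positions carrying
#' conflicting alternative bases between the RNA candidates and the genomic
#' list are dropped with a message.  The Nipponbare homoeolog is tagged by
#' the reference base, the 93-11 homoeolog by the alternative base.
#'
#' @param indica_rna candidate sites from [select_indica_rna_snps()].
#' @param genomic genomic SNPs (`chrom`, `pos`, `ref`, `alt`), e.g. from
#'   [read_minimal_vcf()].
#' @param exclusion exclusion sites from
#'   [select_nipponbare_exclusion_snps()].
#' @return data.frame of diagnostic SNPs: `chrom`, `pos`, `allele_N`,
#'   `allele_9`, `gene_id` (NA until assigned).
#' @export
derive_diagnostic_snps <- function(indica_rna, genomic, exclusion) {
  pos_key <- function(x) paste(x$chrom, x$pos, sep = ":")
  conflict <- intersect(pos_key(indica_rna), pos_key(genomic))
  conflict <- conflict[!(conflict %in%
                           pos_key(genomic)[snp_key(genomic) %in%
                                              snp_key(indica_rna)])]
  if (length(conflict))
    message(length(conflict),
            " site(s) dropped: conflicting alternative bases ",
            "between RNA and genomic SNP lists")
  keep <- indica_rna[snp_key(indica_rna) %in% snp_key(genomic) &
                       !(snp_key(indica_rna) %in% snp_key(exclusion)), ]
  out <- data.frame(chrom = keep$chrom, pos = keep$pos,
                    allele_N = keep$ref, allele_9 = keep$alt,
                    gene_id = rep(NA_character_, nrow(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

as_exon_granges <- function(gene_models) {
  if (is.character(gene_models)) {
    gr <- rtracklayer::import(gene_models, format = "gff3")
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
    S4Vectors::mcols(ex)$gene_id <- parent
    return(ex)
  }
  if (is.data.frame(gene_models)) {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in%
                    names(gene_models)))
    if (any(gene_models$end < gene_models$start))
      stop("degenerate gene interval(s)")
    return(GenomicRanges::GRanges(
      gene_models$chrom,
      IRanges::IRanges(gene_models$start, gene_models$end),
      gene_id = gene_models$gene_id))
  }
  stopifnot(methods::is(gene_models, "GRanges"))
  gene_models
}

#' Assign diagnostic SNPs to gene models
#'
#' A SNP falling inside the exon span of exactly one gene gets that gene's
#' id; SNPs hitting zero genes or the overlap of two or more gene models
#' remain unassigned (multi-gene SNPs would let the same reads be tested
#' twice).  Coordinates are 1-based inclusive and counting is unstranded.
#'
#' @param snps diagnostic SNPs from [derive_diagnostic_snps()].
#' @param gene_models a GFF3 file path (exon features with `Parent`
#'   attributes), a data.frame (`gene_id`, `chrom`, `start`, `end`), or a
#'   `GRanges` with a `gene_id` metadata column.
#' @return `snps` with `gene_id` filled in where uniquely assignable.
#' @export
assign_snps_to_genes <- function(snps, gene_models) {
  ex <- as_exon_granges(gene_models)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, ex, ignore.strand = TRUE)
  gene_per_hit <- ex$gene_id[S4Vectors::subjectHits(hits)]
  by_snp <- split(gene_per_hit, S4Vectors::queryHits(hits))
  n_genes <- vapply(by_snp, function(g) length(unique(g)), integer(1))
  unique_idx <- as.integer(names(by_snp))[n_genes == 1L]
  snps$gene_id <- NA_character_
  snps$gene_id[unique_idx] <-
    vapply(by_snp[n_genes == 1L], `[`, character(1), 1)
  n_multi <- sum(n_genes > 1L)
  if (n_multi)
    message(n_multi, " SNP(s) left unassigned: overlap >= 2 gene models")
  snps
}

#' Tabulate per-gene allele counts from pileups at diagnostic SNPs
#'
#' For every sample pileup, reads matching the Nipponbare allele
#' (reference base) and the 93-11 allele (alternative base) at each
#' assigned diagnostic SNP are summed per gene; reads matching neither
#' allele are ignored.  Genes without any assigned diagnostic SNP are
#' absent from the output.
#'
#' @param site_tables named list of pileup data.frames, one per sample.
#' @param snps assigned diagnostic SNPs (rows with `NA` `gene_id` are
#'   skipped).
#' @return data.frame `gene_id`, `sample`, `n_count`, `i_count`, one row
#'   per gene per sample (genes with zero reads retained).
#' @export
count_gene_alleles <- function(site_tables, snps) {
  stopifnot(is.list(site_tables), !is.null(names(site_tables)))
  snps <- snps[!is.na(snps$gene_id), ]
  if (!nrow(snps)) stop("no assigned diagnostic SNPs")
  bases <- c("A", "C", "G", "T")
  out <- lapply(names(site_tables), function(smp) {
    tab <- site_tables[[smp]]
    idx <- match(paste(snps$chrom, snps$pos),
                 paste(tab$chrom, tab$pos))
    counts <- as.matrix(tab[, bases])
    nc <- ifelse(is.na(idx), 0L,
                 counts[cbind(idx, match(snps$allele_N, bases))])
    ic <- ifelse(is.na(idx), 0L,
                 counts[cbind(idx, match(snps$allele_9, bases))])
    agg_n <- rowsum(nc, snps$gene_id)
    agg_i <- rowsum(ic, snps$gene_id)
    data.frame(gene_id = rownames(agg_n), sample = smp,
               n_count = as.integer(agg_n[, 1]),
               i_count = as.integer(agg_i[, 1]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the in silico hybrid by 1:1 mixing of the parental samples
#'
#' Scales each parent's diagnostic-site reads to the smaller of the two
#' library sizes (library size = total diagnostic-site reads in that
#' parent), so the mix represents the two parents at exactly 1:1 on the
#' reads being analysed, then rounds to the nearest integer (ties to
#' even).  The Nipponbare allele counts come from the Nipponbare parent,
#' the 93-11 allele counts from the 93-11 parent.
#'
#' @param parent_N,parent_9 data.frames with `gene_id`, `n_count`,
#'   `i_count` for the two parents, over the same gene universe.
#' @return data.frame `gene_id`, `sample` (`"in_silico"`), `n_count`,
#'   `i_count`.
#' @export
build_in_silico_hybrid <- function(parent_N, parent_9) {
  if (!nrow(parent_N) || !nrow(parent_9)) stop("empty parent table")
  if (!setequal(parent_N$gene_id, parent_9$gene_id))
    stop("parent tables must cover the same gene universe")
  parent_9 <- parent_9[match(parent_N$gene_id, parent_9$gene_id), ]
  lib_N <- sum(as.numeric(parent_N$n_count) + parent_N$i_count)
  lib_9 <- sum(as.numeric(parent_9$n_count) + parent_9$i_count)
  if (lib_N == 0 || lib_9 == 0) stop("parent library size is zero")
  common <- min(lib_N, lib_9)
  data.frame(gene_id = parent_N$gene_id, sample = "in_silico",
             n_count = as.integer(round(as.numeric(parent_N$n_count) *
                                          common / lib_N)),
             i_count = as.integer(round(as.numeric(parent_9$i_count) *
                                          common / lib_9)),
             stringsAsFactors = FALSE)
}

#' Restrict the analysis to adequately covered genes
#'
#' Keeps genes whose total allele count (`n + i`) reaches `min_total` in
#' every analysed sample.  A gene absent from a sample counts as zero
#' there.
#'
#' @param counts long gene count table (`gene_id`, `sample`, `n_count`,
#'   `i_count`).
#' @param min_total minimum per-sample total (default 10).
#' @param samples samples that must meet the threshold; defaults to all
#'   samples present in `counts`.
#' @return character vector of retained gene ids.
#' @export
filter_testable_genes <- function(counts, min_total = 10, samples = NULL) {
  if (is.null(samples)) samples <- unique(counts$sample)
  sub <- counts[counts$sample %in% samples, ]
  tot <- stats::xtabs((n_count + i_count) ~ gene_id + sample, data = sub)
  missing_sample <- setdiff(samples, colnames(tot))
  ok <- rowSums(tot[, intersect(samples, colnames(tot)), drop = FALSE] >=
                  min_total) == length(samples) - length(missing_sample)
  if (length(missing_sample) && min_total > 0) ok[] <- FALSE
  sort(rownames(tot)[ok])
}
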