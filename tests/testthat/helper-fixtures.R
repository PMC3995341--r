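# Small builders shared across test files.

pileup_row <- function(chrom, pos, ref, alt, ref_n, alt_n) {
  counts <- stats::setNames(as.list(integer(4)), c("A", "C", "G", "T"))
  counts[[ref]] <- ref_n
  counts[[alt]] <- counts[[alt]] + alt_n
  cbind(data.frame(chrom = chrom, pos = pos, ref = ref,
                   stringsAsFactors = FALSE),
        as.data.frame(counts))
}

pileup_table <- function(...) do.call(rbind, list(...))

gene_counts_1 <- function(gene_id, n, i) {
  data.frame(gene_id = gene_id, n_count = n, i_count = i,
             stringsAsFactors = FALSE)
}

# per-site depth and alternative-base reads of a pileup at known SNP sites
site_counts_at <- function(pileup, snp_truth) {
  idx <- match(paste(snp_truth$chrom, snp_truth$pos),
               paste(pileup$chrom, pileup$pos))
  counts <- as.matrix(pileup[idx, c("A", "C", "G", "T")])
  data.frame(depth = rowSums(counts),
             alt_reads = counts[cbind(seq_len(nrow(counts)),
                                      match(snp_truth$alt,
                                            c("A", "C", "G", "T")))])
}

# counts table for a handful of genes across the standard sample set
toy_counts <- function(genes, n, i, sample) {
  data.frame(gene_id = genes, sample = sample, n_count = n, i_count = i,
             stringsAsFactors = FALSE)
}
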