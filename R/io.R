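#' Read and write the pipeline's tab-separated tables
#'
#' All tabular interchange is plain TSV with a header line.
#' Gene allele counts use columns `gene_id`, `sample`, `n_count`,
#' `i_count`; site pileup summaries use `chrom`, `pos` (1-based), `ref`,
#' `A`, `C`, `G`, `T`.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_*` return a data.frame; `write_*` return `path`
#'   invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_gene_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(gene_id = "character",
                                        sample = "character"))
  need <- c("gene_id", "sample", "n_count", "i_count")
  if (!all(need %in% names(x)))
    stop("gene count table must have columns: ", paste(need, collapse = ", "))
  x
}

#' @rdname table_io
#' @export
read_site_counts <- function(path) {
  x <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                error = function(e) stop("failed to parse pileup table '",
                                         path, "': ", conditionMessage(e)))
  need <- c("chrom", "pos", "ref", "A", "C", "G", "T")
  if (!all(need %in% names(x)))
    stop("pileup table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(x$pos) | x$pos < 1)
  if (length(bad))
    stop("malformed pileup rows (pos < 1) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  x
}

#' Minimal VCF input and output for genomic SNP lists
#'
#' The genomic SNP interchange format is a minimal VCF: the standard
#' 8-column body with only CHROM, POS, REF and ALT populated.  Only
#' single-nucleotide, single-allele records are kept on reading.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param path file path.
#' @return `read_minimal_vcf` returns a data.frame with columns `chrom`,
#'   `pos`, `ref`, `alt`; `write_minimal_vcf` returns `path` invisibly.
#' @export
write_minimal_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", snps$chrom,
                       as.integer(snps$pos), snps$ref, snps$alt), con)
  invisible(path)
}

#' @rdname write_minimal_vcf
#' @export
read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 5))
    stop("malformed VCF record at line ",
         which(!startsWith(lines, "#"))[which(nf < 5)[1]])
  x <- data.frame(chrom = vapply(f, `[`, "", 1),
                  pos = as.integer(vapply(f, `[`, "", 2)),
                  ref = vapply(f, `[`, "", 4),
                  alt = vapply(f, `[`, "", 5),
                  stringsAsFactors = FALSE)
  x[nchar(x$ref) == 1 & nchar(x$alt) == 1 &
      !grepl(",", x$alt, fixed = TRUE), , drop = FALSE]
}

#' Write gene exon spans as GFF3
#'
#' Emits one `gene` and one `exon` feature per row, with `ID`/`Parent`
#' attributes, suitable for [assign_snps_to_genes()].
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(c(
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
              g$chrom, g$start, g$end, g$gene_id),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t+\t.\tID=%s.exon1;Parent=%s",
              g$chrom, g$start, g$end, g$gene_id, g$gene_id)), con)
  }
  invisible(path)
}
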