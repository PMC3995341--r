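test_that("93-11 candidate selection applies strict depth and fraction rules", {
  sites <- pileup_table(
    pileup_row("chr1", 100, "A", "G", 0, 12),    # depth 12, alt 12: in
    pileup_row("chr1", 200, "A", "G", 0, 10),    # depth 10: out (strict >10)
    pileup_row("chr1", 300, "A", "G", 5, 95),    # 95%: out (strict >95%)
    pileup_row("chr1", 400, "C", "T", 3, 97))    # in
  sel <- select_indica_rna_snps(sites)
  expect_equal(sel$pos, c(100, 400))
  expect_equal(sel$alt, c("G", "T"))
})

test_that("Nipponbare exclusion list uses the >5% rule at the same depth", {
  sites <- pileup_table(
    pileup_row("chr1", 100, "A", "G", 94, 6),    # 6%: excluded site
    pileup_row("chr1", 200, "A", "G", 95, 5),    # 5%: not excluded
    pileup_row("chr1", 300, "A", "G", 0, 8))     # depth 8: not excluded
  sel <- select_nipponbare_exclusion_snps(sites)
  expect_equal(sel$pos, 100)
})

test_that("diagnostic SNPs are the RNA/genomic intersection minus exclusions", {
  rna <- data.frame(chrom = "chr1", pos = c(1, 2, 3), ref = "A",
                    alt = c("G", "G", "G"), stringsAsFactors = FALSE)
  genomic <- data.frame(chrom = "chr1", pos = c(1, 3, 9), ref = "A",
                        alt = "G", stringsAsFactors = FALSE)
  excl <- data.frame(chrom = "chr1", pos = 3, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  out <- derive_diagnostic_snps(rna, genomic, excl)
  expect_equal(out$pos, 1)                       # 2: not genomic; 3: excluded
  expect_equal(out$allele_N, "A")
  expect_equal(out$allele_9, "G")
  # order invariance
  out2 <- derive_diagnostic_snps(rna[3:1, ], genomic[c(2, 3, 1), ], excl)
  expect_equal(out, out2)
  # conflicting alternative bases are dropped with a message
  genomic2 <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "T",
                         stringsAsFactors = FALSE)
  expect_message(out3 <- derive_diagnostic_snps(rna, genomic2, excl),
                 "conflicting")
  expect_equal(nrow(out3), 0)
})

test_that("SNPs map to genes only when the exon assignment is unambiguous", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(100, 180), end = c(200, 260),
                      stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "chr1", pos = c(150, 190, 500),
                     allele_N = "A", allele_9 = "G",
                     gene_id = NA_character_, stringsAsFactors = FALSE)
  expect_message(out <- assign_snps_to_genes(snps, genes), "unassigned")
  expect_equal(out$gene_id, c("gA", NA, NA))
  # same result through the GFF3 file route
  gff <- tempfile(fileext = ".gff3")
  write_gff3(genes, gff)
  out2 <- suppressMessages(assign_snps_to_genes(snps, gff))
  expect_equal(out2$gene_id, out$gene_id)
})

test_that("per-gene allele counting sums reads matching each parental base", {
  snps <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
                     allele_N = c("A", "C", "A"),
                     allele_9 = c("G", "T", "G"),
                     gene_id = c("g1", "g1", "g2"), stringsAsFactors = FALSE)
  pile <- pileup_table(
    pileup_row("chr1", 10, "A", "G", 30, 10),
    pileup_row("chr1", 20, "C", "T", 50, 10),
    pileup_row("chr1", 30, "A", "G", 0, 0))
  out <- count_gene_alleles(list(s1 = pile), snps)
  expect_equal(out$n_count[out$gene_id == "g1"], 80)
  expect_equal(out$i_count[out$gene_id == "g1"], 20)
  # zero-count gene retained
  expect_equal(out$n_count[out$gene_id == "g2"], 0)
  expect_equal(out$i_count[out$gene_id == "g2"], 0)
})

test_that("in silico mixing scales to the smaller library at 1:1", {
  pN <- gene_counts_1(c("g1", "g2"), c(300, 999700), c(0, 0))
  p9 <- gene_counts_1(c("g1", "g2"), c(0, 0), c(100, 499900))
  mix <- build_in_silico_hybrid(pN, p9)
  expect_equal(mix$n_count[mix$gene_id == "g1"], 150)  # scaled by 1/2
  expect_equal(mix$i_count[mix$gene_id == "g1"], 100)  # scale 1
  # equal library sizes: identity on per-gene counts
  pN <- gene_counts_1(c("g1", "g2"), c(300, 700), c(0, 0))
  p9 <- gene_counts_1(c("g1", "g2"), c(0, 0), c(100, 900))
  mix <- build_in_silico_hybrid(pN, p9)
  expect_equal(mix$n_count, c(300, 700))
  expect_equal(mix$i_count, c(100, 900))
  # both parents zero for a gene
  pN <- gene_counts_1(c("g1", "g2"), c(0, 10), c(0, 0))
  p9 <- gene_counts_1(c("g1", "g2"), c(0, 0), c(0, 10))
  expect_equal(build_in_silico_hybrid(pN, p9)$n_count[1], 0)
  expect_error(build_in_silico_hybrid(pN[0, ], p9), "empty")
})

test_that("coverage filter requires min_total in every analysed sample", {
  cnt <- rbind(toy_counts(c("g1", "g2"), c(50, 3), c(50, 2), "in_silico"),
               toy_counts(c("g1", "g2"), c(40, 60), c(40, 60), "N9"))
  expect_equal(filter_testable_genes(cnt, 10), "g1")
  expect_setequal(filter_testable_genes(cnt, 0), c("g1", "g2"))
  # a gene absent from one sample fails a positive threshold
  cnt2 <- rbind(cnt, toy_counts("g3", 100, 100, "in_silico"))
  expect_false("g3" %in% filter_testable_genes(cnt2, 10))
})

test_that("a clean simulated site table is recovered exactly as diagnostic", {
  cfg <- sim_config(n_genes = 60, depth = 600, snps_per_gene = 2,
                    error_rate = 0, withheld_frac = 0,
                    contaminated_frac = 0, seed = 31)
  tr <- sample_truth(cfg)
  st <- simulate_site_table(tr, cfg)
  cand <- select_indica_rna_snps(st$sites_9)
  excl <- select_nipponbare_exclusion_snps(st$sites_N)
  snps <- derive_diagnostic_snps(cand, st$genomic_snps, excl)
  expect_setequal(paste(snps$chrom, snps$pos, snps$allele_9),
                  with(st$snp_truth, paste(chrom, pos, alt)))
  snps <- assign_snps_to_genes(snps, st$genes)
  truth_gene <- st$snp_truth$gene_id[match(snps$pos, st$snp_truth$pos)]
  expect_equal(snps$gene_id, truth_gene)
  # counting conservation: per-gene totals equal summed per-site reads
  gc <- count_gene_alleles(list(parent_9 = st$sites_9), snps)
  s9 <- site_counts_at(st$sites_9, st$snp_truth)
  per_gene <- rowsum(s9$alt_reads, st$snp_truth$gene_id)
  expect_equal(gc$i_count, as.integer(per_gene[gc$gene_id, 1]))
  expect_true(all(gc$n_count == 0))   # error-free: no N-base reads in 93-11
})

test_that("withheld and contaminated sites are filtered by the set rules", {
  cfg <- sim_config(n_genes = 80, depth = 800, snps_per_gene = 2,
                    error_rate = 0, withheld_frac = 0.3,
                    contaminated_frac = 0.3, seed = 33)
  tr <- sample_truth(cfg)
  st <- simulate_site_table(tr, cfg)
  snps <- derive_diagnostic_snps(select_indica_rna_snps(st$sites_9),
                                 st$genomic_snps,
                                 select_nipponbare_exclusion_snps(st$sites_N))
  got <- paste(snps$chrom, snps$pos)
  truth <- st$snp_truth
  kept <- !truth$withheld & !truth$contaminated
  expect_setequal(got, with(truth[kept, ], paste(chrom, pos)))
})
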