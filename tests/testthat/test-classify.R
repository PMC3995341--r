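test_that("bias calls respect direction and the q < alpha rule", {
  out <- call_bias(gene_counts_1("g1", 500, 500))
  expect_equal(out$call, "EQUAL")
  expect_equal(out$p, 1)
  expect_equal(call_bias(gene_counts_1("g1", 800, 200))$call, "N_BIASED")
  expect_equal(call_bias(gene_counts_1("g1", 200, 800))$call, "I_BIASED")
  zero <- call_bias(gene_counts_1("g1", 0, 0))
  expect_equal(zero$call, "EQUAL")
  expect_equal(zero$q, 1)
  expect_true(zero$untestable)
  # FDR family is the whole sample: many null genes shield one weak signal
  many <- gene_counts_1(sprintf("g%03d", 1:50),
                        c(60, rep(50, 49)), c(40, rep(50, 49)))
  expect_equal(call_bias(many)$call[1], "EQUAL")  # q = p * 50 / 1 > 0.05
})

test_that("cis/trans types follow the seven significance rules", {
  one <- function(np, ip, nh, ih)
    classify_cis_trans(gene_counts_1("g1", np, ip),
                       gene_counts_1("g1", nh, ih))$type
  expect_equal(one(80, 20, 80, 20), "CIS_ONLY")
  expect_equal(one(100, 100, 150, 50), "COMPENSATORY")
  expect_equal(one(150, 50, 100, 100), "TRANS_ONLY")
  expect_equal(one(50, 50, 50, 50), "CONSERVED")
  # concordant significant shift in P, H and T: cis + trans
  expect_equal(one(180, 20, 140, 60), "CIS_PLUS_TRANS")
  # significant in all three with opposite directions: cis x trans
  expect_equal(one(150, 50, 60, 140), "CIS_BY_TRANS")
  # zero-margin T test is untestable, hence ambiguous
  expect_equal(one(0, 0, 50, 50), "AMBIGUOUS")
})

test_that("regulation groups compare divergence distance to the mix", {
  one <- function(np, ip, ns, is)
    classify_group(gene_counts_1("g1", np, ip),
                   gene_counts_1("g1", ns, is))$group
  expect_equal(one(150, 50, 100, 100), "GROUP_I_CONVERGENT")
  expect_equal(one(100, 100, 160, 40), "GROUP_II_DIVERGENT")
  expect_equal(one(120, 80, 120, 80), "GROUP_III_CONSERVED")
  # equal distance with a significant change means the direction flipped
  expect_equal(one(160, 40, 40, 160), "GROUP_II_DIVERGENT")
  g <- classify_group(gene_counts_1("g1", 0, 0), gene_counts_1("g1", 0, 0))
  expect_equal(g$group, "GROUP_III_CONSERVED")
  expect_true(g$untestable)
})

test_that("inheritance categories cover the 3x3 cross exactly", {
  calls <- c("EQUAL", "N_BIASED", "I_BIASED")
  grid <- expand.grid(P = calls, S = calls, stringsAsFactors = FALSE)
  out <- classify_inheritance(grid$P, grid$S)
  expect_equal(nrow(out), 9)
  expect_equal(length(unique(out$pattern)), 9)
  expect_equal(as.integer(sort(table(out$category))), c(2, 2, 2, 3))
  expect_equal(classify_inheritance("EQUAL", "EQUAL")$category,
               "parental_condition")
  expect_equal(classify_inheritance("EQUAL", "N_BIASED")$category,
               "novel_bias")
  expect_equal(classify_inheritance("N_BIASED", "I_BIASED")$category,
               "opposite_bias")
  expect_equal(classify_inheritance("N_BIASED", "EQUAL")$category,
               "no_bias")
  expect_error(classify_inheritance("EQUAL", "WAT"))
})

test_that("the hybrid/tetraploid direct comparison flags ratio changes", {
  H <- gene_counts_1(c("g1", "g2"), c(100, 100), c(100, 100))
  expect_equal(wgd_affected(H, H), character(0))
  T4 <- gene_counts_1(c("g1", "g2"), c(180, 100), c(20, 100))
  expect_equal(wgd_affected(H, T4), "g1")
  expect_equal(wgd_affected(H, T4, alpha = 0), character(0))
})

test_that("overlap regions and inherited/novel proportions are exact", {
  A <- c("g1", "g2", "g3"); B <- c("g2", "g3", "g4")
  ov <- overlap_summary(list(A = A, B = B))
  expect_equal(ov$count[ov$region == "A&B"], 2)
  pr <- inherited_novel_proportions(A, B)
  expect_equal(unname(pr["inherited"]), 2 / 3)
  expect_equal(unname(pr["novel"]), 1 / 3)
  ident <- overlap_summary(list(A = A, B = A))
  expect_equal(ident$count[ident$region == "A&B"], 3)
  expect_equal(unname(inherited_novel_proportions(A, A)["inherited"]), 1)
  disj <- overlap_summary(list(A = A, B = "g9"))
  expect_false("A&B" %in% disj$region)
  expect_error(overlap_summary(list(A = A, B = B), universe = A),
               "universe")
})

test_that("classifications are equivariant under allele relabeling", {
  cfg <- sim_config(n_genes = 400, depth = 400, seed = 17)
  cnt <- simulate_gene_counts(sample_truth(cfg), cfg)
  P <- cnt[cnt$sample == "in_silico", c("gene_id", "n_count", "i_count")]
  H <- cnt[cnt$sample == "N9", c("gene_id", "n_count", "i_count")]
  swap <- function(x) data.frame(gene_id = x$gene_id, n_count = x$i_count,
                                 i_count = x$n_count)
  b1 <- call_bias(P); b2 <- call_bias(swap(P))
  expect_equal(b2$call,
               c(N_BIASED = "I_BIASED", I_BIASED = "N_BIASED",
                 EQUAL = "EQUAL")[b1$call], ignore_attr = TRUE)
  expect_equal(b1$q, b2$q, tolerance = 1e-12)
  t1 <- classify_cis_trans(P, H)
  t2 <- classify_cis_trans(swap(P), swap(H))
  expect_equal(t1$type, t2$type)   # type membership is label-free
  g1 <- classify_group(P, H); g2 <- classify_group(swap(P), swap(H))
  expect_equal(g1$group, g2$group)
  # inheritance mirror cells swap between the two labelings
  i1 <- classify_inheritance(b1$call, call_bias(H)$call)
  i2 <- classify_inheritance(b2$call, call_bias(swap(H))$call)
  expect_equal(i1$category, i2$category)
  mirror <- c("N>9 -> N<9" = "N<9 -> N>9", "N<9 -> N>9" = "N>9 -> N<9")
  flipped <- i1$pattern %in% names(mirror)
  expect_equal(i2$pattern[flipped],
               unname(mirror[i1$pattern[flipped]]))
})

test_that("every gene receives exactly one label per classifier", {
  cfg <- sim_config(n_genes = 300, depth = 300, w_sd = 0.5, seed = 19)
  cnt <- simulate_gene_counts(sample_truth(cfg), cfg)
  fit <- hse(cnt)
  n <- length(fit$universe)
  for (h in names(fit$cis_trans)) {
    tab <- table(fit$cis_trans[[h]]$type)
    expect_equal(sum(tab), n)
  }
  for (s in names(fit$groups))
    expect_equal(sum(table(fit$groups[[s]]$group)), n)
  for (s in names(fit$inheritance))
    expect_equal(sum(table(fit$inheritance[[s]]$pattern)), n)
  # structural consistency: CIS_BY_TRANS requires discordant directions
  for (h in names(fit$cis_trans)) {
    ct <- fit$cis_trans[[h]]
    expect_true(all(ct$dir_P[ct$type == "CIS_BY_TRANS"] !=
                      ct$dir_H[ct$type == "CIS_BY_TRANS"]))
    expect_true(all(ct$dir_P[ct$type == "CIS_PLUS_TRANS"] ==
                      ct$dir_H[ct$type == "CIS_PLUS_TRANS"]))
  }
})
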