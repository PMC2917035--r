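# Luminal A/B classification: centroid reference, Pearson labeling,
# RPPA luminalness score.

ref_matrix <- function(seed = 12, n_genes = 30, sep = 2) {
  set.seed(seed)
  base <- matrix(rnorm(n_genes * 8), n_genes, 8,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 c(paste0("a", 1:4), paste0("b", 1:4))))
  shift <- rnorm(n_genes, sd = sep)
  base[, 5:8] <- base[, 5:8] + shift
  expression_matrix(base, "gene")
}

test_that("centroid reference does the two-group midpoint arithmetic", {
  m <- matrix(c(3, 3, 1, 1,
                0, 2, 4, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
  ref <- build_centroid_reference(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(ref$lumA_profile[1], 1)   # means 3 vs 1, centroid 2
  expect_equal(ref$lumB_profile[1], -1)
  expect_equal(ref$lumA_profile, -ref$lumB_profile, tolerance = 1e-9)

  # identical groups -> degenerate flag
  same <- matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"),
                                            c("a1", "a2", "b1", "b2")))
  same[, 3:4] <- same[, 1:2]
  ref0 <- build_centroid_reference(same, c("a1", "a2"), c("b1", "b2"))
  expect_true(ref0$degenerate)

  expect_error(build_centroid_reference(m, c("a1", "a2"), c("a2", "b1")),
               class = "pathscore_validation_error")
})

test_that("profiles matching a centroid profile get that label", {
  m <- ref_matrix()
  ref <- build_centroid_reference(m, paste0("a", 1:4), paste0("b", 1:4))
  pb <- setNames(ref$lumB_profile, ref$gene_ids)
  call_b <- classify_mrna_subtype(pb, ref)
  expect_identical(call_b$label, "lumB")
  expect_equal(call_b$r_lumB, 1, tolerance = 1e-12)
  expect_equal(call_b$r_lumA, -1, tolerance = 1e-12)
  # the exact negative of the lumA profile is also lumB (two-group identity)
  pa_neg <- setNames(-ref$lumA_profile, ref$gene_ids)
  expect_identical(classify_mrna_subtype(pa_neg, ref)$label, "lumB")
})

test_that("classification is invariant to positive affine transforms and r_lumA = -r_lumB", {
  m <- ref_matrix(seed = 4)
  ref <- build_centroid_reference(m, paste0("a", 1:4), paste0("b", 1:4))
  set.seed(77)
  for (i in 1:20) {
    p <- setNames(rnorm(length(ref$gene_ids)), ref$gene_ids)
    r <- classify_mrna_subtype(p, ref)
    expect_equal(r$r_lumA, -r$r_lumB, tolerance = 1e-9)
    r2 <- classify_mrna_subtype(p * runif(1, 0.2, 5) + rnorm(1), ref)
    expect_equal(r2$r_lumA, r$r_lumA, tolerance = 1e-9)
    expect_identical(r2$label, r$label)
  }
})

test_that("flat profiles and exact ties are unclassified", {
  m <- ref_matrix(seed = 9)
  ref <- build_centroid_reference(m, paste0("a", 1:4), paste0("b", 1:4))
  flat <- setNames(rep(1, length(ref$gene_ids)), ref$gene_ids)
  r <- classify_mrna_subtype(flat, ref)
  expect_identical(r$label, "unclassified")
  expect_identical(r$flag, "zero_variance")
})

test_that("luminalness score follows the weighted-sum rule and tie convention", {
  panel <- luminalness_panel()
  zero <- setNames(rep(0, length(panel$weights)), names(panel$weights))
  r0 <- rppa_luminalness(zero, panel)
  expect_equal(r0$score, 0)
  expect_identical(r0$label, "lumA")  # 0 >= -0.907

  # worked example: ER/PR/Bcl2 at +0.2, the seven B markers at +0.3
  v <- zero
  v[c("ER", "PR", "Bcl2")] <- 0.2
  v[setdiff(names(panel$weights), c("ER", "PR", "Bcl2"))] <- 0.3
  r <- rppa_luminalness(v, panel)
  expect_equal(r$score, 0.6 - 2.1, tolerance = 1e-12)
  expect_identical(r$label, "lumB")

  # boundary: a score of exactly the cutoff is luminal A
  v2 <- zero; v2["ER"] <- panel$cutoff
  expect_identical(rppa_luminalness(v2, panel)$label, "lumA")

  # linearity and global sign flip
  expect_equal(rppa_luminalness(v * 2, panel)$score, 2 * r$score,
               tolerance = 1e-12)
  expect_equal(rppa_luminalness(-v, panel)$score, -r$score, tolerance = 1e-12)
})

test_that("samples missing over a quarter of the panel are unclassified", {
  panel <- luminalness_panel()
  v <- setNames(rep(0.1, length(panel$weights)), names(panel$weights))
  v[1:3] <- NA  # 3 of 10 missing -> 30%
  r <- rppa_luminalness(v, panel)
  expect_identical(r$label, "unclassified")
  expect_identical(r$flag, "too_many_missing")
  v[3] <- 0.1   # 20% missing is tolerated
  expect_true(rppa_luminalness(v, panel)$label %in% c("lumA", "lumB"))
})

test_that("centroid classifier recovers subtypes of a separated synthetic cohort", {
  sig <- gene_signature("s", sprintf("u%02d", 1:40), sprintf("d%02d", 1:40))
  # well separated: gene-level subtype shift (gene_loading * activity
  # shift = 2) at twice the unit noise sd, balanced strata, within-class
  # activity spread well below the shift
  cfg <- cohort_config(n_tumors = 120, gene_loading = 1, lumB_fraction = 0.5,
                       activity_sd = 0.5, lumB_activity_shift = 2,
                       n_background_genes = 50, seed = 301)
  train <- simulate_tumor_cohort(cfg, sig)
  test_cfg <- cfg; test_cfg$seed <- 302L
  test <- simulate_tumor_cohort(test_cfg, sig)
  ref <- build_centroid_reference(
    train$matrix,
    train$truth$sample_id[train$truth$subtype_label == "lumA"],
    train$truth$sample_id[train$truth$subtype_label == "lumB"])
  calls <- classify_cohort_subtypes(test$matrix, ref)
  acc <- mean(calls$label == test$truth$subtype_label)
  expect_gt(acc, 0.9)
})
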