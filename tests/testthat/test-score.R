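# Activity scoring: centering, the signature t score, the protein score.

test_that("centering modes satisfy their definitions", {
  m <- make_matrix(10, 6)
  med <- center_genes(m, "median")
  expect_equal(unname(apply(med, 1, median)), rep(0, 10))
  mn <- center_genes(m, "mean")
  expect_equal(unname(rowMeans(mn)), rep(0, 10), tolerance = 1e-12)

  row <- matrix(c(1, 2, 3, 4), 1, dimnames = list("g", paste0("s", 1:4)))
  sc <- center_genes(row, "median_sd_scaled")
  expect_equal(unname(sc[1, ]), c(-1.162, -0.387, 0.387, 1.162),
               tolerance = 1e-3)
})

test_that("centering preserves missing values in place", {
  m <- make_matrix(4, 5)
  m[2, 3] <- NA
  out <- center_genes(m, "median")
  expect_true(is.na(out[2, 3]))
  expect_equal(median(out[2, ], na.rm = TRUE), 0)
})

test_that("signature t score matches the pooled-t hand example and symmetry", {
  sig <- tiny_signature()
  profile <- c(g01 = 1, g02 = 2, g03 = 3, g04 = 0, g05 = 0, g06 = 0)
  r <- signature_tscore(profile, sig)
  expect_equal(r$score, 3.4641, tolerance = 1e-4)
  expect_identical(c(r$n_up_used, r$n_down_used), c(3L, 3L))

  # identical multisets in both arms -> 0
  p0 <- c(g01 = 1, g02 = 2, g03 = 3, g04 = 1, g05 = 2, g06 = 3)
  expect_equal(signature_tscore(p0, sig)$score, 0)

  # swapped arms negate the score
  swapped <- gene_signature("sw", sig$repressed, sig$induced)
  expect_equal(signature_tscore(profile, swapped)$score, -r$score)
})

test_that("t score is shift-invariant, scale-invariant for k > 0, negates for k < 0", {
  sig <- tiny_signature()
  set.seed(8)
  for (i in 1:25) {
    p <- setNames(rnorm(6), sprintf("g%02d", 1:6))
    base <- signature_tscore(p, sig)$score
    expect_equal(signature_tscore(p + rnorm(1), sig)$score, base,
                 tolerance = 1e-10)
    k <- runif(1, 0.1, 10)
    expect_equal(signature_tscore(p * k, sig)$score, base, tolerance = 1e-10)
    expect_equal(signature_tscore(p * -k, sig)$score, -base, tolerance = 1e-10)
  }
})

test_that("degenerate profiles are flagged instead of scored", {
  sig <- tiny_signature()
  r <- signature_tscore(c(g01 = 1, g02 = 2, g04 = 0, g05 = 0), sig)
  expect_false(r$degenerate)  # 2 per arm is the minimum
  r1 <- signature_tscore(c(g01 = 1, g04 = 0, g05 = 0), sig)
  expect_true(r1$degenerate)
  expect_true(is.na(r1$score))
  # zero pooled variance with unequal means
  r2 <- signature_tscore(c(g01 = 1, g02 = 1, g03 = 1, g04 = 0, g05 = 0, g06 = 0),
                         sig)
  expect_true(r2$degenerate)
})

test_that("cohort scoring orients inhibition signatures and is permutation-equivariant", {
  sig <- tiny_signature()  # derivation_meaning defaults to inhibition
  m <- make_matrix(6, 10, seed = 3)
  sc <- score_cohort_activity(m, sig)
  # relabeling as activation-derived with arms swapped gives identical scores
  sig_act <- gene_signature("act", sig$repressed, sig$induced,
                            derivation_meaning = "activation")
  sc2 <- score_cohort_activity(m, sig_act)
  expect_equal(sc$score, sc2$score, tolerance = 1e-12)

  perm <- sample(ncol(m))
  scp <- score_cohort_activity(m[, perm], sig)
  expect_equal(scp$score[match(sc$sample_id, scp$sample_id)], sc$score)

  expect_error(score_cohort_activity(m[4:6, ], sig),
               class = "pathscore_validation_error")
})

test_that("t score equals an independently coded pooled t on random profiles", {
  sig <- tiny_signature()
  set.seed(21)
  for (i in 1:50) {
    p <- setNames(rnorm(6), sprintf("g%02d", 1:6))
    expect_equal(signature_tscore(p, sig)$score,
                 oracle_pooled_t(p[sig$induced], p[sig$repressed]),
                 tolerance = 1e-10)
  }
})

test_that("protein score is the signed sum of centered panel endpoints", {
  vals <- c(pAkt = 1.0, pmTOR = 0.5, pGSK3 = -0.2, pS6K = 0.3, pS6 = 0.1,
            PTEN = 0.4)
  p <- cbind(s1 = vals, s2 = -vals)  # already centered: rows have mean 0
  r <- pi3k_protein_score(p, center = FALSE)
  expect_equal(r$score[1], 1.3, tolerance = 1e-9)
  expect_equal(r$score[2], -1.3, tolerance = 1e-9)

  # all-zero centered values -> 0
  z <- matrix(0, 6, 3, dimnames = list(names(vals), paste0("s", 1:3)))
  expect_equal(pi3k_protein_score(z, center = FALSE)$score, rep(0, 3))

  # raising PTEN by delta lowers the score by exactly delta
  p2 <- p; p2["PTEN", "s1"] <- p2["PTEN", "s1"] + 0.25
  r2 <- pi3k_protein_score(p2, center = FALSE)
  expect_equal(r2$score[1], r$score[1] - 0.25, tolerance = 1e-12)
})

test_that("AKT phosphosites are resolved per panel policy", {
  p <- matrix(c(2, 1, 0.5, 0.3, 0.2, 0.1, 0.4), ncol = 1,
              dimnames = list(c("pAKT_T308", "pAKT_S473", "pmTOR", "pGSK3",
                                "pS6K", "pS6", "PTEN"), "s1"))
  r_avg <- pi3k_protein_score(p, center = FALSE)
  expect_equal(r_avg$score, 1.5 + 0.5 + 0.3 + 0.2 + 0.1 - 0.4, tolerance = 1e-12)
  r_308 <- pi3k_protein_score(p, protein_score_panel(akt_site_policy = "T308"),
                              center = FALSE)
  expect_equal(r_308$score, 2 + 0.5 + 0.3 + 0.2 + 0.1 - 0.4, tolerance = 1e-12)
  expect_error(pi3k_protein_score(p[-1, , drop = FALSE], center = FALSE),
               class = "pathscore_validation_error")
})

test_that("missing endpoint values follow the declared policy", {
  vals <- c(pAkt = 1.0, pmTOR = 0.5, pGSK3 = -0.2, pS6K = 0.3, pS6 = 0.1,
            PTEN = 0.4)
  p <- cbind(s1 = vals, s2 = vals)
  p["pmTOR", "s2"] <- NA
  skip <- pi3k_protein_score(p, center = FALSE, missing_policy = "skip_sample")
  expect_true(is.na(skip$score[2]) && skip$degenerate[2])
  ren <- pi3k_protein_score(p, center = FALSE, missing_policy = "renormalize")
  expect_equal(ren$score[2], (1.3 - 0.5) * 6 / 5, tolerance = 1e-12)
  # an endpoint missing for every sample is an error regardless of policy
  p["pmTOR", ] <- NA
  expect_error(pi3k_protein_score(p, center = FALSE,
                                  missing_policy = "renormalize"),
               class = "pathscore_validation_error")
})
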