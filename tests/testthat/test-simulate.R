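# Synthetic-data generators: reproducibility, planted structure, nulls.

test_that("identical config and seed give bit-identical outputs", {
  cfg <- perturbation_config(n_genes = 200, seed = 8,
                             n_true_induced = 10, n_true_repressed = 10)
  a <- simulate_perturbation_experiment(cfg)
  b <- simulate_perturbation_experiment(cfg)
  expect_identical(a, b)

  sig <- tiny_signature()
  cc <- cohort_config(n_tumors = 30, n_background_genes = 20, seed = 8)
  expect_identical(simulate_tumor_cohort(cc, sig),
                   simulate_tumor_cohort(cc, sig))
  expect_identical(simulate_rppa_cohort(cc), simulate_rppa_cohort(cc))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_perturbation_experiment(
    perturbation_config(n_genes = 50, n_true_induced = 5,
                        n_true_repressed = 5, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("null perturbation yields uniform p-values", {
  cfg <- perturbation_config(n_genes = 5000, n_true_induced = 0,
                             n_true_repressed = 0, effect_size = 0, seed = 21)
  sim <- simulate_perturbation_experiment(cfg)
  st <- two_group_ttest(sim$matrix, sim$treated, sim$control)
  ks <- suppressWarnings(ks.test(st$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted shifts appear exactly in the noiseless limit", {
  cfg <- perturbation_config(n_genes = 100, n_true_induced = 10,
                             n_true_repressed = 10, effect_size = 2,
                             noise_sd = 1e-12, seed = 4)
  sim <- simulate_perturbation_experiment(cfg)
  d <- rowMeans(sim$matrix[, sim$treated]) - rowMeans(sim$matrix[, sim$control])
  expect_equal(unname(d[sim$truth$label == "induced"]), rep(2, 10),
               tolerance = 1e-9)
  expect_equal(unname(d[sim$truth$label == "repressed"]), rep(-2, 10),
               tolerance = 1e-9)
  expect_equal(unname(d[sim$truth$label == "null"]), rep(0, 80),
               tolerance = 1e-9)
})

test_that("low-noise cohorts are scored with exact sign and near-perfect rank agreement", {
  # the t score is scale-invariant within a sample, so its magnitude
  # saturates as noise vanishes; the sign against the cohort median is
  # exact and the ranking approaches the latent ordering
  sig <- gene_signature("wide", sprintf("u%03d", 1:60), sprintf("d%03d", 1:60))
  cfg <- cohort_config(n_tumors = 40, noise_sd = 1e-3,
                       n_background_genes = 10, seed = 13)
  co <- simulate_tumor_cohort(cfg, sig)
  sc <- score_cohort_activity(co$matrix, sig)
  a <- co$truth$latent_activity
  expect_identical(sign(sc$score), sign(a - median(a)))
  expect_gt(cor(sc$score, a, method = "spearman"), 0.95)
})

test_that("decoupled ER shows no association with the score", {
  sig <- tiny_signature()
  rhos <- vapply(1:25, function(s) {
    cfg <- cohort_config(n_tumors = 100, er_coupling = 0,
                         n_background_genes = 20, seed = s)
    co <- simulate_tumor_cohort(cfg, sig)
    sc <- score_cohort_activity(co$matrix, sig)
    cor(sc$score, co$annotations$er_level, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("matched platforms share the latent variable, independent ones do not", {
  sig <- gene_signature("wide", sprintf("u%03d", 1:60), sprintf("d%03d", 1:60))
  cfg <- cohort_config(n_tumors = 40, noise_sd = 1e-6,
                       n_background_genes = 10, seed = 19)
  co <- simulate_tumor_cohort(cfg, sig)
  rp <- simulate_rppa_cohort(cfg, shared_truth = co$truth)
  sc <- score_cohort_activity(co$matrix, sig)
  ps <- pi3k_protein_score(rp$matrix)
  # the protein score is linear in the latent variable: exact ranks
  expect_equal(cor(ps$score, co$truth$latent_activity, method = "spearman"), 1)
  expect_gt(cor(sc$score, ps$score, method = "spearman"), 0.95)

  # independent truths: concordance centered on zero across seeds
  rhos <- vapply(1:25, function(s) {
    c1 <- cohort_config(n_tumors = 40, n_background_genes = 10, seed = s)
    c2 <- cohort_config(n_tumors = 40, n_background_genes = 10, seed = s + 5000)
    a <- simulate_tumor_cohort(c1, sig)
    b <- simulate_rppa_cohort(c2)
    sa <- score_cohort_activity(a$matrix, sig)
    pb <- pi3k_protein_score(b$matrix)
    cor(sa$score, pb$score, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(perturbation_config(n_genes = 10, n_true_induced = 8,
                                   n_true_repressed = 8),
               class = "pathscore_validation_error")
  expect_error(perturbation_config(n_treated = 1),
               class = "pathscore_validation_error")
  expect_error(perturbation_config(noise_sd = 0),
               class = "pathscore_validation_error")
  expect_error(cohort_config(n_tumors = 5),
               class = "pathscore_validation_error")
  expect_error(cohort_config(lumB_fraction = 1.2),
               class = "pathscore_validation_error")
})
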