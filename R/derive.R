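# Signature derivation: per-gene two-group t tests on log expression with
# Storey q-value FDR control, then selection of induced / repressed gene
# sets at conjunctive p and q thresholds.

#' Per-gene two-group t test
#'
#' Row-wise two-sided t test comparing `groupA` against `groupB` columns
#' (difference reported as A − B on the log2 scale). Pooled-variance Student
#' t by default; Welch by `variance_mode = "welch"`. Genes with fewer than
#' two non-missing values in either group get `NA` statistics.
#'
#' @param m numeric matrix, genes/probes in rows, samples in columns.
#' @param groupA,groupB disjoint character vectors of sample (column)
#'   identifiers, each of length >= 2.
#' @param variance_mode `"pooled"` (Student) or `"welch"`.
#' @return data frame with columns `gene_id`, `mean_diff`, `t_stat`,
#'   `p_value`, `df`, `n_a`, `n_b`.
#' @export
two_group_ttest <- function(m, groupA, groupB,
                            variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  groupA <- as.character(groupA); groupB <- as.character(groupB)
  if (length(intersect(groupA, groupB)))
    stop_validation("groups overlap: ",
                    paste(intersect(groupA, groupB), collapse = ", "))
  missing_ids <- setdiff(c(groupA, groupB), colnames(m))
  if (length(missing_ids))
    stop_validation("sample ids absent from matrix: ",
                    paste(utils::head(missing_ids, 5L), collapse = ", "))
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_validation("each group needs >= 2 samples")

  a <- m[, groupA, drop = FALSE]
  b <- m[, groupB, drop = FALSE]
  row_moments <- function(x) {
    n <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    v <- rowSums((x - mu)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
    v[n < 2L] <- NA_real_
    mu[n < 1L] <- NA_real_
    list(n = n, mean = mu, var = v)
  }
  ma <- row_moments(a); mb <- row_moments(b)
  usable <- ma$n >= 2L & mb$n >= 2L
  diff <- ma$mean - mb$mean

  if (variance_mode == "pooled") {
    df <- ma$n + mb$n - 2
    sp2 <- ((ma$n - 1) * ma$var + (mb$n - 1) * mb$var) / df
    se <- sqrt(sp2 * (1 / ma$n + 1 / mb$n))
  } else {
    va <- ma$var / ma$n; vb <- mb$var / mb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ma$n - 1) + vb^2 / (mb$n - 1))
  }
  t_stat <- diff / se
  # degenerate zero-variance rows: t = 0 when means agree, +/-Inf otherwise
  zero_se <- usable & !is.na(se) & se == 0
  t_stat[zero_se] <- sign(diff[zero_se]) * Inf
  t_stat[zero_se & diff == 0] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[zero_se & diff == 0] <- 1
  t_stat[!usable] <- NA_real_
  p[!usable] <- NA_real_
  diff[!usable] <- NA_real_

  data.frame(gene_id = rownames(m), mean_diff = diff, t_stat = t_stat,
             p_value = p, df = df, n_a = ma$n, n_b = mb$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the null proportion pi0 on a lambda grid
#' (`pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`), smooths
#' `pi0(lambda)` with a cubic smoothing spline and evaluates it at the
#' largest lambda, clamping to (0, 1]. Q-values are the step-up
#' `pi0 * min over p_(j) >= p_(i) of m p_(j) / j`; with `pi0_mode = "fixed"`
#' and `pi0 = 1` this is exactly the Benjamini–Hochberg procedure.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA` propagates.
#' @param lambda_grid grid for the pi0 smoother (default 0.05..0.95 by 0.05).
#' @param pi0_mode `"smoother"` (spline, the default), `"fixed_lambda"`
#'   (point estimate at `fixed_lambda`, stabler for small m), or `"fixed"`
#'   (use the supplied `pi0`).
#' @param pi0 null proportion for `pi0_mode = "fixed"`.
#' @param fixed_lambda lambda for `pi0_mode = "fixed_lambda"`.
#' @return list with `q_values` (input order), `pi0_estimate`,
#'   `lambda_grid`, `pi0_lambda` (raw grid estimates).
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                           pi0_mode = c("smoother", "fixed_lambda", "fixed"),
                           pi0 = NULL, fixed_lambda = 0.5) {
  pi0_mode <- match.arg(pi0_mode)
  ok <- !is.na(p)
  pv <- p[ok]
  if (!length(pv)) stop_validation("no non-missing p-values")
  if (any(pv < 0 | pv > 1)) stop_validation("p-values must lie in [0, 1]")
  m <- length(pv)

  pi0_lambda <- vapply(lambda_grid, function(l) mean(pv > l) / (1 - l),
                       numeric(1L))
  pi0_est <- switch(pi0_mode,
    fixed = {
      if (is.null(pi0) || pi0 <= 0 || pi0 > 1)
        stop_validation("pi0_mode = 'fixed' needs pi0 in (0, 1]")
      pi0
    },
    fixed_lambda = min(1, max(.Machine$double.eps,
                              mean(pv > fixed_lambda) / (1 - fixed_lambda))),
    smoother = {
      fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = 3)
      est <- stats::predict(fit, x = max(lambda_grid))$y
      min(1, max(.Machine$double.eps, est))
    })

  o <- order(pv)
  qs <- pi0_est * (m / seq_len(m) * pv[o])
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  qv <- numeric(m)
  qv[o] <- qs
  q_full <- rep(NA_real_, length(p))
  q_full[ok] <- qv
  list(q_values = q_full, pi0_estimate = pi0_est,
       lambda_grid = lambda_grid, pi0_lambda = pi0_lambda)
}

#' Derive an induced/repressed gene signature from a perturbation contrast
#'
#' Runs [two_group_ttest()] (treated vs control), attaches Storey q-values,
#' and keeps genes with `p_value < p_max` AND `q_value < q_max`. Genes with
#' a positive treated−control difference form the induced set, negative the
#' repressed set. For an inhibitor experiment keep
#' `derivation_meaning = "inhibition"` so downstream scoring orients the
#' score as pathway *activity*.
#'
#' @param m expression matrix (genes/probes x samples, log2).
#' @param treated,control sample id vectors.
#' @param p_max,q_max selection thresholds (defaults 0.01 and 0.1).
#' @param name signature name.
#' @param derivation_meaning what "induced" means; see [gene_signature()].
#' @param variance_mode,pi0_mode passed through to the t test / q-values.
#' @return `gene_signature` with the full per-gene statistics table attached.
#' @export
derive_signature <- function(m, treated, control, p_max = 0.01, q_max = 0.1,
                             name = "signature",
                             derivation_meaning = c("inhibition", "activation"),
                             variance_mode = c("pooled", "welch"),
                             pi0_mode = c("smoother", "fixed_lambda", "fixed"),
                             ...) {
  derivation_meaning <- match.arg(derivation_meaning)
  if (!(p_max > 0 && p_max <= 1 && q_max > 0 && q_max <= 1))
    stop_validation("thresholds must lie in (0, 1]")
  stats_tab <- two_group_ttest(m, treated, control,
                               variance_mode = match.arg(variance_mode))
  qres <- storey_qvalues(stats_tab$p_value, pi0_mode = match.arg(pi0_mode), ...)
  stats_tab$q_value <- qres$q_values

  pass <- !is.na(stats_tab$p_value) & !is.na(stats_tab$q_value) &
    stats_tab$p_value < p_max & stats_tab$q_value < q_max &
    stats_tab$mean_diff != 0
  if (!any(pass)) {
    min_p <- suppressWarnings(min(stats_tab$p_value, na.rm = TRUE))
    stop_validation(sprintf(
      "no genes pass p < %g and q < %g (min p = %.3g, pi0 = %.3f)",
      p_max, q_max, min_p, qres$pi0_estimate))
  }
  induced <- stats_tab$gene_id[pass & stats_tab$mean_diff > 0]
  repressed <- stats_tab$gene_id[pass & stats_tab$mean_diff < 0]
  sig <- gene_signature(name, induced, repressed,
                        derivation_meaning = derivation_meaning,
                        per_gene_stats = stats_tab)
  attr(sig, "pi0_estimate") <- qres$pi0_estimate
  attr(sig, "thresholds") <- c(p_max = p_max, q_max = q_max)
  sig
}
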