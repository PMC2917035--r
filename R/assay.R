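# Wet-lab quantification arithmetic: qPCR relative expression by the
# 2^-ddCt method and growth-inhibition percentages from endpoint
# absorbance, plus their group tests.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) − Ct(reference); ddCt =
#' mean(dCt treated) − mean(dCt control); fold change = 2^(−ddCt).
#' The SEM is propagated on the log2 (dCt) scale as
#' `sqrt(sem_treated^2 + sem_control^2)` (a single-replicate group
#' contributes zero spread) and also reported on the fold scale by the
#' delta method; per-replicate treated fold changes (each against the
#' control mean dCt) are returned for error bars.
#'
#' @param ct_target_treated,ct_ref_treated paired treated-replicate Ct
#'   values (target and endogenous-control gene, cycles).
#' @param ct_target_control,ct_ref_control the control replicates.
#' @return list: `fold_change`, `ddct`, `sem_log2`, `sem_fold`,
#'   `replicate_folds` (treated), `n_treated`, `n_control`.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  if (length(ct_target_treated) != length(ct_ref_treated) ||
      length(ct_target_control) != length(ct_ref_control))
    stop_validation("target and reference Ct vectors must be paired")
  if (!length(ct_target_treated) || !length(ct_target_control))
    stop_validation("both groups need >= 1 replicate")
  all_ct <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(all_ct) | all_ct <= 0))
    stop_validation("Ct values must be positive and finite")
  dct_t <- ct_target_treated - ct_ref_treated
  dct_c <- ct_target_control - ct_ref_control
  ddct <- mean(dct_t) - mean(dct_c)
  fold <- 2^(-ddct)
  sem_g <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  sem_log2 <- sqrt(sem_g(dct_t)^2 + sem_g(dct_c)^2)
  sem_fold <- fold * log(2) * sem_log2   # delta method on 2^-x
  list(fold_change = fold, ddct = ddct, sem_log2 = sem_log2,
       sem_fold = sem_fold,
       replicate_folds = 2^(-(dct_t - mean(dct_c))),
       n_treated = length(dct_t), n_control = length(dct_c))
}

#' Growth inhibition from endpoint absorbance
#'
#' Per treated well: `(1 − OD / mean(control OD)) * 100`. Values above the
#' control mean give negative inhibition (growth stimulation); these are
#' reported, not clipped, and counted in `n_stimulated`.
#'
#' @param od_treated treated-well absorbance values (>= 0).
#' @param od_control control-well absorbance values; their mean must be
#'   positive.
#' @return list: `percent` (per treated well), `mean`, `sd`,
#'   `n_stimulated`.
#' @export
growth_inhibition <- function(od_treated, od_control) {
  if (any(od_treated < 0, na.rm = TRUE) || any(od_control < 0, na.rm = TRUE))
    stop_validation("absorbance values must be >= 0")
  ctrl <- mean(od_control, na.rm = TRUE)
  if (!is.finite(ctrl) || ctrl <= 0)
    stop_validation("mean control OD must be positive")
  pct <- (1 - od_treated / ctrl) * 100
  list(percent = pct, mean = mean(pct, na.rm = TRUE),
       sd = stats::sd(pct), n_stimulated = sum(pct < 0, na.rm = TRUE))
}

#' Classic one-way fixed-effects ANOVA
#'
#' Thin wrapper over `stats::oneway.test(var.equal = TRUE)`; with two
#' groups F equals the square of the pooled two-sample t statistic.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list: `F`, `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop_validation("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_validation("every group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(y) == 0)           # identical groups: no variance anywhere
    return(list(F = 0, df1 = length(groups) - 1L,
                df2 = length(y) - length(groups), p_value = 1))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1L]),
       df2 = unname(ft$parameter[2L]), p_value = unname(ft$p.value))
}
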