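# Association statistics: Spearman rank correlations of activity scores
# with ER/PR levels, luminal B vs luminal A score comparison, and
# cross-platform (protein vs mRNA) score concordance.

# all permutations of 1..n as an (n! x n) matrix; n <= 9 by construction
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with tie-aware ranks
#'
#' rho is the Pearson correlation of average ranks (ties share their mean
#' rank). The p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` for n >= 10 and an exact
#' two-sided permutation test (all n! permutations) for n < 10. Incomplete
#' pairs are dropped pairwise-complete.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return data frame of class `association_result`: `variable_pair`, `n`,
#'   `spearman_rho`, `p_value`, `method_notes`; zero-variance input gives
#'   `NA` rho with a flag in `method_notes`.
#' @export
spearman_assoc <- function(x, y, variable_pair = "x~y") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_validation("need >= 3 complete pairs, have ", n)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(structure(data.frame(
      variable_pair = variable_pair, n = n, spearman_rho = NA_real_,
      p_value = NA_real_, method_notes = "undefined: zero rank variance",
      stringsAsFactors = FALSE),
      class = c("association_result", "data.frame")))
  rho <- stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
  if (n >= 10L) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    notes <- "average ranks; t approximation"
  } else {
    perms <- all_permutations(n)
    sx <- (rx - mean(rx)); sy <- (ry - mean(ry))
    denom <- sqrt(sum(sx^2) * sum(sy^2))
    # sum_i sx[i] * sy[perm[i]], vectorized over all permutations
    rho_perm <- apply(perms, 1L, function(pm) sum(sx * sy[pm])) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    notes <- "average ranks; exact permutation"
  }
  structure(data.frame(variable_pair = variable_pair, n = n,
                       spearman_rho = rho, p_value = p, method_notes = notes,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Two-group comparison of scores by pooled t test
#'
#' Two-sided pooled-variance Student t test of the mean score between the
#' two label levels, with a direction string naming the higher group.
#'
#' @param scores numeric vector.
#' @param labels parallel vector with exactly two distinct non-missing
#'   levels, each with >= 2 scores.
#' @return data frame of class `group_comparison`: group names and means,
#'   `t_stat`, `df`, `p_value`, `direction`.
#' @export
group_mean_ttest <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.character(labels[ok])
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop_validation("labels must have exactly 2 levels, have ",
                    length(lv))
  g1 <- scores[labels == lv[1L]]; g2 <- scores[labels == lv[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop_validation("each group needs >= 2 scores")
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean(g1) - mean(g2)
  tt <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
  p <- if (se == 0 && d == 0) 1 else 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  direction <- if (d > 0) paste(lv[1L], "higher")
               else if (d < 0) paste(lv[2L], "higher") else "equal means"
  structure(data.frame(group1 = lv[1L], group2 = lv[2L],
                       mean1 = mean(g1), mean2 = mean(g2),
                       n1 = n1, n2 = n2, t_stat = tt, df = n1 + n2 - 2,
                       p_value = p, direction = direction,
                       stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' Assemble the standard association report for a scored cohort
#'
#' One table bundling: Spearman correlation of the activity score with ER
#' and with PR levels; the luminal B vs luminal A score comparison (when
#' the annotations carry subtype labels); and, when a second score table
#' from the other platform is supplied, the cross-platform score
#' concordance. Rows with fewer than 3 aligned samples are kept and
#' flagged rather than dropped. Duplicated sample ids in any input are an
#' error (merged cohorts must be de-duplicated first, see
#' [drop_samples()]).
#'
#' @param scores `activity_scores` data frame (or any data frame with
#'   `sample_id` and `score`).
#' @param ann annotation data frame (`sample_id`, optional `er_level`,
#'   `pr_level`, `subtype_label`).
#' @param scores2 optional second score table (other platform).
#' @return data frame: `analysis`, `n`, `estimate`, `statistic`,
#'   `p_value`, `note`.
#' @export
association_report <- function(scores, ann, scores2 = NULL) {
  check_unique(scores$sample_id, "score sample ids")
  check_unique(ann$sample_id, "annotation sample ids")
  merged <- merge(scores[, c("sample_id", "score")], ann, by = "sample_id")
  rows <- list()
  add_spearman <- function(analysis, x, y) {
    ok <- sum(!is.na(x) & !is.na(y))
    if (ok < 3L)
      return(data.frame(analysis = analysis, n = ok, estimate = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        note = "flagged: < 3 aligned samples",
                        stringsAsFactors = FALSE))
    r <- spearman_assoc(x, y, analysis)
    data.frame(analysis = analysis, n = r$n, estimate = r$spearman_rho,
               statistic = NA_real_, p_value = r$p_value, note = r$method_notes,
               stringsAsFactors = FALSE)
  }
  if ("er_level" %in% names(merged))
    rows$er <- add_spearman("score~ER", merged$score, merged$er_level)
  if ("pr_level" %in% names(merged))
    rows$pr <- add_spearman("score~PR", merged$score, merged$pr_level)
  if ("subtype_label" %in% names(merged)) {
    sub <- merged[merged$subtype_label %in% c("lumA", "lumB"), ]
    if (length(unique(sub$subtype_label)) == 2L &&
        min(table(sub$subtype_label)) >= 2L) {
      gc <- group_mean_ttest(sub$score, sub$subtype_label)
      rows$sub <- data.frame(analysis = "lumB_vs_lumA", n = gc$n1 + gc$n2,
                             estimate = gc$mean2 - gc$mean1,
                             statistic = gc$t_stat, p_value = gc$p_value,
                             note = gc$direction, stringsAsFactors = FALSE)
    } else {
      rows$sub <- data.frame(analysis = "lumB_vs_lumA",
                             n = nrow(sub), estimate = NA_real_,
                             statistic = NA_real_, p_value = NA_real_,
                             note = "flagged: need both subtypes with >= 2 samples",
                             stringsAsFactors = FALSE)
    }
  }
  if (!is.null(scores2)) {
    check_unique(scores2$sample_id, "second score-table sample ids")
    both <- merge(scores[, c("sample_id", "score")],
                  scores2[, c("sample_id", "score")],
                  by = "sample_id", suffixes = c("_1", "_2"))
    rows$xp <- add_spearman("platform_concordance", both$score_1, both$score_2)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  msg(nrow(out), " association row(s); no multiplicity correction applied")
  out
}
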