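# Sample-level pathway activity scoring:
#  * mRNA "t score": within one sample, the pooled two-sample t statistic
#    comparing centered expression of a signature's induced genes against
#    its repressed genes; oriented so a high score means high activity.
#  * composite protein score: sum of mean-centered phosphoprotein endpoints
#    minus the pathway inhibitor's total level (pAkt + pmTOR + pGSK3 + pS6K
#    + pS6 - PTEN).

#' Center a matrix per gene (row) across samples
#'
#' `"median"` subtracts the across-sample median per row (the mRNA
#' convention); `"mean"` subtracts the mean (the RPPA convention);
#' `"median_sd_scaled"` subtracts the median and divides by the
#' across-sample standard deviation (used when mixing array subsets with
#' different dynamic ranges). Missing values are ignored in the statistics
#' and preserved in place; all-missing rows are left as-is and counted.
#'
#' @param m numeric matrix (rows = genes or endpoints, >= 2 columns).
#' @param method centering method.
#' @return centered matrix; attributes `centering` and (for the scaled
#'   mode) no others record the method used.
#' @export
center_genes <- function(m, method = c("median", "mean", "median_sd_scaled")) {
  method <- match.arg(method)
  if (ncol(m) < 2L) stop_validation("centering needs >= 2 samples")
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) msg(sum(all_missing), " all-missing row(s) left untouched")
  ctr <- if (method == "mean") rowMeans(m, na.rm = TRUE)
         else apply(m, 1L, stats::median, na.rm = TRUE)
  out <- m - ctr
  if (method == "median_sd_scaled") {
    s <- apply(m, 1L, stats::sd, na.rm = TRUE)
    s[!is.na(s) & s == 0] <- NA_real_  # flat rows cannot be scaled
    out <- out / s
  }
  out[all_missing, ] <- NA_real_
  attr(out, "id_space") <- attr(m, "id_space")
  attr(out, "centering") <- method
  out
}

#' Signature t score of a single profile
#'
#' Two-sample pooled-variance t statistic treating the profile's values on
#' the signature's induced genes as group 1 and on the repressed genes as
#' group 2. The profile should already be centered across samples (see
#' [center_genes()]); this function does not orient the sign — see
#' [score_cohort_activity()] for activity orientation.
#'
#' @param profile named numeric vector (one sample's centered values).
#' @param sig `gene_signature`.
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @return list with `score`, `n_up_used`, `n_down_used`, `degenerate`
#'   (TRUE with `NA` score when < 2 usable genes in either arm or the
#'   pooled variance is zero).
#' @export
signature_tscore <- function(profile, sig, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(sig, "gene_signature"))
  up <- profile[intersect(sig$induced, names(profile))]
  dn <- profile[intersect(sig$repressed, names(profile))]
  up <- up[!is.na(up)]; dn <- dn[!is.na(dn)]
  n1 <- length(up); n2 <- length(dn)
  if (n1 < 2L || n2 < 2L)
    return(list(score = NA_real_, n_up_used = n1, n_down_used = n2,
                degenerate = TRUE))
  if (variance_mode == "pooled") {
    sp2 <- ((n1 - 1) * stats::var(up) + (n2 - 1) * stats::var(dn)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(stats::var(up) / n1 + stats::var(dn) / n2)
  }
  d <- mean(up) - mean(dn)
  if (se == 0) {
    if (d == 0)
      return(list(score = 0, n_up_used = n1, n_down_used = n2, degenerate = FALSE))
    return(list(score = NA_real_, n_up_used = n1, n_down_used = n2,
                degenerate = TRUE))
  }
  list(score = d / se, n_up_used = n1, n_down_used = n2, degenerate = FALSE)
}

#' Score every sample of a cohort for pathway activity
#'
#' Centers the matrix per gene, computes the signature t score per sample,
#' then orients it as *activity*: for an inhibition-derived signature the
#' score is the negated t (profiles anticorrelated with the
#' inhibitor-induced pattern have high pathway activity); for an
#' activation-derived signature the t itself.
#'
#' @param m gene-level expression matrix (log2), samples in columns.
#' @param sig `gene_signature`; must hit >= 2 matrix rows in each arm.
#' @param centering passed to [center_genes()] (default `"median"`).
#' @param variance_mode passed to [signature_tscore()].
#' @return data frame of class `activity_scores`: `sample_id`, `score`,
#'   `platform`, `n_up_used`, `n_down_used`, `degenerate`; centering and
#'   orientation recorded as attributes.
#' @export
score_cohort_activity <- function(m, sig,
                                  centering = c("median", "mean", "median_sd_scaled"),
                                  variance_mode = c("pooled", "welch")) {
  centering <- match.arg(centering)
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(sig, "gene_signature"))
  hit_up <- intersect(sig$induced, rownames(m))
  hit_dn <- intersect(sig$repressed, rownames(m))
  if (length(hit_up) < 2L || length(hit_dn) < 2L)
    stop_validation("signature maps to < 2 matrix rows in an arm (induced: ",
                    length(hit_up), ", repressed: ", length(hit_dn), ")")
  cm <- center_genes(m, centering)
  flip <- if (identical(sig$derivation_meaning, "inhibition")) -1 else 1
  rows <- lapply(colnames(cm), function(s) {
    r <- signature_tscore(cm[, s], sig, variance_mode)
    data.frame(sample_id = s, score = flip * r$score, platform = "mrna",
               n_up_used = r$n_up_used, n_down_used = r$n_down_used,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("activity_scores", "data.frame"),
            centering = centering, signature = sig$name,
            orientation = sig$derivation_meaning)
}

#' @export
print.activity_scores <- function(x, ...) {
  cat("Activity scores:", nrow(x), "samples (",
      unique(x$platform), "platform )\n")
  if (!is.null(attr(x, "centering")))
    cat("  centering:", attr(x, "centering"), "\n")
  ok <- x$score[!x$degenerate & !is.na(x$score)]
  if (length(ok))
    cat(sprintf("  score range: [%.3f, %.3f], median %.3f\n",
                min(ok), max(ok), stats::median(ok)))
  if (any(x$degenerate)) cat("  degenerate samples:", sum(x$degenerate), "\n")
  invisible(x)
}

#' Protein score panel definition
#'
#' Endpoints entering the composite protein score with +1 (phospho
#' endpoints, pathway-on) or −1 (the pathway inhibitor's total level)
#' coefficients. `akt_site_policy` resolves the single "pAkt" term of the
#' score formula from the two measured AKT phosphosites.
#'
#' @param positive_endpoints endpoints summed with +1 (default pAkt,
#'   pmTOR, pGSK3, pS6K, pS6 — "pAkt" resolved per `akt_site_policy`).
#' @param negative_endpoints endpoints subtracted (default PTEN).
#' @param akt_site_policy `"average_T308_S473"` (default), `"T308"` or
#'   `"S473"`.
#' @return list of class `protein_score_panel`.
#' @export
protein_score_panel <- function(positive_endpoints = c("pAkt", "pmTOR", "pGSK3",
                                                       "pS6K", "pS6"),
                                negative_endpoints = "PTEN",
                                akt_site_policy = c("average_T308_S473",
                                                    "T308", "S473")) {
  akt_site_policy <- match.arg(akt_site_policy)
  if (!length(positive_endpoints) || !length(negative_endpoints))
    stop_validation("both endpoint lists must be non-empty")
  if (length(intersect(positive_endpoints, negative_endpoints)))
    stop_validation("endpoint lists must be disjoint")
  structure(list(positive_endpoints = positive_endpoints,
                 negative_endpoints = negative_endpoints,
                 akt_site_policy = akt_site_policy),
            class = "protein_score_panel")
}

# Resolve the "pAkt" row from per-site measurements per the panel policy.
resolve_akt <- function(p, policy) {
  if ("pAkt" %in% rownames(p)) return(p)
  sites <- c(T308 = "pAKT_T308", S473 = "pAKT_S473")
  have <- sites[sites %in% rownames(p)]
  if (!length(have)) return(p)
  want <- if (policy == "average_T308_S473") c("T308", "S473") else policy
  lack <- setdiff(sites[want], rownames(p))
  if (length(lack))
    stop_validation("akt_site_policy '", policy, "' needs endpoint(s): ",
                    paste(lack, collapse = ", "))
  akt <- if (policy == "average_T308_S473")
    (p[sites[["T308"]], ] + p[sites[["S473"]], ]) / 2
  else p[sites[[policy]], ]
  out <- rbind(p, pAkt = akt)
  out[setdiff(rownames(out), sites), , drop = FALSE]
}

#' Composite protein activity score from an RPPA endpoint matrix
#'
#' Per-endpoint mean centering across samples (the RPPA convention) is
#' applied unless `center = FALSE`, then each sample's score is the sum of
#' the panel's positive endpoints minus the sum of its negative endpoints
#' — with the defaults, pAkt + pmTOR + pGSK3 + pS6K + pS6 − PTEN, pAkt
#' being the average of the T308 and S473 phosphosite ratios.
#'
#' @param p protein endpoint matrix (endpoints x samples, normalized RPPA
#'   units; phospho endpoints as ratios to total protein).
#' @param panel [protein_score_panel()].
#' @param center mean-center per endpoint first (default TRUE). Set FALSE
#'   only if `p` is already centered.
#' @param missing_policy per-sample handling when a panel endpoint value is
#'   missing: `"skip_sample"` (flag the sample, `NA` score) or
#'   `"renormalize"` (scale the partial sum by panel_size / n_observed).
#' @return `activity_scores` data frame (`platform = "protein"`).
#' @export
pi3k_protein_score <- function(p, panel = protein_score_panel(), center = TRUE,
                               missing_policy = c("skip_sample", "renormalize")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(panel, "protein_score_panel"))
  p <- resolve_akt(p, panel$akt_site_policy)
  need <- c(panel$positive_endpoints, panel$negative_endpoints)
  absent <- setdiff(need, rownames(p))
  if (length(absent))
    stop_validation("panel endpoints absent from matrix: ",
                    paste(absent, collapse = ", "))
  all_na <- need[rowSums(!is.na(p[need, , drop = FALSE])) == 0L]
  if (length(all_na))
    stop_validation("panel endpoints with no observed values: ",
                    paste(all_na, collapse = ", "))
  if (center) p <- center_genes(p, "mean")
  w <- c(rep(1, length(panel$positive_endpoints)),
         rep(-1, length(panel$negative_endpoints)))
  sub <- p[need, , drop = FALSE]
  contrib <- sub * w
  n_obs <- colSums(!is.na(sub))
  score <- colSums(contrib, na.rm = TRUE)
  incomplete <- n_obs < length(need)
  if (missing_policy == "skip_sample") {
    score[incomplete] <- NA_real_
  } else {
    score[incomplete] <- score[incomplete] * length(need) / n_obs[incomplete]
    score[n_obs == 0L] <- NA_real_
  }
  out <- data.frame(sample_id = colnames(p), score = unname(score),
                    platform = "protein",
                    n_up_used = NA_integer_, n_down_used = NA_integer_,
                    degenerate = unname(incomplete & missing_policy == "skip_sample"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("activity_scores", "data.frame"),
            centering = if (center) "mean" else "precentered",
            panel = panel, missing_policy = missing_policy)
}
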