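# Luminal A vs luminal B subtype assignment:
#  * mRNA: mean-centroid reference (two group averages centered on their
#    midpoint) + Pearson-correlation nearest-centroid labeling.
#  * RPPA: "luminalness" score — panel markers weighted +1 (luminal-A
#    associated: ER-function markers) or -1 (luminal-B associated: HER2,
#    apoptosis, protein-synthesis, cell-cycle markers), summed on
#    log-mean-centered values and thresholded at a fixed cutoff.

#' Build a two-group mean-centroid reference
#'
#' Per gene: `a` = mean over the luminal A samples, `b` = mean over luminal
#' B, centroid = (a + b) / 2; the stored profiles are `a - centroid` and
#' `b - centroid`, which are exact negatives of each other.
#'
#' @param ref gene-level expression matrix of the reference cohort.
#' @param lumA_ids,lumB_ids disjoint sample id vectors, each >= 2.
#' @return object of class `centroid_reference` with `gene_ids`,
#'   `lumA_profile`, `lumB_profile`, `source_label`, and a `degenerate`
#'   flag set when the two profiles are identically zero.
#' @export
build_centroid_reference <- function(ref, lumA_ids, lumB_ids,
                                     source_label = "reference") {
  lumA_ids <- as.character(lumA_ids); lumB_ids <- as.character(lumB_ids)
  if (length(intersect(lumA_ids, lumB_ids)))
    stop_validation("reference groups overlap")
  if (length(lumA_ids) < 2L || length(lumB_ids) < 2L)
    stop_validation("each reference group needs >= 2 samples")
  missing_ids <- setdiff(c(lumA_ids, lumB_ids), colnames(ref))
  if (length(missing_ids))
    stop_validation("sample ids absent from reference matrix: ",
                    paste(utils::head(missing_ids, 5L), collapse = ", "))
  a <- rowMeans(ref[, lumA_ids, drop = FALSE], na.rm = TRUE)
  b <- rowMeans(ref[, lumB_ids, drop = FALSE], na.rm = TRUE)
  centroid <- (a + b) / 2
  lumA_profile <- a - centroid
  lumB_profile <- b - centroid
  degenerate <- all(abs(lumA_profile) < 1e-12, na.rm = TRUE)
  if (degenerate) msg("centroid reference is degenerate (identical group means)")
  structure(list(gene_ids = rownames(ref), lumA_profile = unname(lumA_profile),
                 lumB_profile = unname(lumB_profile),
                 source_label = source_label, degenerate = degenerate),
            class = "centroid_reference")
}

#' @export
print.centroid_reference <- function(x, ...) {
  cat("Centroid reference (", x$source_label, "): ",
      length(x$gene_ids), " genes\n", sep = "")
  if (x$degenerate) cat("  DEGENERATE: group means identical\n")
  invisible(x)
}

#' Classify one expression profile as luminal A or B
#'
#' Pearson correlation of the profile against each centroid-centered group
#' profile, over the genes common to profile and reference with non-missing
#' values; the label is the higher correlation. Exact ties (difference
#' below 1e-12) and zero-variance profiles are returned `unclassified`.
#'
#' @param profile named numeric vector (one sample's expression).
#' @param ref [build_centroid_reference()] result.
#' @return list: `r_lumA`, `r_lumB`, `label`, `n_genes_used`, `flag`.
#' @export
classify_mrna_subtype <- function(profile, ref) {
  stopifnot(inherits(ref, "centroid_reference"))
  idx <- match(names(profile), ref$gene_ids)
  keep <- !is.na(idx) & !is.na(profile) &
    !is.na(ref$lumA_profile[idx]) & !is.na(ref$lumB_profile[idx])
  n <- sum(keep)
  if (n < 3L)
    stop_validation("need >= 3 common non-missing genes, have ", n)
  x <- as.numeric(profile[keep])
  pa <- ref$lumA_profile[idx[keep]]
  pb <- ref$lumB_profile[idx[keep]]
  if (stats::sd(x) == 0 || stats::sd(pa) == 0)
    return(list(r_lumA = NA_real_, r_lumB = NA_real_, label = "unclassified",
                n_genes_used = n, flag = "zero_variance"))
  r_a <- stats::cor(x, pa)
  r_b <- stats::cor(x, pb)
  label <- if (abs(r_a - r_b) < 1e-12) "unclassified"
           else if (r_a > r_b) "lumA" else "lumB"
  list(r_lumA = r_a, r_lumB = r_b, label = label, n_genes_used = n,
       flag = NA_character_)
}

#' Classify every sample of a cohort by centroid correlation
#'
#' Profiles are median-centered per gene across the cohort first (the same
#' convention used before signature scoring), so that each profile's
#' correlation with the centered centroid profiles reflects its deviation
#' from the cohort-typical expression; pass `centering = "none"` for
#' matrices centered upstream.
#'
#' @param m gene-level expression matrix.
#' @param ref `centroid_reference`.
#' @param centering `"median"` (default), `"mean"` or `"none"`.
#' @return data frame: `sample_id`, `r_lumA`, `r_lumB`, `label`,
#'   `n_genes_used`.
#' @export
classify_cohort_subtypes <- function(m, ref,
                                     centering = c("median", "mean", "none")) {
  centering <- match.arg(centering)
  if (centering != "none") m <- center_genes(m, centering)
  rows <- lapply(colnames(m), function(s) {
    r <- classify_mrna_subtype(m[, s], ref)
    data.frame(sample_id = s, r_lumA = r$r_lumA, r_lumB = r$r_lumB,
               label = r$label, n_genes_used = r$n_genes_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default RPPA luminalness marker panel
#'
#' Markers weighted +1 (luminal-A associated, ER-function: ER, PR, Bcl2)
#' or −1 (luminal-B associated: HER2 level and activity, cleaved caspase 7
#' and cleaved PARP, p-p70S6K and pS6, cyclin B1). Bcl2 sits in both the
#' ER-function and apoptosis marker groups and is counted once, positively.
#' Collagen VI (a stromal marker with no firmly assigned direction) is
#' excluded by default and can be added with either sign via the JSON
#' panel file. Higher score = more luminal-A-like; samples at or above the
#' cutoff (default −0.907, an externally established constant treated as
#' opaque) are called luminal A.
#'
#' @param path optional JSON file with fields `weights` (marker -> +1/-1)
#'   and `cutoff`; defaults to the panel shipped in `inst/extdata`.
#' @return list of class `luminalness_panel`: `weights` (named +1/-1
#'   vector), `cutoff`.
#' @export
luminalness_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "luminalness_panel.json",
                        package = "pathscore", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(cfg$weights)
  if (!all(w %in% c(-1, 1))) stop_validation("panel weights must be +1 or -1")
  if (!is.numeric(cfg$cutoff) || !is.finite(cfg$cutoff))
    stop_validation("panel cutoff must be a finite number")
  structure(list(weights = w, cutoff = cfg$cutoff), class = "luminalness_panel")
}

#' RPPA luminalness score and luminal A/B call for one sample
#'
#' `score = sum(weight_m * value_m)` over the panel markers; values are
#' expected log-mean-centered per endpoint (see [center_genes()] with
#' `"mean"`). `label = "lumA"` when `score >= cutoff` (the boundary goes to
#' luminal A), else `"lumB"`. A sample missing more than 25% of the panel
#' markers is `unclassified`.
#'
#' @param values named numeric vector: one sample's centered marker values.
#' @param panel [luminalness_panel()].
#' @return list: `score`, `label`, `n_markers_used`, `flag`.
#' @export
rppa_luminalness <- function(values, panel = luminalness_panel()) {
  stopifnot(inherits(panel, "luminalness_panel"))
  w <- panel$weights
  v <- values[names(w)]
  used <- !is.na(v)
  if (mean(!used) > 0.25)
    return(list(score = NA_real_, label = "unclassified",
                n_markers_used = sum(used), flag = "too_many_missing"))
  score <- sum(w[used] * v[used])
  list(score = score,
       label = if (score >= panel$cutoff) "lumA" else "lumB",
       n_markers_used = sum(used), flag = NA_character_)
}

#' Luminalness calls for every sample of an RPPA matrix
#'
#' @param p protein matrix (markers x samples); mean-centered per endpoint
#'   internally unless `center = FALSE`.
#' @param panel [luminalness_panel()].
#' @param center mean-center per endpoint first (default TRUE).
#' @return data frame: `sample_id`, `score`, `label`, `n_markers_used`.
#' @export
classify_rppa_cohort <- function(p, panel = luminalness_panel(), center = TRUE) {
  absent <- setdiff(names(panel$weights), rownames(p))
  if (length(absent))
    stop_validation("panel markers absent from matrix: ",
                    paste(absent, collapse = ", "))
  if (center) p <- center_genes(p, "mean")
  rows <- lapply(colnames(p), function(s) {
    r <- rppa_luminalness(p[, s], panel)
    data.frame(sample_id = s, score = r$score, label = r$label,
               n_markers_used = r$n_markers_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
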