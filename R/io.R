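# File I/O and core data containers: expression / protein matrices (TSV),
# gene signatures (GMT), sample annotations (TSV), probe-to-gene maps and
# JSON configuration.
#
# Matrices are plain numeric matrices with unique rownames (genes, probes or
# protein endpoints) and unique colnames (samples); log2 scale is assumed for
# expression. An "id_space" attribute ("probe" or "gene") records what the
# rows of an expression matrix identify.

#' Construct and validate an expression matrix
#'
#' @param values numeric matrix (log2 units; `NA` allowed) with rownames
#'   (gene or probe identifiers) and colnames (sample identifiers).
#' @param id_space `"gene"` or `"probe"` — what the row identifiers are.
#' @return The validated matrix, carrying an `id_space` attribute.
#' @export
expression_matrix <- function(values, id_space = c("gene", "probe")) {
  id_space <- match.arg(id_space)
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("values must have row and column names")
  check_unique(rownames(values), "row identifiers")
  check_unique(colnames(values), "sample identifiers")
  attr(values, "id_space") <- id_space
  values
}

#' @rdname expression_matrix
#' @export
id_space <- function(values) {
  sp <- attr(values, "id_space")
  if (is.null(sp)) "gene" else sp
}

#' Read a tab-separated expression or protein matrix
#'
#' Expects a header row of sample identifiers and row identifiers in the
#' first column; blank cells and `NA` become missing values. Ragged rows are
#' a format error; duplicated row or column identifiers are a validation
#' error.
#'
#' @param path file path.
#' @param id_space `"gene"` or `"probe"` (use `"gene"` for protein endpoint
#'   matrices; endpoint names live in the rownames either way).
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` to raw-scale input.
#' @return numeric matrix with `id_space` attribute.
#' @export
read_expression_table <- function(path, id_space = c("gene", "probe"),
                                  log2_transform = FALSE) {
  id_space <- match.arg(id_space)
  if (!file.exists(path)) stop_format("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) stop_format("matrix file needs a header and >= 1 row: ", path)
  if (length(unique(nf)) != 1L)
    stop_format("ragged TSV (rows have differing field counts): ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  row_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
  }
  rownames(vals) <- row_ids
  colnames(vals) <- names(df)[-1L]  # undo make.unique from `[.data.frame`
  if (log2_transform) {
    if (any(vals < 0, na.rm = TRUE))
      stop_validation("log2_transform requested but matrix has negative values")
    vals <- log2(vals + 1)
  }
  expression_matrix(vals, id_space)
}

#' Write a matrix as TSV (row ids in column 1, `NA` for missing)
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header for the row-identifier column.
#' @export
write_expression_table <- function(m, path, id_column = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a gene signature
#'
#' A signature is a pair of disjoint gene sets. `derivation_meaning` records
#' what "induced" means: `"inhibition"` if the sets came from an inhibitor
#' contrast (so induced genes mark *low* pathway activity and scoring must
#' flip the sign), `"activation"` otherwise.
#'
#' @param name signature name.
#' @param induced,repressed character vectors of gene identifiers.
#' @param derivation_meaning `"inhibition"` or `"activation"`.
#' @param per_gene_stats optional data frame of per-gene statistics
#'   (columns `gene_id`, `mean_diff`, `t_stat`, `p_value`, `q_value`).
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, induced, repressed,
                           derivation_meaning = c("inhibition", "activation"),
                           per_gene_stats = NULL) {
  derivation_meaning <- match.arg(derivation_meaning)
  induced <- unique(as.character(induced))
  repressed <- unique(as.character(repressed))
  both <- intersect(induced, repressed)
  if (length(both))
    stop_validation("genes in both induced and repressed sets: ",
                    paste(utils::head(both, 5L), collapse = ", "))
  structure(
    list(name = as.character(name), induced = induced, repressed = repressed,
         derivation_meaning = derivation_meaning,
         per_gene_stats = per_gene_stats),
    class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature:", x$name, "\n")
  cat("  induced:  ", length(x$induced), "genes\n")
  cat("  repressed:", length(x$repressed), "genes\n")
  cat("  derivation meaning:", x$derivation_meaning,
      if (identical(x$derivation_meaning, "inhibition"))
        "(high activity = anticorrelated with signature)" else "", "\n")
  if (!is.null(x$per_gene_stats))
    cat("  per-gene stats for", nrow(x$per_gene_stats), "genes attached\n")
  invisible(x)
}

#' Read a gene signature from a two-line GMT file
#'
#' Expects lines named `<name>_UP` and `<name>_DN` (tab-separated: set name,
#' description, then genes). UP genes become the induced set, DN the
#' repressed set.
#'
#' @param path GMT file path.
#' @param derivation_meaning passed to [gene_signature()].
#' @return `gene_signature`.
#' @export
read_signature_gmt <- function(path,
                               derivation_meaning = c("inhibition", "activation")) {
  derivation_meaning <- match.arg(derivation_meaning)
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  set_names <- vapply(parts, `[[`, "", 1L)
  up_i <- grep("_UP$", set_names)
  dn_i <- grep("_DN$", set_names)
  if (length(up_i) != 1L || length(dn_i) != 1L)
    stop_format("GMT must contain exactly one <name>_UP and one <name>_DN line")
  get_genes <- function(p) {
    if (length(p) < 3L) character(0) else unique(p[-(1:2)])
  }
  name_up <- sub("_UP$", "", set_names[up_i])
  name_dn <- sub("_DN$", "", set_names[dn_i])
  if (!identical(name_up, name_dn))
    stop_format("UP/DN line names disagree: ", name_up, " vs ", name_dn)
  gene_signature(name_up,
                 induced = get_genes(parts[[up_i]]),
                 repressed = get_genes(parts[[dn_i]]),
                 derivation_meaning = derivation_meaning)
}

#' Write a gene signature as a two-line GMT file
#'
#' @param sig `gene_signature`.
#' @param path output path.
#' @export
write_signature_gmt <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  desc <- paste0("derivation_meaning=", sig$derivation_meaning)
  lines <- c(paste(c(paste0(sig$name, "_UP"), desc, sig$induced), collapse = "\t"),
             paste(c(paste0(sig$name, "_DN"), desc, sig$repressed), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with a `sample_id` column (or row ids in column 1) and optional
#' `er_level`, `pr_level`, `subtype_label`, `cohort_id` columns. Missing ER
#' or PR levels stay `NA`.
#'
#' @param path TSV path.
#' @return data frame with one row per sample.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  check_unique(df$sample_id, "sample identifiers")
  if ("subtype_label" %in% names(df)) {
    bad <- setdiff(stats::na.omit(unique(df$subtype_label)),
                   c("lumA", "lumB", "unclassified"))
    if (length(bad))
      stop_validation("unknown subtype labels: ", paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_annotations
#' @param ann annotation data frame.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Drop named samples from a matrix
#'
#' Annotation-driven cohort filter, e.g. for removing tumors duplicated
#' between merged cohorts before computing correlations.
#'
#' @param m matrix with sample columns.
#' @param ids sample identifiers to remove; ids absent from `m` are ignored
#'   with a message.
#' @return the filtered matrix.
#' @export
drop_samples <- function(m, ids) {
  ids <- as.character(ids)
  absent <- setdiff(ids, colnames(m))
  if (length(absent)) msg(length(absent), " sample id(s) to drop not present")
  keep <- setdiff(colnames(m), ids)
  if (!length(keep)) stop_validation("dropping all samples leaves an empty matrix")
  m2 <- m[, keep, drop = FALSE]
  attr(m2, "id_space") <- attr(m, "id_space")
  m2
}

#' Read / write a probe-to-gene map
#'
#' TSV with columns `probe_id`, `gene_id` and optional logical `override`
#' marking a probe pinned as *the* representative for its gene (the
#' convention used to pin one fixed probe set for a gene such as ER across
#' array datasets). Each probe maps to exactly one gene.
#'
#' @param path TSV path.
#' @return data frame `probe_id`, `gene_id`, `override`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  probe_map(df$probe_id, df$gene_id,
            overrides = if ("override" %in% names(df))
              df$probe_id[isTRUE_vec(df$override)] else character(0))
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

#' @rdname read_probe_map
#' @param probe_id,gene_id parallel character vectors (many probes to one gene).
#' @param overrides probes pinned as the representative for their gene; at
#'   most one per gene.
#' @export
probe_map <- function(probe_id, gene_id, overrides = character(0)) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  if (length(probe_id) != length(gene_id))
    stop_validation("probe_id and gene_id lengths differ")
  check_unique(probe_id, "probe identifiers")
  overrides <- as.character(overrides)
  missing_ov <- setdiff(overrides, probe_id)
  if (length(missing_ov))
    stop_validation("override probes absent from map: ",
                    paste(missing_ov, collapse = ", "))
  ov_genes <- gene_id[match(overrides, probe_id)]
  check_unique(ov_genes, "override target genes")
  df <- data.frame(probe_id = probe_id, gene_id = gene_id,
                   override = probe_id %in% overrides,
                   stringsAsFactors = FALSE)
  class(df) <- c("probe_map", "data.frame")
  df
}

#' Collapse a probe-level matrix to gene level
#'
#' Genes measured by several probe sets keep exactly one probe's row, picked
#' by a seeded uniform draw so a published run can be replayed; probes
#' marked `override` in the map always win for their gene. Probes absent
#' from the map are dropped (count logged).
#'
#' @param m probe-level matrix (`id_space` `"probe"`).
#' @param map [probe_map()] data frame.
#' @param seed integer seed for the per-gene probe draw; recorded in the
#'   output's `collapse_seed` attribute.
#' @return gene-level matrix (`id_space` `"gene"`).
#' @export
collapse_probes_to_genes <- function(m, map, seed = 1L) {
  if (identical(id_space(m), "gene")) return(m)  # idempotent on gene-level input
  probes <- rownames(m)
  known <- probes %in% map$probe_id
  if (any(!known)) msg(sum(!known), " probe(s) absent from map; dropped")
  probes <- probes[known]
  if (!length(probes)) stop_validation("no probes left after map filtering")
  genes <- map$gene_id[match(probes, map$probe_id)]
  override <- map$override[match(probes, map$probe_id)]
  # deterministic iteration order: sorted gene ids
  chosen <- with_seed(seed, {
    vapply(split(seq_along(probes), genes), function(idx) {
      ov <- idx[override[idx]]
      if (length(ov) >= 1L) return(probes[ov[1L]])
      if (length(idx) == 1L) return(probes[idx])
      probes[idx][sample.int(length(idx), 1L)]
    }, character(1L))
  })
  out <- m[chosen, , drop = FALSE]
  rownames(out) <- names(chosen)
  out <- expression_matrix(out, "gene")
  attr(out, "collapse_seed") <- as.integer(seed)
  out
}

#' Read a JSON configuration file
#'
#' @param path JSON path.
#' @return named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
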