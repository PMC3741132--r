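# Domain model: polymorphism panels, cohort tables, and the coding schemes
# that turn a cohort into numeric design matrices.
#
# A cohort is an ordinary data.frame with columns
#   subject_id, group, <one column per panel polymorphism>, folate,
#   homocysteine, vitamin_b12
# where group is "AD" or "control", genotype columns hold three-level
# genotype strings (e.g. "CC"/"CT"/"TT") and the biomarkers are
# non-negative (folate ng/ml, homocysteine umol/l, vitamin B12 pg/ml).

BIOMARKERS <- c("folate", "homocysteine", "vitamin_b12")
GENO_SUFFIX <- c("wild_type", "heterozygous", "mutant")

#' Define a panel of biallelic polymorphisms
#'
#' Each polymorphism is biallelic, yielding three genotype classes: wild
#' type (major homozygous), heterozygous, and mutant (minor homozygous).
#'
#' @param df Data frame with columns `name`, `rsid`, `wild`, `het`, `mut`.
#' @return The validated data frame with class `"ocm_panel"`.
#' @export
polymorphism_panel <- function(df) {
  need <- c("name", "rsid", "wild", "het", "mut")
  if (!all(need %in% names(df)))
    ocm_stop("panel must have columns %s", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$name))
    ocm_stop("panel polymorphism names must be unique")
  for (i in seq_len(nrow(df))) {
    labs <- c(df$wild[i], df$het[i], df$mut[i])
    if (anyDuplicated(labs))
      ocm_stop("polymorphism '%s': genotype labels must be pairwise distinct",
               df$name[i])
  }
  class(df) <- c("ocm_panel", "data.frame")
  df
}

#' Load a polymorphism panel from JSON
#'
#' The JSON is a list of objects `{name, rsid, wild, het, mut}`.
#'
#' @param path Path to the JSON file.
#' @return An `ocm_panel`.
#' @export
read_panel <- function(path) {
  polymorphism_panel(jsonlite::fromJSON(path))
}

#' The packaged nine-polymorphism one-carbon metabolism panel
#'
#' MTHFR 677C>T and 1298A>C, TYMS 28-bp repeat and 1494 6-bp ins/del,
#' MTRR 66A>G, MTR 2756A>G, RFC1 (SLC19A1) 80G>A, and DNMT3B -149C>T and
#' -579G>T, with their dbSNP identifiers and genotype labels.
#'
#' @return An `ocm_panel` with 9 rows.
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "panel_one_carbon.json",
                         package = "ocmann", mustWork = TRUE))
}

#' Validate a cohort data frame against a panel
#'
#' Checks the column set, class labels, genotype vocabulary and biomarker
#' ranges.  Missing values are rejected, not imputed.
#'
#' @param cohort Cohort data frame (see package overview for the schema).
#' @param panel An `ocm_panel`.
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   offending subject and column.
#' @export
validate_cohort <- function(cohort, panel = default_panel()) {
  need <- c("subject_id", "group", panel$name, BIOMARKERS)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    ocm_stop("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) == 0) ocm_stop("cohort has no records")
  check_labels(cohort$group)
  for (i in seq_len(nrow(panel))) {
    labs <- c(panel$wild[i], panel$het[i], panel$mut[i])
    g <- as.character(cohort[[panel$name[i]]])
    bad <- which(is.na(g) | !(g %in% labs))
    if (length(bad) > 0)
      ocm_stop("subject '%s' (row %d): genotype '%s' is not a valid %s genotype (expected %s)",
               cohort$subject_id[bad[1]], bad[1], g[bad[1]], panel$name[i],
               paste(labs, collapse = "/"))
  }
  for (b in BIOMARKERS) {
    x <- cohort[[b]]
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0)
      ocm_stop("subject '%s' (row %d): %s must be finite and non-negative (got %s)",
               cohort$subject_id[bad[1]], bad[1], b, format(x[bad[1]]))
  }
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' UTF-8 CSV with header `subject_id, group, <polymorphisms>, folate,
#' homocysteine, vitamin_b12`.
#'
#' @param path File path.
#' @param panel Panel used for validation.
#' @return `read_cohort` returns the validated cohort data frame.
#' @export
read_cohort <- function(path, panel = default_panel()) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  for (b in BIOMARKERS) if (b %in% names(cohort))
    cohort[[b]] <- as.numeric(cohort[[b]])
  validate_cohort(cohort, panel)
  cohort
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- design matrices -------------------------------------------------------

# A design matrix is a numeric matrix in [0,1] with attributes:
#   provenance   character per column: "genotype-indicator",
#                "scaled-biomarker", "complement-biomarker", "class-indicator"
#   class_labels character per row ("AD"/"control"), when carried
#   scaling      named list biomarker -> c(min, max) used for min-max scaling
new_design <- function(values, provenance, class_labels = NULL, scaling = NULL) {
  stopifnot(is.matrix(values), length(provenance) == ncol(values))
  if (any(!is.finite(values)) || any(values < -1e-12) || any(values > 1 + 1e-12))
    ocm_stop("design matrix entries must lie in [0, 1]")
  structure(values,
            provenance = provenance,
            class_labels = class_labels,
            scaling = scaling,
            class = c("ocm_design", "matrix", "array"))
}

#' @export
print.ocm_design <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("design matrix: %d records x %d columns\n", nrow(x), ncol(x)))
  print(table(provenance = prov))
  invisible(x)
}

#' One-hot encode the genotype block of a cohort
#'
#' Each polymorphism contributes three indicator columns
#' `<name>_wild_type`, `<name>_heterozygous`, `<name>_mutant`; a column is
#' 1 if the variable (genotype class) is present in the record and 0 if
#' absent, so the triple is one-hot per record.  Column order follows the
#' panel order, then wild/het/mut within a polymorphism.
#'
#' @param cohort Cohort data frame.
#' @param panel An `ocm_panel`.
#' @return An `ocm_design` matrix with `3 * nrow(panel)` indicator columns.
#' @export
encode_genotypes <- function(cohort, panel = default_panel()) {
  validate_cohort(cohort, panel)
  n <- nrow(cohort)
  blocks <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    labs <- c(panel$wild[i], panel$het[i], panel$mut[i])
    g <- as.character(cohort[[panel$name[i]]])
    m <- matrix(0, n, 3,
                dimnames = list(NULL, paste(panel$name[i], GENO_SUFFIX, sep = "_")))
    m[cbind(seq_len(n), match(g, labs))] <- 1
    blocks[[i]] <- m
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- cohort$subject_id
  new_design(values,
             provenance = rep("genotype-indicator", ncol(values)),
             class_labels = check_labels(cohort$group))
}

#' Recover genotype strings from a one-hot genotype block
#'
#' Inverse of [encode_genotypes()]: each indicator triple is mapped back to
#' its genotype label.
#'
#' @param design Genotype-indicator design matrix.
#' @param panel The panel used for encoding.
#' @return Data frame of genotype strings, one column per polymorphism.
#' @export
decode_genotypes <- function(design, panel = default_panel()) {
  out <- vector("list", nrow(panel))
  names(out) <- panel$name
  for (i in seq_len(nrow(panel))) {
    cols <- paste(panel$name[i], GENO_SUFFIX, sep = "_")
    block <- unclass(design)[, cols, drop = FALSE]
    if (any(abs(rowSums(block) - 1) > 1e-9))
      ocm_stop("genotype block for %s is not one-hot", panel$name[i])
    labs <- c(panel$wild[i], panel$het[i], panel$mut[i])
    out[[i]] <- labs[max.col(block, ties.method = "first")]
  }
  as.data.frame(out, check.names = FALSE)
}

#' Min-max scale cohort biomarkers to \[0, 1\]
#'
#' Scaling is `(x - min) / (max - min)` over the pooled cohort (cases and
#' controls together), so between-group differences are preserved.  The
#' per-biomarker min/max are stored in the result's `scaling` attribute so
#' the affine map can be inverted.
#'
#' @param cohort Cohort data frame.
#' @param which Biomarkers to scale (default all three).
#' @return An `ocm_design` with one `scaled-biomarker` column per biomarker.
#' @export
scale_biomarkers <- function(cohort, which = BIOMARKERS) {
  bad <- setdiff(which, BIOMARKERS)
  if (length(bad) > 0) ocm_stop("unknown biomarker(s): %s", paste(bad, collapse = ", "))
  if (nrow(cohort) == 0) ocm_stop("cohort has no records")
  scaling <- list()
  cols <- lapply(which, function(b) {
    x <- as.numeric(cohort[[b]])
    if (any(!is.finite(x))) ocm_stop("%s contains non-finite values", b)
    rng <- range(x)
    if (diff(rng) == 0)
      ocm_stop("cannot scale %s: constant column (zero range)", b)
    scaling[[b]] <<- c(min = rng[1], max = rng[2])
    (x - rng[1]) / (rng[2] - rng[1])
  })
  values <- do.call(cbind, cols)
  colnames(values) <- which
  rownames(values) <- cohort$subject_id
  new_design(values, provenance = rep("scaled-biomarker", length(which)),
             class_labels = if ("group" %in% names(cohort)) check_labels(cohort$group),
             scaling = scaling)
}

#' Invert min-max scaling using the stored bounds
#'
#' @param design A design matrix produced by [scale_biomarkers()].
#' @return Matrix of raw biomarker values.
#' @export
unscale_biomarkers <- function(design) {
  scaling <- attr(design, "scaling")
  if (is.null(scaling)) ocm_stop("design carries no scaling bounds")
  out <- unclass(design)[, names(scaling), drop = FALSE]
  for (b in names(scaling)) {
    rng <- scaling[[b]]
    out[, b] <- out[, b] * (rng["max"] - rng["min"]) + rng["min"]
  }
  out
}

#' Add complement columns to a \[0, 1\] block
#'
#' For each column `x` (scaled from zero to 1) a complement column
#' `<x>_LOW` with value `1 - x` is appended, doubling the column count.
#' Low-biomarker states thereby become explicit nodes in the association
#' map (e.g. `folate_LOW` for reduced folates).
#'
#' @param design An `ocm_design` (or numeric matrix) with entries in \[0, 1\].
#' @return An `ocm_design` with the original columns followed by their
#'   complements.
#' @export
add_complements <- function(design) {
  values <- unclass(design)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    ocm_stop("complement coding requires entries in [0, 1]")
  comp <- 1 - values
  colnames(comp) <- paste0(colnames(values), "_LOW")
  prov <- attr(design, "provenance") %||% rep("scaled-biomarker", ncol(values))
  new_design(cbind(values, comp),
             provenance = c(prov, rep("complement-biomarker", ncol(values))),
             class_labels = attr(design, "class_labels"),
             scaling = attr(design, "scaling"))
}

#' Assemble the 30-column classification matrix
#'
#' 27 genotype indicator columns (9 polymorphisms x 3 classes) followed by
#' the 3 min-max-scaled biomarkers: the 30 genetic and biochemical input
#' variables used by the supervised learners.  Class labels are carried in
#' the `class_labels` attribute, not as input columns.
#'
#' @param cohort Cohort data frame.
#' @param panel An `ocm_panel`.
#' @return An `ocm_design` with 30 columns.
#' @export
assemble_classification_matrix <- function(cohort, panel = default_panel()) {
  geno <- encode_genotypes(cohort, panel)
  biom <- scale_biomarkers(cohort)
  new_design(cbind(unclass(geno), unclass(biom)),
             provenance = c(attr(geno, "provenance"), attr(biom, "provenance")),
             class_labels = attr(geno, "class_labels"),
             scaling = attr(biom, "scaling"))
}

#' Assemble the 35-column Auto-CM input matrix
#'
#' The classification variables plus the biomarker complements and two
#' one-hot class indicator columns (`AD`, `control`), so the class itself
#' participates as a node in the association map: 27 + 3 + 3 + 2 = 35
#' columns, all in \[0, 1\].
#'
#' @inheritParams assemble_classification_matrix
#' @return An `ocm_design` with 35 columns.
#' @export
assemble_autocm_matrix <- function(cohort, panel = default_panel()) {
  geno <- encode_genotypes(cohort, panel)
  biom <- add_complements(scale_biomarkers(cohort))
  labels <- attr(geno, "class_labels")
  cls <- cbind(AD = as.numeric(labels == "AD"),
               control = as.numeric(labels == "control"))
  new_design(cbind(unclass(geno), unclass(biom), cls),
             provenance = c(attr(geno, "provenance"), attr(biom, "provenance"),
                            rep("class-indicator", 2)),
             class_labels = labels,
             scaling = attr(biom, "scaling"))
}

#' Write / read a design matrix as CSV with a provenance sidecar
#'
#' The matrix goes to `<path>` as CSV (row names = subject ids when
#' present); column provenance, class labels and scaling bounds go to
#' `<path>.json`.
#'
#' @param design An `ocm_design`.
#' @param path CSV path.
#' @return `read_design` returns the reconstructed `ocm_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(unclass(design)), path, row.names = TRUE)
  meta <- list(provenance = attr(design, "provenance"),
               class_labels = attr(design, "class_labels"),
               scaling = attr(design, "scaling"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  scaling <- NULL
  if (!is.null(meta$scaling) && length(meta$scaling) > 0)
    scaling <- lapply(meta$scaling, function(v) {
      v <- unlist(v)
      names(v) <- c("min", "max")
      v
    })
  new_design(as.matrix(df),
             provenance = unlist(meta$provenance),
             class_labels = if (length(meta$class_labels)) unlist(meta$class_labels),
             scaling = scaling)
}
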