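# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

ocm_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Class labels used throughout the package
#'
#' The binary outcome is coded as `"control"` / `"AD"`.  `"control"` sorts
#' first; deterministic tie-breaks (e.g. an even class vote in KNN) resolve
#' to the lower-ordered label.
#'
#' @return Character vector `c("control", "AD")`.
#' @export
group_levels <- function() c("control", "AD")

# Validate a vector of class labels, returning it as character.
check_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), group_levels())
  if (length(bad) > 0)
    ocm_stop("unknown class label(s): %s (expected %s)",
             paste(bad, collapse = ", "), paste(group_levels(), collapse = "/"))
  labels
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' One global seed drives a whole study run; each pipeline stage receives a
#' deterministic seed derived from it so stages can be rerun in isolation.
#' The scheme is `(seed * 7919 + stage_index) mod (2^31 - 1)` (7919 is the
#' 1000th prime; the modulus keeps the result a valid 32-bit integer seed).
#'
#' @param seed Integer global seed.
#' @param stage Stage name, one of `"simulate"`, `"encode"`, `"battery30"`,
#'   `"split30"`, `"twist"`, `"battery16"`, `"autocm"`.
#' @return Integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "encode", "battery30", "split30",
              "twist", "battery16", "autocm")
  idx <- match(stage, stages)
  if (is.na(idx)) ocm_stop("unknown stage '%s'", stage)
  as.integer((as.numeric(seed) * 7919 + idx) %% 2147483647)
}

# round-half-up percent formatting as used in the report tables ("93.83%")
fmt_pct <- function(x) sprintf("%.2f%%", x)
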