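# Synthetic cohort generator.
#
# The study's subject-level data are not deposited; what is published is a
# per-group summary table: genotype percentages for the nine polymorphisms
# and mean with 95% CI for the three biomarkers, at n = 40 per group.  This
# module turns that summary into a generative model so every downstream
# stage can be exercised on data with the same marginal structure.
#
# Biomarkers are drawn from a lognormal distribution moment-matched to the
# printed mean and the CI-derived standard deviation: draws are strictly
# positive and the printed mean is preserved in expectation (a zero-
# truncated normal would inflate it).  Optional joint structure (e.g. the
# folate/homocysteine inverse correlation reported across the literature)
# is injected through a Gaussian copula on the latent draws, leaving the
# marginals untouched.

#' Convert a 95% CI half-width to a standard deviation
#'
#' The published summary prints each biomarker as mean and 95% CI; the CI
#' column is read as the half-width of a symmetric normal-theory interval
#' at the group size, so `sd = half_width * sqrt(n) / 1.959964`.
#'
#' @param half_width CI half-width, same units as the mean; must be > 0.
#' @param n Group size used for the interval; must be >= 2.
#' @return The implied standard deviation.
#' @export
derive_sd <- function(half_width, n) {
  if (any(half_width <= 0)) ocm_stop("half_width must be positive")
  if (any(n < 2)) ocm_stop("n must be >= 2")
  half_width * sqrt(n) / 1.959964
}

#' Per-group marginal distributions for cohort generation
#'
#' @param genotype_freqs Named list, one entry per polymorphism: numeric
#'   triple (wild, het, mut) of probabilities or percentages; renormalized
#'   to sum to 1 (printed percentages may miss 100 by rounding).
#' @param biomarker_params Named list over `folate`, `homocysteine`,
#'   `vitamin_b12`: each `list(mean =, ci_half_width =, n =)`.
#' @return A `group_marginals` object with normalized genotype triples and
#'   derived biomarker standard deviations.
#' @export
group_marginals <- function(genotype_freqs, biomarker_params) {
  freqs <- lapply(genotype_freqs, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3 || any(p < 0) || sum(p) == 0)
      ocm_stop("each genotype triple must be 3 non-negative numbers, not all zero")
    stats::setNames(p / sum(p), GENO_SUFFIX)
  })
  params <- lapply(biomarker_params, function(b) {
    b$sd <- derive_sd(b$ci_half_width, b$n)
    b
  })
  structure(list(genotype_freqs = freqs, biomarker_params = params),
            class = "group_marginals")
}

#' Packaged per-group parameterization of the study summary table
#'
#' Biomarker means and 95% CI half-widths (n = 40 per group): AD folate
#' 6.2 (1.8) ng/ml vs control 6.8 (1.2); AD homocysteine 22.3 (4.7) umol/l
#' vs control 16.2 (1.7); AD vitamin B12 401.3 (78.2) pg/ml vs control
#' 404.9 (73.5).  Genotype triples are the printed percentages,
#' renormalized to sum to 1.
#'
#' @return List with elements `AD` and `control`, each a `group_marginals`.
#' @export
table1_marginals <- function() {
  n <- 40
  ad_geno <- list(
    MTHFR_C677T  = c(28, 40, 32),
    MTHFR_A1298C = c(45, 55, 0),
    TYMS_28bp    = c(32, 45, 23),
    TYMS_6bp     = c(15, 57, 28),
    MTRR_A66G    = c(23, 43, 35),
    MTR_A2756G   = c(82, 15, 3),
    RFC1_A80G    = c(22, 60, 18),
    DNMT3B_149CT = c(45, 47, 8),
    DNMT3B_579GT = c(48, 47, 5))
  ctrl_geno <- list(
    MTHFR_C677T  = c(38, 47, 15),
    MTHFR_A1298C = c(60, 40, 0),
    TYMS_28bp    = c(20, 57, 23),
    TYMS_6bp     = c(35, 53, 13),
    MTRR_A66G    = c(25, 52, 23),
    MTR_A2756G   = c(87, 13, 0),
    RFC1_A80G    = c(10, 62, 28),
    DNMT3B_149CT = c(50, 40, 10),
    DNMT3B_579GT = c(62, 28, 10))
  ad_biom <- list(
    folate      = list(mean = 6.2,   ci_half_width = 1.8,  n = n),
    homocysteine= list(mean = 22.3,  ci_half_width = 4.7,  n = n),
    vitamin_b12 = list(mean = 401.3, ci_half_width = 78.2, n = n))
  ctrl_biom <- list(
    folate      = list(mean = 6.8,   ci_half_width = 1.2,  n = n),
    homocysteine= list(mean = 16.2,  ci_half_width = 1.7,  n = n),
    vitamin_b12 = list(mean = 404.9, ci_half_width = 73.5, n = n))
  list(AD = group_marginals(ad_geno, ad_biom),
       control = group_marginals(ctrl_geno, ctrl_biom))
}

# ---- coupling --------------------------------------------------------------

#' Pairwise rank-correlation targets for the generator
#'
#' Joint structure the marginals alone cannot encode: each row requests a
#' Spearman correlation between two generator dimensions within each group.
#' Dimensions are biomarker names or polymorphism names (interpreted as
#' wild < het < mut genotype dosage on the latent scale).
#'
#' @param var1,var2 Character vectors of dimension names.
#' @param rho Target Spearman correlations in (-1, 1).
#' @return A `coupling_spec` data frame; empty spec means independence.
#' @export
coupling_spec <- function(var1 = character(), var2 = character(), rho = numeric()) {
  stopifnot(length(var1) == length(var2), length(var1) == length(rho))
  if (any(abs(rho) >= 1)) ocm_stop("rank correlations must lie in (-1, 1)")
  if (any(var1 == var2)) ocm_stop("coupling requires two distinct variables")
  structure(data.frame(var1 = as.character(var1), var2 = as.character(var2),
                       rho = as.numeric(rho), stringsAsFactors = FALSE),
            class = c("coupling_spec", "data.frame"))
}

#' Literature-motivated coupling preset
#'
#' Encodes the inverse folate/homocysteine and positive folate/B12
#' relationships reported across one-carbon metabolism studies, at
#' conventional magnitude 0.5.  Strengths are a package choice, not
#' published estimates.
#'
#' @return A `coupling_spec`.
#' @export
coupling_preset_literature <- function() {
  coupling_spec(var1 = c("folate", "folate"),
                var2 = c("homocysteine", "vitamin_b12"),
                rho = c(-0.5, 0.5))
}

# Nearest positive semi-definite repair by eigenvalue clipping, keeping a
# unit diagonal.
nearest_psd <- function(R, eps = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(e$values >= eps)) return(R)
  vals <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2
}

# Build the latent Gaussian correlation matrix over the generator
# dimensions.  Spearman targets are converted to latent Pearson
# correlations via r = 2 sin(pi * rho_s / 6) (exact for the continuous
# margins; approximate for the discretized genotype dosages).
coupling_matrix <- function(coupling, dims) {
  R <- diag(length(dims))
  dimnames(R) <- list(dims, dims)
  if (is.null(coupling) || nrow(coupling) == 0) return(R)
  for (i in seq_len(nrow(coupling))) {
    a <- coupling$var1[i]; b <- coupling$var2[i]
    if (!(a %in% dims) || !(b %in% dims))
      ocm_stop("coupling names unknown generator dimension: %s / %s", a, b)
    r <- 2 * sin(pi * coupling$rho[i] / 6)
    R[a, b] <- R[b, a] <- r
  }
  R <- nearest_psd(R)
  if (any(!is.finite(R))) ocm_stop("coupling matrix could not be repaired to PSD")
  R
}

# Lognormal parameters matching a target mean m and sd s.
lognormal_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Draw one group's worth of subjects from its marginals.
draw_group <- function(marg, n, group, coupling, id_prefix) {
  bio_names <- names(marg$biomarker_params)
  geno_names <- names(marg$genotype_freqs)
  dims <- c(bio_names, geno_names)
  R <- coupling_matrix(coupling, dims)
  L <- chol(nearest_psd(R))
  Z <- matrix(stats::rnorm(n * length(dims)), n) %*% L
  colnames(Z) <- dims
  U <- stats::pnorm(Z)
  rec <- list(subject_id = sprintf("%s%04d", id_prefix, seq_len(n)),
              group = rep(group, n))
  for (g in geno_names) {
    p <- marg$genotype_freqs[[g]]
    labs_idx <- findInterval(U[, g], cumsum(p), left.open = TRUE) + 1L
    labs_idx <- pmin(labs_idx, 3L)  # guard against cumsum rounding at 1
    rec[[g]] <- labs_idx  # dosage index 1/2/3; mapped to labels later
  }
  for (b in bio_names) {
    pars <- marg$biomarker_params[[b]]
    lp <- lognormal_params(pars$mean, pars$sd)
    rec[[b]] <- stats::qlnorm(U[, b], meanlog = lp$meanlog, sdlog = lp$sdlog)
  }
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Generate a synthetic case-control cohort
#'
#' Genotypes are drawn categorically from each group's normalized triples;
#' biomarkers from a moment-matched lognormal (positivity guaranteed, the
#' published mean preserved in expectation); optional coupling is applied
#' through a Gaussian copula on the latent draws.  Fully reproducible
#' given `seed`.
#'
#' @param marginals_ad,marginals_control `group_marginals` for the two
#'   groups (default: the packaged study parameterization).
#' @param n_per_group Number of subjects per group.
#' @param seed Integer seed.
#' @param coupling A [coupling_spec()] or `NULL` for independence.
#' @param panel Panel supplying genotype labels (must cover the marginals'
#'   polymorphisms).
#' @return A cohort data frame of `2 * n_per_group` records (AD first).
#' @export
generate_cohort <- function(marginals_ad = table1_marginals()$AD,
                            marginals_control = table1_marginals()$control,
                            n_per_group = 40, seed = 1, coupling = NULL,
                            panel = default_panel()) {
  if (n_per_group < 1) ocm_stop("n_per_group must be >= 1")
  with_seed(seed, {
    ad <- draw_group(marginals_ad, n_per_group, "AD", coupling, "AD_")
    ct <- draw_group(marginals_control, n_per_group, "control", coupling, "CT_")
    cohort <- rbind(ad, ct)
    # dosage index -> genotype label per the panel
    for (g in names(marginals_ad$genotype_freqs)) {
      row <- panel[panel$name == g, ]
      if (nrow(row) != 1) ocm_stop("panel does not define polymorphism '%s'", g)
      cohort[[g]] <- c(row$wild, row$het, row$mut)[cohort[[g]]]
    }
    validate_cohort(cohort, panel)
    cohort
  })
}

#' Benchmark data with planted class signal
#'
#' Generates a two-class matrix in which `n_informative` columns differ
#' between classes by `effect` standard deviations and `n_noise` columns
#' are class-independent standard normal.  The ground-truth mask makes
#' this the reference problem for testing variable selection: a
#' single informative column has theoretical AUC `pnorm(effect / sqrt(2))`.
#'
#' @param n_per_group Records per class.
#' @param n_informative,n_noise Column counts (>= 0).
#' @param effect Between-class mean separation in within-class sd units
#'   (>= 0).
#' @param seed Integer seed.
#' @return List with `x` (matrix), `labels` (character, "control"/"AD"),
#'   and `informative` (logical truth mask of length
#'   `n_informative + n_noise`).
#' @export
planted_signal_cohort <- function(n_per_group, n_informative, n_noise,
                                  effect, seed = 1) {
  if (n_informative < 0 || n_noise < 0) ocm_stop("column counts must be >= 0")
  if (effect < 0) ocm_stop("effect must be >= 0")
  p <- n_informative + n_noise
  with_seed(seed, {
    n <- 2 * n_per_group
    labels <- rep(c("control", "AD"), each = n_per_group)
    x <- matrix(stats::rnorm(n * p), n, p)
    if (n_informative > 0)
      x[labels == "AD", seq_len(n_informative)] <-
        x[labels == "AD", seq_len(n_informative)] + effect
    colnames(x) <- c(sprintf("signal_%02d", seq_len(n_informative)),
                     sprintf("noise_%02d", seq_len(n_noise)))[seq_len(p)]
    list(x = x, labels = labels,
         informative = rep(c(TRUE, FALSE), c(n_informative, n_noise)))
  })
}

#' Summarize a cohort in the style of the study's descriptive table
#'
#' Per group: biomarker mean and normal-theory 95% CI half-width
#' (`1.959964 * sd / sqrt(n)`), and genotype class percentages.
#'
#' @param cohort Cohort data frame.
#' @param panel An `ocm_panel`.
#' @return Data frame with columns `parameter`, `AD_mean`, `AD_ci`,
#'   `control_mean`, `control_ci`; biomarker rows first, then one row per
#'   genotype class.
#' @export
summarize_cohort <- function(cohort, panel = default_panel()) {
  validate_cohort(cohort, panel)
  groups <- c("AD", "control")
  rows <- list()
  for (b in BIOMARKERS) {
    vals <- lapply(groups, function(g) {
      x <- cohort[[b]][cohort$group == g]
      c(mean = mean(x), ci = 1.959964 * stats::sd(x) / sqrt(length(x)))
    })
    rows[[b]] <- data.frame(parameter = b,
                            AD_mean = vals[[1]]["mean"], AD_ci = vals[[1]]["ci"],
                            control_mean = vals[[2]]["mean"], control_ci = vals[[2]]["ci"],
                            row.names = NULL)
  }
  for (i in seq_len(nrow(panel))) {
    labs <- c(panel$wild[i], panel$het[i], panel$mut[i])
    for (k in 1:3) {
      pct <- vapply(groups, function(g) {
        gg <- cohort[[panel$name[i]]][cohort$group == g]
        100 * mean(gg == labs[k])
      }, numeric(1))
      nm <- paste(panel$name[i], GENO_SUFFIX[k], sep = "_")
      rows[[nm]] <- data.frame(parameter = nm,
                               AD_mean = pct["AD"], AD_ci = NA_real_,
                               control_mean = pct["control"], control_ci = NA_real_,
                               row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
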