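# Evolutionary joint selection of input variables and a record
# bipartition ("training with input selection and testing").
#
# A genome concatenates a variable mask (p bits) with a record assignment
# (n bits, TRUE = subset A).  Fitness is the blind two-way KNN accuracy of
# the bipartition restricted to the masked variables, softly penalized for
# mask size (parsimony) and for distributional imbalance between the two
# subsets.  The search is a standard generational GA with tournament
# selection, uniform crossover, per-bit mutation, elitism, and a repair
# operator that restores the solution invariants (non-empty mask; both
# subsets non-empty and containing both classes).

#' Evolutionary search configuration
#'
#' @param population_size Number of genomes per generation.
#' @param generations Generation limit.
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-bit flip probability; `NULL` (the default)
#'   uses the standard 1/L heuristic, one expected flip per genome of
#'   length L.
#' @param elitism Number of best genomes copied unchanged each generation
#'   (guarantees a non-decreasing best fitness).
#' @param patience Stop after this many generations without improvement of
#'   the best-ever fitness.
#' @param tournament_size Tournament size for parent selection.
#' @param k KNN neighbourhood size used by the fitness engine.
#' @param parsimony_weight Penalty weight on the fraction of variables
#'   selected (small, so masks do not bloat neutrally).
#' @param divergence_weight Penalty weight on the partition's
#'   max-divergence (soft pressure toward statistically equivalent
#'   subsets).
#' @param seed Integer seed for the whole run.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(population_size = 50, generations = 100,
                             crossover_rate = 0.9, mutation_rate = NULL,
                             elitism = 2, patience = 25, tournament_size = 3,
                             k = 1, parsimony_weight = 0.01,
                             divergence_weight = 0.1, seed = 1) {
  cfg <- list(population_size = population_size, generations = generations,
              crossover_rate = crossover_rate, mutation_rate = mutation_rate,
              elitism = elitism, patience = patience,
              tournament_size = tournament_size, k = k,
              parsimony_weight = parsimony_weight,
              divergence_weight = divergence_weight, seed = seed)
  if (population_size < 2 || generations < 1 || elitism < 0 ||
      elitism >= population_size || tournament_size < 1 || k < 1)
    ocm_stop("invalid evolution configuration (sizes)")
  for (r in c("crossover_rate", "mutation_rate"))
    if (!is.null(cfg[[r]]) && (cfg[[r]] < 0 || cfg[[r]] > 1))
      ocm_stop("%s must lie in [0, 1]", r)
  if (parsimony_weight < 0 || divergence_weight < 0)
    ocm_stop("penalty weights must be >= 0")
  structure(cfg, class = "evolution_config")
}

#' A candidate solution of the joint selection problem
#'
#' @param variable_mask Logical per input column (>= 1 TRUE).
#' @param record_assignment Logical per record; both subsets must be
#'   non-empty and contain both classes (validated against `labels` when
#'   supplied).
#' @param fitness Optional fitness value.
#' @return A `twist_solution`.
#' @export
twist_solution <- function(variable_mask, record_assignment, fitness = NA_real_) {
  structure(list(variable_mask = as.logical(variable_mask),
                 record_assignment = as.logical(record_assignment),
                 fitness = fitness),
            class = "twist_solution")
}

solution_valid <- function(sol, labels) {
  m <- sol$variable_mask; a <- sol$record_assignment
  if (!any(m)) return(FALSE)
  if (!any(a) || all(a)) return(FALSE)
  for (g in unique(labels))
    if (!any(a & labels == g) || !any(!a & labels == g)) return(FALSE)
  TRUE
}

#' Fitness of a joint variable/partition solution
#'
#' The two-subset protocol's weighted-mean accuracy (on \[0, 1\]) using only
#' the masked variables, minus `parsimony_weight` times the fraction of
#' variables selected and `divergence_weight` times the partition's
#' max-divergence, clipped to \[0, 1\].  Solutions violating the invariants
#' score 0.
#'
#' @param solution A [twist_solution()].
#' @param x Input matrix.
#' @param labels Class labels per record.
#' @param config An [evolution_config()].
#' @return Fitness in \[0, 1\].
#' @export
twist_fitness <- function(solution, x, labels, config = evolution_config()) {
  x <- as.matrix(x); labels <- check_labels(labels)
  if (!solution_valid(solution, labels)) return(0)
  rep <- two_subset_protocol(x[, solution$variable_mask, drop = FALSE], labels,
                             function(a, ay, b) knn_fit_predict(a, ay, b, k = config$k),
                             solution$record_assignment)
  div <- attr(distribution_equivalence(x, solution$record_assignment),
              "max_divergence")
  score <- rep$w_mean / 100 -
    config$parsimony_weight * mean(solution$variable_mask) -
    config$divergence_weight * div
  min(max(score, 0), 1)
}

# ---- fast fitness path -----------------------------------------------------
# Per-column squared-difference matrices are precomputed once so a masked
# distance matrix is a sum over selected columns; divergence uses
# precomputed per-column subset sums.  twist_fitness() is the slow
# reference path; tests assert the two agree.

precompute_fitness <- function(x, labels) {
  n <- nrow(x)
  cols <- lapply(seq_len(ncol(x)), function(j) {
    diff <- outer(x[, j], x[, j], "-")
    diff * diff
  })
  list(cols = cols, x = x, labels = labels, n = n,
       is_ad = labels == "AD")
}

fast_fitness <- function(mask, assign, pre, config) {
  sol <- twist_solution(mask, assign)
  if (!solution_valid(sol, pre$labels)) return(0)
  D <- Reduce(`+`, pre$cols[mask])
  a <- which(assign); b <- which(!assign)
  err <- 0
  for (dir in 1:2) {
    tr <- if (dir == 1) a else b
    te <- if (dir == 1) b else a
    pred <- knn_from_dist2(D[te, tr, drop = FALSE], pre$labels[tr], config$k)
    err <- err + sum(pred != pre$labels[te])
  }
  acc <- 1 - err / pre$n
  m_a <- colMeans(pre$x[a, , drop = FALSE])
  m_b <- colMeans(pre$x[b, , drop = FALSE])
  div <- max(abs(m_a - m_b))
  score <- acc - config$parsimony_weight * mean(mask) -
    config$divergence_weight * div
  min(max(score, 0), 1)
}

repair_genome <- function(mask, assign, labels) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < 2) next
    if (!any(assign[idx])) assign[sample(idx, 1)] <- TRUE
    if (all(assign[idx])) assign[sample(idx, 1)] <- FALSE
  }
  list(mask = mask, assign = assign)
}

#' Evolve a joint variable-subset / record-bipartition solution
#'
#' Generational GA over genomes `[variable mask | record assignment]`.
#' Initialization draws masks with ~50% bits on and class-stratified
#' ~50/50 assignments; variation is tournament selection, uniform
#' crossover and per-bit mutation; elites are copied unchanged; a repair
#' step restores the invariants.  Stops at the generation limit or after
#' `patience` stagnant generations.  Fitness evaluations are cached by
#' genome.
#'
#' @param x Input matrix (records x variables).
#' @param labels Class labels per record (>= 2 records per class).
#' @param config An [evolution_config()].
#' @return List with `best` (a [twist_solution()] with fitness),
#'   `history` (data frame `generation`, `best`, `mean`), and
#'   `evaluations` (number of distinct genomes evaluated).
#' @export
twist_evolve <- function(x, labels, config = evolution_config()) {
  x <- as.matrix(x); labels <- check_labels(labels)
  if (min(table(labels)) < 2) ocm_stop("need >= 2 records per class")
  p <- ncol(x); n <- nrow(x)
  if (is.null(config$mutation_rate)) config$mutation_rate <- 1 / (p + n)
  pre <- precompute_fitness(x, labels)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_eval <- 0L
  eval_genome <- function(mask, assign) {
    key <- paste(c(mask, assign), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fast_fitness(mask, assign, pre, config)
    cache[[key]] <- f
    n_eval <<- n_eval + 1L
    f
  }
  with_seed(config$seed, {
    pop <- replicate(config$population_size, {
      mask <- stats::runif(p) < 0.5
      assign <- logical(n)
      for (g in unique(labels)) {
        idx <- which(labels == g)
        assign[sample(idx, floor(length(idx) / 2))] <- TRUE
      }
      r <- repair_genome(mask, assign, labels)
      list(mask = r$mask, assign = r$assign)
    }, simplify = FALSE)
    fit <- vapply(pop, function(g) eval_genome(g$mask, g$assign), numeric(1))
    best_idx <- which.max(fit)
    best <- list(mask = pop[[best_idx]]$mask, assign = pop[[best_idx]]$assign,
                 fitness = fit[best_idx])
    history <- data.frame(generation = 0, best = best$fitness, mean = mean(fit))
    stagnant <- 0L
    for (gen in seq_len(config$generations)) {
      new_pop <- vector("list", config$population_size)
      # elites: best genomes survive unchanged
      elite_order <- order(-fit)[seq_len(config$elitism)]
      for (e in seq_along(elite_order)) new_pop[[e]] <- pop[[elite_order[e]]]
      i <- config$elitism
      while (i < config$population_size) {
        pick <- function() {
          cand <- sample.int(config$population_size, config$tournament_size,
                             replace = TRUE)
          pop[[cand[which.max(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        g1 <- c(p1$mask, p1$assign); g2 <- c(p2$mask, p2$assign)
        if (stats::runif(1) < config$crossover_rate) {
          swap <- stats::runif(p + n) < 0.5
          tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
        }
        for (g in list(g1, g2)) {
          if (i >= config$population_size) break
          flip <- stats::runif(p + n) < config$mutation_rate
          g <- xor(g, flip)
          r <- repair_genome(g[seq_len(p)], g[p + seq_len(n)], labels)
          i <- i + 1L
          new_pop[[i]] <- list(mask = r$mask, assign = r$assign)
        }
      }
      pop <- new_pop
      fit <- vapply(pop, function(g) eval_genome(g$mask, g$assign), numeric(1))
      gen_best <- which.max(fit)
      if (fit[gen_best] > best$fitness) {
        best <- list(mask = pop[[gen_best]]$mask,
                     assign = pop[[gen_best]]$assign, fitness = fit[gen_best])
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      history <- rbind(history,
                       data.frame(generation = gen, best = best$fitness,
                                  mean = mean(fit)))
      if (stagnant >= config$patience) break
    }
    list(best = twist_solution(best$mask, best$assign, best$fitness),
         history = history, evaluations = n_eval)
  })
}

#' Report the selected variables and record subsets
#'
#' Two-column layout mirroring the study's selection table: every original
#' variable on the left, the selected subset on the right (blank where a
#' variable was dropped).
#'
#' @param solution A [twist_solution()].
#' @param column_names Names of the input columns, in matrix order.
#' @return Data frame with columns `original` and `selected`, plus
#'   attributes `n_selected` and `assignment`.
#' @export
export_selection <- function(solution, column_names) {
  if (length(column_names) != length(solution$variable_mask))
    ocm_stop("column_names length must match the variable mask")
  out <- data.frame(original = column_names,
                    selected = ifelse(solution$variable_mask, column_names, ""),
                    stringsAsFactors = FALSE)
  attr(out, "n_selected") <- sum(solution$variable_mask)
  attr(out, "assignment") <- solution$record_assignment
  out
}
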