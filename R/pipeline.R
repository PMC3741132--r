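# End-to-end study replication: code the cohort, benchmark the battery on
# all 30 variables (k-fold, then random split), select variables and an
# optimal bipartition evolutionarily, re-benchmark on the selected
# variables (k-fold, then the two evolved subsets), and build the
# connectivity map — writing one report bundle with a hash manifest.

#' Study run configuration
#'
#' @param cohort Either `list(source = "synthetic", n_per_group =,
#'   coupling =)` or `list(source = "file", path =)`.
#' @param specs Battery of [classifier_spec()]s.
#' @param K Folds for the k-fold protocol (study default 10).
#' @param train_fraction Random-split training fraction (default 0.5).
#' @param evolution An [evolution_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param autocm_C Contraction parameter, `"auto"` = number of variables.
#' @param seed Global seed; stage seeds derive from it via [stage_seed()].
#' @param out_dir Output directory.
#' @return A `study_config` list.
#' @export
study_config <- function(cohort = list(source = "synthetic", n_per_group = 40,
                                       coupling = NULL),
                         specs = list(knn_classifier(), logistic_classifier(),
                                      majority_classifier()),
                         K = 10, train_fraction = 0.5,
                         evolution = evolution_config(),
                         autocm_C = "auto", seed = 1, out_dir = tempfile("study_")) {
  structure(list(cohort = cohort, specs = specs, K = K,
                 train_fraction = train_fraction, evolution = evolution,
                 autocm_C = autocm_C, seed = seed, out_dir = out_dir),
            class = "study_config")
}

#' Validate a cohort CSV before running a study
#'
#' Schema check of the cohort file: column set, class labels, genotype
#' vocabulary, biomarker ranges; errors are row- and column-addressed.
#'
#' @param path Cohort CSV path.
#' @param panel An `ocm_panel`.
#' @return List `valid` (logical) and `errors` (character vector).
#' @export
validate_inputs <- function(path, panel = default_panel()) {
  if (!file.exists(path)) ocm_stop("cannot read '%s': no such file", path)
  errors <- character(0)
  tryCatch(read_cohort(path, panel),
           error = function(e) errors <<- conditionMessage(e))
  list(valid = length(errors) == 0, errors = errors)
}

write_report_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full study pipeline
#'
#' Produces, in order: the k-fold battery report on all 30 variables, the
#' random-split report on all 30, the evolutionary selection report, the
#' k-fold report restricted to the selected variables, the two-subset
#' report on the evolved bipartition, and the Auto-CM connectivity map.
#' A manifest records the seeds and an MD5 hash of every emitted file.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `battery_kfold_30`, `battery_split_30`, `selection`,
#'   `battery_kfold_sel`, `battery_two_subset_sel`, `map`, `manifest`).
#' @export
run_study <- function(config = study_config()) {
  panel <- default_panel()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  cohort <- if (identical(config$cohort$source, "file")) {
    read_cohort(config$cohort$path, panel)
  } else {
    generate_cohort(n_per_group = config$cohort$n_per_group %||% 40,
                    seed = stage_seed(config$seed, "simulate"),
                    coupling = config$cohort$coupling)
  }
  write_cohort(cohort, out("cohort.csv")); files <- c(files, out("cohort.csv"))

  x30 <- assemble_classification_matrix(cohort, panel)
  labels <- attr(x30, "class_labels")

  b4 <- run_battery(config$specs, "kfold", x30, labels, K = config$K,
                    seed = stage_seed(config$seed, "battery30"))
  files <- c(files, write_report_csv(b4, out("report_kfold_30.csv")))

  b5 <- run_battery(config$specs, "split", x30, labels,
                    train_fraction = config$train_fraction,
                    seed = stage_seed(config$seed, "split30"))
  files <- c(files, write_report_csv(b5, out("report_split_30.csv")))

  evo_cfg <- config$evolution
  evo_cfg$seed <- stage_seed(config$seed, "twist")
  evo <- twist_evolve(unclass(x30), labels, evo_cfg)
  sel <- export_selection(evo$best, colnames(x30))
  files <- c(files, write_report_csv(sel, out("report_selection.csv")))
  files <- c(files, write_report_csv(evo$history, out("twist_history.csv")))
  subsets <- data.frame(subject_id = cohort$subject_id,
                        subset = ifelse(evo$best$record_assignment, "A", "B"))
  files <- c(files, write_report_csv(subsets, out("twist_subsets.csv")))

  x_sel <- unclass(x30)[, evo$best$variable_mask, drop = FALSE]
  b6 <- run_battery(config$specs, "kfold", x_sel, labels, K = config$K,
                    seed = stage_seed(config$seed, "battery16"))
  files <- c(files, write_report_csv(b6, out("report_kfold_selected.csv")))

  b7 <- run_battery(config$specs, "two_subset", x_sel, labels,
                    assignment = evo$best$record_assignment)
  files <- c(files, write_report_csv(b7, out("report_two_subset_selected.csv")))

  x35 <- assemble_autocm_matrix(cohort, panel)
  model <- train_autocm(unclass(x35), C = config$autocm_C)
  map <- build_map(model)
  files <- c(files, write_report_csv(map$edges, out("map_edges.csv")))
  utils::write.csv(round(map$distances, 9), out("map_distances.csv"))
  files <- c(files, out("map_distances.csv"))
  export_map(map, out("map.graphml"), "graphml"); files <- c(files, out("map.graphml"))
  export_map(map, out("map.dot"), "dot"); files <- c(files, out("map.dot"))

  manifest <- list(
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(c("simulate", "battery30", "split30", "twist", "battery16"),
             function(s) stage_seed(config$seed, s)),
      c("simulate", "battery30", "split30", "twist", "battery16")),
    twist_evaluations = evo$evaluations,
    n_selected = sum(evo$best$variable_mask),
    autocm_epochs = model$epochs,
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, battery_kfold_30 = b4, battery_split_30 = b5,
                 selection = sel, twist = evo, battery_kfold_sel = b6,
                 battery_two_subset_sel = b7, model = model, map = map,
                 manifest = manifest, out_dir = config$out_dir))
}

# ---- command line ----------------------------------------------------------

cli_args <- function(args) {
  # --key value pairs after the subcommand
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      out[[substring(args[i], 3)]] <- args[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort CSV), `encode`
#' (cohort -> design matrix CSVs), `validate` (schema check), `twist`
#' (evolutionary selection), `autocm` (connectivity map from a design
#' CSV), `run-study` (full pipeline).  Options are `--key value` pairs;
#' see the package README.  Installed as the `ocm-ann` script under
#' `inst/exec`.
#'
#' @param args Character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Exit status 0 on success (invisibly).
#' @export
ocm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    ocm_stop("usage: ocm-ann simulate|encode|validate|twist|autocm|run-study [--key value ...]")
  cmd <- args[1]
  opt <- cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1)
  switch(cmd,
    simulate = {
      cohort <- generate_cohort(n_per_group = as.integer(opt$n %||% 40),
                                seed = seed,
                                coupling = if (identical(opt$coupling, "literature"))
                                  coupling_preset_literature())
      write_cohort(cohort, opt$out %||% "cohort.csv")
      message("wrote ", opt$out %||% "cohort.csv")
    },
    encode = {
      cohort <- read_cohort(opt$cohort)
      write_design(assemble_classification_matrix(cohort),
                   opt$out %||% "design_30.csv")
      message("wrote ", opt$out %||% "design_30.csv")
    },
    validate = {
      res <- validate_inputs(opt$cohort)
      if (!res$valid) ocm_stop("invalid cohort: %s", paste(res$errors, collapse = "; "))
      message("cohort is valid")
    },
    twist = {
      cohort <- read_cohort(opt$cohort)
      x <- assemble_classification_matrix(cohort)
      evo <- twist_evolve(unclass(x), attr(x, "class_labels"),
                          evolution_config(seed = seed))
      dir.create(opt$out %||% "twist_out", showWarnings = FALSE, recursive = TRUE)
      write_report_csv(export_selection(evo$best, colnames(x)),
                       file.path(opt$out %||% "twist_out", "selection.csv"))
      write_report_csv(evo$history,
                       file.path(opt$out %||% "twist_out", "history.csv"))
      message("selected ", sum(evo$best$variable_mask), " variables")
    },
    autocm = {
      design <- read_design(opt$matrix)
      map <- build_map(train_autocm(unclass(design), C = opt$C %||% "auto"))
      dir.create(opt$out %||% "map_out", showWarnings = FALSE, recursive = TRUE)
      write_report_csv(map$edges, file.path(opt$out %||% "map_out", "edges.csv"))
      export_map(map, file.path(opt$out %||% "map_out", "map.graphml"), "graphml")
      export_map(map, file.path(opt$out %||% "map_out", "map.dot"), "dot")
      message("map with ", nrow(map$edges), " edges; hubs: ",
              paste(map$hubs, collapse = ", "))
    },
    `run-study` = {
      cfg <- study_config(seed = seed, out_dir = opt$out %||% "study_out")
      if (!is.null(opt$cohort))
        cfg$cohort <- list(source = "file", path = opt$cohort)
      run_study(cfg)
      message("study bundle written to ", cfg$out_dir)
    },
    ocm_stop("unknown subcommand '%s'", cmd))
  invisible(0L)
}
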