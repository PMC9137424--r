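#' Read a trial table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header containing at least
#' `subject_id`, `group`, `modality`, `mask`, `target`, `response` (the
#' postalveolar fricative is serialized as `"sh"`). Row-level validation
#' errors are collected and reported together with their line numbers.
#'
#' @param path CSV path. Lines starting with `#` are treated as comments
#'   (provenance headers written by [run_pipeline()]).
#' @return A validated trial tibble.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Trial table not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("subject_id", "group", "modality", "mask", "target", "response")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trial table %s lacks column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  checks <- list(
    group = group_levels(), modality = modality_levels(), mask = mask_levels(),
    target = consonants(), response = consonants()
  )
  problems <- character()
  for (col in names(checks)) {
    bad <- which(!(d[[col]] %in% checks[[col]]))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "line %d: invalid %s '%s'", bad + 1L, col, d[[col]][bad]))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Validation failed for ", path, ":\n  ",
                 paste(head(problems, 20), collapse = "\n  ")))
  }
  validate_trials(d)
}

#' Write a trial table to CSV
#'
#' @param trials A trial tibble.
#' @param path Output path.
#' @param provenance Optional named list written as `# key=value` comment
#'   lines above the header.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path, provenance = NULL) {
  trials <- validate_trials(trials)
  write_with_provenance(trials, path, provenance)
}

write_with_provenance <- function(df, path, provenance = NULL) {
  if (!is.null(provenance)) {
    hdr <- sprintf("# %s=%s", names(provenance),
                   vapply(provenance, as.character, character(1)))
    writeLines(hdr, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed for the run.
#' @param design A [cohort_design()].
#' @param params A [listener_params()].
#' @param spec A [model_spec()].
#' @param trials_csv Optional path to an existing trial table; when given,
#'   the simulation stage is skipped and the table is loaded instead.
#' @return A `masksim_config` object.
#' @export
run_config <- function(out_dir, seed = 1, design = cohort_design(),
                       params = listener_params(), spec = model_spec(),
                       trials_csv = NULL) {
  if (!is.null(trials_csv) && !file.exists(trials_csv)) {
    abort(sprintf("Configured input does not exist: %s", trials_csv))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 params = params, spec = spec, trials_csv = trials_csv),
            class = "masksim_config")
}

#' Run the simulate - score - analyze pipeline
#'
#' Executes the full tabular pipeline: simulate (or load) a trial table,
#' score it per subject and condition, fit the mixed-effects accuracy
#' model, and write `trials.csv`, `scores.csv` and `model.json` into the
#' output directory. Every output embeds the configuration hash and the
#' seed, and a fixed seed yields byte-identical score tables.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "masksim_config"))
  if (!is.null(config$trials_csv) && !file.exists(config$trials_csv)) {
    abort(sprintf("Pre-flight failure: input %s is missing.", config$trials_csv))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # canonicalize before hashing: formulas carry environments that would
  # otherwise make identical configs hash differently
  hash <- rlang::hash(list(
    seed = config$seed,
    design = unclass(config$design),
    params = unclass(config$params),
    fixed = deparse(config$spec$fixed, width.cutoff = 500),
    random = config$spec$random, alpha = config$spec$alpha,
    reference = config$spec$reference,
    trials_csv = config$trials_csv))
  prov <- list(config_hash = hash, seed = config$seed)

  trials <- tryCatch({
    if (is.null(config$trials_csv)) {
      simulate_cohort(config$design, config$params, seed = config$seed)
    } else {
      read_trial_table(config$trials_csv)
    }
  }, error = function(e) abort(paste0("Pipeline stage 'simulate' failed: ",
                                      conditionMessage(e))))
  write_trial_table(trials, file.path(config$out_dir, "trials.csv"), prov)

  scores <- tryCatch(
    score_trials(trials),
    error = function(e) abort(paste0("Pipeline stage 'score' failed: ",
                                     conditionMessage(e))))
  write_with_provenance(scores, file.path(config$out_dir, "scores.csv"), prov)

  fit <- tryCatch(
    fit_accuracy_model(scores[scores$modality %in% c("AO", "AV"), ],
                       config$spec),
    error = function(e) abort(paste0("Pipeline stage 'analyze' failed: ",
                                     conditionMessage(e))))
  model_out <- list(
    config_hash = hash, seed = config$seed,
    fixed = deparse(fit$fixed),
    eliminated = fit$elimination$dropped,
    anova = cbind(term = rownames(fit$anova), as.data.frame(fit$anova)),
    coefficients = as.data.frame(tidy(fit)),
    glance = as.data.frame(glance(fit))
  )
  jsonlite::write_json(model_out, file.path(config$out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
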