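#' Default pipeline configuration
#'
#' Settings reproducing the packaged study: the shipped training, test,
#' screening and energy tables; Pearson selection at |r| >= 0.5; subset
#' sizes 4, 5 and 6; the five pinned training outliers; activity cutoff
#' pEC50 > 5.64936; and a fixed seed for the synthetic ranked screen.
#'
#' @param ... Named overrides for any configuration field.
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(...) {
  config <- list(
    training = a2a_file("a2a_training.tsv"),
    test = a2a_file("a2a_test.tsv"),
    screening = a2a_file("a2a_screening.tsv"),
    energy = a2a_file("a2a_energy.tsv"),
    models = a2a_file("a2a_models.json"),
    activity = "pec50",
    correlation_cutoff = 0.5,
    sizes = c(4, 5, 6),
    outliers = as.character(c(2:5, 8)),   # pinned; use NULL for the automatic rule
    activity_cutoff = 5.64936,
    recovery_k = c(13, 19),
    seed = 1
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(config))
  if (length(bad)) {
    abort(paste0("unknown configuration field(s): ", paste(bad, collapse = ", ")))
  }
  modifyList(config, overrides)
}

read_stage_table <- function(path, stage) {
  if (is.data.frame(path)) return(validate_compound_table(path))
  if (!is.character(path) || !file.exists(path)) {
    abort(paste0("[", stage, "] input file not found: ", path))
  }
  read_compound_table(path)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full agonist-potency analysis pipeline
#'
#' Orchestrates every stage on one configuration: read and validate the
#' input tables, fill in pEC50 from EC50, select descriptors by Pearson
#' correlation, enumerate and fit all candidate regression subsets on
#' the outlier-free training set, rank them, validate the reference
#' coefficient models internally and externally, classify the screening
#' hits, evaluate pharmacophore-screen recovery on a seeded synthetic
#' ranking, and aggregate the MM/GBSA energy components. Each stage logs
#' a row count to stderr. Output is deterministic given the
#' configuration (including its seed).
#'
#' @param config A configuration list from [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage result is
#'   written there as TSV plus a `summary.json`.
#' @return Invisibly, a named list with every stage result:
#'   `correlations`, `selected`, `outliers`, `models` (ranked tibble),
#'   `validation_training`, `validation_test`, `screening`, `recovery`,
#'   `energetics`, `summary`.
#' @examples
#' res <- run_qsar_pipeline(pipeline_config())
#' res$summary$n_models
#' @export
run_qsar_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  training <- read_stage_table(config$training, "read") %>% convert_activity()
  test <- read_stage_table(config$test, "read") %>% convert_activity()
  screening <- read_stage_table(config$screening, "read")
  stage_log("read", nrow(training), " training / ", nrow(test), " test / ",
            nrow(screening), " screening compounds")

  correlations <- correlate_activity(training, activity = config$activity,
                                     cutoff = config$correlation_cutoff)
  selected <- select_descriptors(correlations)
  stage_log("select", length(selected), " descriptors pass |r| >= ",
            config$correlation_cutoff, ": ", paste(selected, collapse = ", "))

  outliers <- detect_outliers(training, selected, activity = config$activity,
                              ids = config$outliers)
  stage_log("outliers", length(outliers), " compounds excluded: ",
            paste(outliers, collapse = ", "))

  models <- fit_all_models(training, sizes = config$sizes,
                           descriptors = selected,
                           activity = config$activity, exclude = outliers) %>%
    rank_models()
  stage_log("fit", nrow(models), " candidate models; best: ", models$subset[1],
            sprintf(" (r = %.4f)", models$r[1]))

  reference <- a2a_models(config$models)
  train_kept <- filter(training, !.data$compound_id %in% outliers)
  validation_training <- purrr::imap(
    reference, ~ mutate(validate_qsar(.x, training, config$activity), model = .y)
  ) %>% bind_rows()
  validation_test <- purrr::imap(
    reference, ~ mutate(validate_qsar(.x, test, config$activity), model = .y)
  ) %>% bind_rows()
  stage_log("validate", nrow(validation_training), " internal + ",
            nrow(validation_test), " external predictions")

  screening_decisions <- screen_compounds(screening, models = reference,
                                          cutoff = config$activity_cutoff)
  stage_log("screen", sum(screening_decisions$active), " of ",
            nrow(screening_decisions), " hits classified active at pEC50 > ",
            config$activity_cutoff)

  screen_ranking <- simulate_ranked_screen(seed = config$seed)
  recovery_report <- purrr::map(config$recovery_k, recovery,
                                screen = screen_ranking) %>% bind_rows()
  stage_log("enrich", "recovery at k = ",
            paste(config$recovery_k, collapse = ", "), ": ",
            paste(recovery_report$percent_agonists_recovered, collapse = ", "),
            "% of agonists")

  energetics <- binding_energy(
    readr::read_tsv(config$energy, show_col_types = FALSE))
  stage_log("energetics", nrow(energetics), " ligands aggregated")

  summary <- list(
    n_training = nrow(training), n_test = nrow(test),
    n_screening = nrow(screening),
    selected_descriptors = selected,
    outliers = outliers,
    n_models = nrow(models),
    best_subset = models$subset[1],
    best_r = models$r[1],
    n_active = sum(screening_decisions$active),
    active_ids = screening_decisions$compound_id[screening_decisions$active],
    recovery = recovery_report
  )

  result <- list(correlations = correlations, selected = selected,
                 outliers = outliers, models = models,
                 validation_training = validation_training,
                 validation_test = validation_test,
                 screening = screening_decisions,
                 screen_ranking = screen_ranking,
                 recovery = recovery_report,
                 energetics = energetics, summary = summary,
                 training = train_kept)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_out <- function(x, name) {
      readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    }
    write_out(correlations, "correlations")
    write_out(select(models, -"fit", -"descriptors"), "models")
    write_out(validation_training, "validation_training")
    write_out(validation_test, "validation_test")
    write_out(screening_decisions, "screening")
    write_out(screen_ranking, "screen_ranking")
    write_out(recovery_report, "recovery")
    write_out(energetics, "energetics")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log("write", "outputs in ", out_dir)
  }
  invisible(result)
}
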