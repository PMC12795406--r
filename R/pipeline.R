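#' Pipeline configuration
#'
#' A single configuration object driving the end-to-end analysis:
#' generate synthetic corpora, pretrain, train/cross-validate the role
#' prediction model, extract predictability records, fit the hierarchical
#' beta regression and write a report. All stage seeds derive from the
#' global seed.
#'
#' @param presets character vector of [preset_language_spec()] names, or a
#'   named list of `rp_language_spec` objects / YAML paths.
#' @param outdir output directory (created if missing).
#' @param n_cdu utterances per language.
#' @param n_adu_words pretraining token budget per language.
#' @param cv_folds cross-validation folds.
#' @param model named list of [srp_config()] overrides.
#' @param regression named list of [regression_spec()] overrides.
#' @param seed global integer seed.
#' @return list of class `rp_pipeline_config`.
#' @export
pipeline_config <- function(presets = c("verb_initial_voice",
                                        "verb_medial_rigid",
                                        "verb_final_case"),
                            outdir, n_cdu = 3000L, n_adu_words = 50000L,
                            cv_folds = 10L, model = list(),
                            regression = list(), seed = 1L) {
  if (is.character(presets)) {
    specs <- lapply(presets, function(p) {
      if (file.exists(p)) read_language_spec(p) else preset_language_spec(p)
    })
    names(specs) <- vapply(specs, `[[`, "", "name")
  } else specs <- presets
  structure(list(specs = specs, outdir = outdir,
                 n_cdu = as.integer(n_cdu),
                 n_adu_words = as.integer(n_adu_words),
                 cv_folds = as.integer(cv_folds),
                 model = model, regression = regression,
                 seed = as.integer(seed)),
            class = "rp_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments.
#'   Referenced preset files must exist (validated before any compute).
#' @return an `rp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  known <- c("verb_initial_voice", "verb_medial_rigid", "verb_final_case",
             "verb_final_deterministic")
  for (p in x$presets)
    if (!(p %in% known) && !file.exists(p))
      stop("preset '", p, "' is neither a shipped preset nor a file",
           call. = FALSE)
  do.call(pipeline_config, x)
}

stage_msg <- function(stage, ...) {
  message(sprintf("[rolepred:%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Stages: generate -> pretrain -> cross-validate -> extract -> regress ->
#' report. Every output file is content-hashed into
#' `<outdir>/manifest.json`; rerunning with an identical config reproduces
#' an identical records table. A stage failure halts with the stage name.
#'
#' @param config an [pipeline_config()].
#' @param stages subset of stages to run (default all, in order).
#' @return invisibly, the manifest as a named list (file -> md5).
#' @export
run_pipeline <- function(config,
                         stages = c("generate", "pretrain", "cv", "extract",
                                    "regress", "report")) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  run_stage <- function(stage, f) {
    stage_msg(stage, "starting")
    tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  if ("generate" %in% stages) run_stage("generate", function() {
    for (nm in names(config$specs)) {
      sp <- config$specs[[nm]]
      corp <- generate_cdu_corpus(sp, config$n_cdu, config$seed)
      write_corpus(corp, out(paste0("cdu_", nm, ".jsonl")))
      log <- attr(corp, "generation_log")
      writeLines(vapply(seq_len(nrow(log)), function(i)
        as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)),
        ""), out(paste0("cdu_", nm, ".log.jsonl")))
      adu <- generate_adu_text(sp, config$n_adu_words, config$seed)
      writeLines(vapply(adu, paste, "", collapse = " "),
                 out(paste0("adu_", nm, ".txt")))
      stage_msg("generate", "%s: %d CDUs, %d ADU tokens", nm, length(corp),
                attr(adu, "n_tokens"))
    }
  })

  model_cfg <- function(nm, corp, adu) {
    vocab <- build_vocab(list(corp, adu))
    args <- modifyList(list(vocab = vocab, seed = config$seed),
                       config$model)
    do.call(srp_config, args)
  }
  load_lang <- function(nm) {
    corp <- read_corpus(out(paste0("cdu_", nm, ".jsonl")))
    adu <- lapply(strsplit(readLines(out(paste0("adu_", nm, ".txt"))), " "),
                  identity)
    list(corp = corp, adu = adu)
  }

  if ("pretrain" %in% stages) run_stage("pretrain", function() {
    for (nm in names(config$specs)) {
      d <- load_lang(nm)
      cfg <- model_cfg(nm, d$corp, d$adu)
      m <- pretrain(d$adu, cfg)
      save_srp_model(m, out(paste0("pretrained_", nm, ".json")))
      utils::write.csv(m$log, out(paste0("pretrain_log_", nm, ".csv")),
                       row.names = FALSE)
      stage_msg("pretrain", "%s done (best epoch %d)", nm,
                m$provenance$best_epoch)
    }
  })

  if ("cv" %in% stages) run_stage("cv", function() {
    for (nm in names(config$specs)) {
      d <- load_lang(nm)
      m <- load_srp_model(out(paste0("pretrained_", nm, ".json")))
      cv <- kfold_evaluate(d$corp, config$cv_folds, m$config, pretrained = m)
      utils::write.csv(cv$fold_accuracy,
                       out(paste0("cv_accuracy_", nm, ".csv")),
                       row.names = FALSE)
      recs <- predictability_table(cv$trajectories, d$corp)
      write_records(recs, out(paste0("records_", nm, ".tsv")))
      stage_msg("cv", "%s: mean held-out accuracy %.3f", nm,
                mean(cv$fold_accuracy$accuracy))
    }
  })

  if ("extract" %in% stages) run_stage("extract", function() {
    recs <- do.call(rbind, lapply(names(config$specs), function(nm)
      read_records(out(paste0("records_", nm, ".tsv")))))
    write_records(recs, out("records_all.tsv"))
    stage_msg("extract", "%d records", nrow(recs))
  })

  if ("regress" %in% stages) run_stage("regress", function() {
    recs <- read_records(out("records_all.tsv"))
    single_lang <- length(unique(recs$language)) < 2
    args <- modifyList(list(
      fixed_terms = c("after_argument", "after_verb", "role",
                      if (!single_lang) "language", "nominality"),
      interactions = c(if (!single_lang)
        "after_argument*after_verb*role*language" else
        "after_argument*after_verb*role", "nominality:role"),
      seed = config$seed), config$regression)
    spec <- do.call(regression_spec, args)
    fit <- fit_beta_hierarchical(build_design(recs, spec))
    utils::write.csv(posterior_summary(fit), out("posterior_summary.csv"),
                     row.names = FALSE)
    writeLines(as.character(jsonlite::toJSON(list(
      converged = fit$converged, divergences = sum(fit$divergences),
      max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
      min_ess_bulk = min(fit$diagnostics$ess_bulk, na.rm = TRUE),
      phi_prior = spec$phi_prior), auto_unbox = TRUE, digits = NA)),
      out("diagnostics.json"))
    grid <- expand.grid(language = unique(recs$language),
                        role = c("A", "P"),
                        after_argument = c(FALSE, TRUE),
                        after_verb = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
    for (v in names(fit$xlevels))
      if (!v %in% colnames(grid)) grid[[v]] <- fit$xlevels[[v]][1]
    utils::write.csv(cell_means(fit, grid), out("cell_means.csv"),
                     row.names = FALSE)
    if (!single_lang)
      utils::write.csv(pairwise_language_contrasts(fit, grid),
                       out("contrasts.csv"), row.names = FALSE)
    stage_msg("regress", "converged: %s", fit$converged)
  })

  manifest <- NULL
  if ("report" %in% stages) run_stage("report", function() {
    files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
    hashes <- tools::md5sum(file.path(config$outdir, files))
    names(hashes) <- files
    manifest <<- as.list(hashes)
    writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE)),
               out("manifest.json"))
    stage_msg("report", "manifest covers %d files", length(files))
  })
  invisible(manifest)
}
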