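#' Position-conditioned predictability records of one utterance
#'
#' Converts a role trajectory into regression response rows. For each
#' argument one record is read off at its own first occurrence and one at
#' each subsequent informative event (the occurrence of the other
#' argument, the occurrence of the verb), from the trajectory time point
#' reached after consuming that element. The two binary position flags
#' record whether the other argument (`after_argument`) and the verb
#' (`after_verb`) have been consumed up to and including the read-off
#' point; `after_argument` is always `FALSE` for single-argument
#' utterances. `p_correct` is the probability assigned to the argument's
#' gold role. Adjunct tokens are never read-off points.
#'
#' @param traj an `rp_role_trajectory` produced from `utt`.
#' @param utt the matching `rp_utterance`.
#' @return data frame with columns `sentence_id`, `language`, `role`,
#'   `after_argument`, `after_verb`, `nominality`, `verb_class`,
#'   `p_correct`.
#' @export
extract_records <- function(traj, utt) {
  if (!identical(traj$id, utt$id) ||
      nrow(traj$probA) != length(utt$arguments))
    stop("trajectory does not match utterance ", utt$id, call. = FALSE)
  rows <- list()
  n_args <- length(utt$arguments)
  for (j in seq_len(n_args)) {
    own <- traj$arg_elements[j]
    other <- if (n_args == 2L) traj$arg_elements[3L - j] else NA_integer_
    events <- own
    if (!is.na(other) && other > own) events <- c(events, other)
    if (traj$verb_element > own) events <- c(events, traj$verb_element)
    events <- sort(events)
    role <- utt$arguments[[j]]$role
    for (t in events) {
      pA <- traj$probA[j, t]
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = utt$id, language = utt$language, role = role,
        after_argument = !is.na(other) && other <= t,
        after_verb = traj$verb_element <= t,
        nominality = utt$arguments[[j]]$nominality,
        verb_class = utt$verb_class,
        p_correct = if (role == "A") pA else 1 - pA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sentence_id = character(), language = character(),
                      role = character(), after_argument = logical(),
                      after_verb = logical(), nominality = character(),
                      verb_class = character(), p_correct = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predictability records for a whole evaluated corpus
#'
#' @param trajectories named list of trajectories (e.g.
#'   `kfold_evaluate(...)$trajectories`).
#' @param corp the matching `rp_corpus`.
#' @return row-bound [extract_records()] output.
#' @export
predictability_table <- function(trajectories, corp) {
  out <- do.call(rbind, lapply(corp$utterances, function(u)
    extract_records(trajectories[[u$id]], u)))
  rownames(out) <- NULL
  out
}

#' Proportional baseline accuracy
#'
#' Expected accuracy on items of a given role when labels are predicted
#' at random according to their empirical proportions: it equals that
#' role's proportion.
#'
#' @param role_proportions named numeric `c(A=, P=)` summing to 1.
#' @param role `"A"` or `"P"`.
#' @return the queried proportion.
#' @export
baseline_accuracy <- function(role_proportions, role) {
  if (!setequal(names(role_proportions), ROLE_LEVELS) ||
      any(role_proportions < 0) ||
      abs(sum(role_proportions) - 1) > 1e-8)
    stop("role_proportions must be a distribution over {A, P}",
         call. = FALSE)
  if (!role %in% ROLE_LEVELS) stop("role must be 'A' or 'P'", call. = FALSE)
  unname(role_proportions[[role]])
}

#' Final-position predictability of stimulus items
#'
#' For experimental stimuli only the probability assigned to the correct
#' role at the last position in the sentence is kept: one record per
#' argument, condition labels carried through, no position flags.
#'
#' @param traj an `rp_role_trajectory`.
#' @param utt the matching stimulus `rp_utterance`.
#' @param condition named list / one-row data frame of condition labels
#'   (required).
#' @return data frame with columns `sentence_id`, `language`, `role`,
#'   `p_correct`, plus one column per condition factor.
#' @export
stimulus_final_probability <- function(traj, utt, condition) {
  if (is.null(condition) || !length(condition))
    stop("missing condition labels for stimulus ", utt$id, call. = FALSE)
  if (!identical(traj$id, utt$id) ||
      nrow(traj$probA) != length(utt$arguments))
    stop("trajectory does not match utterance ", utt$id, call. = FALSE)
  Tn <- traj$n_elements
  rows <- lapply(seq_along(utt$arguments), function(j) {
    role <- utt$arguments[[j]]$role
    pA <- traj$probA[j, Tn]
    cbind(data.frame(sentence_id = utt$id, language = utt$language,
                     role = role,
                     p_correct = if (role == "A") pA else 1 - pA,
                     stringsAsFactors = FALSE),
          as.data.frame(condition, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a stimulus corpus with a trained model
#'
#' Runs [incremental_forward()] on every stimulus and collects
#' [stimulus_final_probability()] rows, using the `conditions` attribute
#' created by [generate_stimuli()].
#'
#' @param stim stimulus `rp_corpus` with a `conditions` attribute.
#' @param model trained `rp_srp_model`.
#' @return stacked stimulus record table.
#' @export
evaluate_stimuli <- function(stim, model) {
  conds <- attr(stim, "conditions")
  if (is.null(conds)) stop("stimulus corpus lacks condition labels",
                           call. = FALSE)
  out <- do.call(rbind, lapply(stim$utterances, function(u) {
    cr <- conds[conds$id == u$id, setdiff(colnames(conds), "id"),
                drop = FALSE]
    stimulus_final_probability(incremental_forward(u, model), u, cr)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a records table as TSV
#'
#' Stable column order and formatting; the regression module's input
#' format.
#' @param records data frame of predictability records.
#' @param path file path.
#' @export
write_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE, encoding = "UTF-8")
}
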