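consonants <- c("b", "d", "g", "k", "l", "m", "n", "p", "r", "s", "t", "w")
vowels <- c("a", "e", "i", "o", "u")

make_words <- function(n, n_syl_min, n_syl_max, used = character()) {
  out <- character(0)
  while (length(out) < n) {
    k <- sample(n_syl_min:n_syl_max, 1)
    w <- paste0(paste0(sample(consonants, k, replace = TRUE),
                       sample(vowels, k, replace = TRUE)), collapse = "")
    if (!(w %in% used) && !(w %in% out)) out <- c(out, w)
  }
  out
}

zipf_weights <- function(k, s) {
  w <- seq_len(k)^(-s)
  w / sum(w)
}

sample_zipf <- function(k, s, n = 1) {
  sample.int(k, n, replace = TRUE, prob = zipf_weights(k, s))
}

#' Generate the lexicon of a synthetic language
#'
#' Builds unique pseudo-words for the noun, verb, pronoun and function
#' categories (words are in rank order; sampling weight of rank r is
#' proportional to `r^-zipf_exponent`), reserves marker tokens (case
#' suffixes, voice affixes, prominence and oblique markers, determiner)
#' from the function alphabet, assigns every verb a verb class, and gives
#' each class disjoint role-specific noun pools that supply plausible A
#' and P fillers (the lexical-semantic cue).
#'
#' @param spec an `rp_language_spec`.
#' @param seed integer seed; output is a pure function of `(spec, seed)`.
#' @return an object of class `rp_lexicon`.
#' @export
generate_lexicon <- function(spec, seed) {
  validate_language_spec(spec)
  with_seed(seed, {
    sz <- spec$lexicon_sizes
    nouns <- make_words(sz[["noun"]], 2, 3)
    verbs <- make_words(sz[["verb"]], 2, 3, used = nouns)
    prons <- make_words(sz[["pronoun"]], 1, 2, used = c(nouns, verbs))
    funcs <- make_words(sz[["function"]], 1, 2, used = c(nouns, verbs, prons))

    markers <- character(0)
    nf <- 0L
    take_func <- function() {
      nf <<- nf + 1L
      if (nf > length(funcs)) stop("function lexicon too small for markers",
                                   call. = FALSE)
      funcs[nf]
    }
    if (spec$marking == "case_suffix") {
      markers <- c(A = take_func(), P = take_func())
    } else if (spec$marking == "voice_affix") {
      for (v in names(spec$voices))
        if (isTRUE(spec$voices[[v]]$affix)) markers[[paste0("affix_", v)]] <- take_func()
      if (any(vapply(spec$voices, function(x) !is.na(x$prominent), TRUE))) {
        markers[["subj"]] <- take_func()
        markers[["nsubj"]] <- take_func()
      }
      if (any(vapply(spec$voices, function(x) isTRUE(x$agent_marker), TRUE)))
        markers[["agent"]] <- take_func()
    }
    determiner <- if (spec$det_prob > 0) take_func() else NA_character_
    adjuncts <- funcs[seq.int(nf + 1L, length(funcs))]

    inv <- verb_class_inventory()
    verb_class <- inv[((seq_along(verbs) - 1L) %% length(inv)) + 1L]

    # noun pools per class: disjoint between A and P within a class, but
    # overlapping across classes, so a noun's role is cued by the verb
    # rather than globally (initial nouns stay role-ambiguous pre-verb)
    m <- max(2L, min(6L, floor(length(nouns) / 4)))
    class_pools <- lapply(unique(verb_class), function(cl) {
      pool <- sample(nouns, 2L * m)
      list(A = pool[seq_len(m)], P = pool[seq.int(m + 1L, 2L * m)])
    })
    names(class_pools) <- unique(verb_class)

    pron_nominality <- c("PRON_1SG", "PRON_2SG",
                         rep("PRON_OTHER", length(prons) - 2L))
    structure(list(noun = nouns, verb = verbs, pronoun = prons,
                   `function` = funcs, markers = markers,
                   determiner = determiner, adjuncts = adjuncts,
                   verb_class = verb_class, class_pools = class_pools,
                   pron_nominality = pron_nominality,
                   zipf_exponent = spec$zipf_exponent, seed = seed),
              class = "rp_lexicon")
  })
}

draw_pattern <- function(spec) {
  if (is.null(spec$voice_distribution)) {
    od <- spec$order_distribution
    list(voice = NA_character_,
         full = sample(names(od), 1, prob = od))
  } else {
    v <- sample(names(spec$voice_distribution), 1,
                prob = spec$voice_distribution)
    od <- spec$order_distribution[[v]]
    list(voice = v, full = sample(names(od), 1, prob = od))
  }
}

realize_argument <- function(spec, lex, role, verb_cl, voice,
                             force_noun = FALSE, force_mark = FALSE) {
  pp <- spec$pronoun_prob_by_role[[role]]
  is_pron <- !force_noun && runif(1) < pp$p
  if (is_pron) {
    typ <- sample(names(pp$dist), 1, prob = pp$dist)
    idx <- switch(typ, PRON_1SG = 1L, PRON_2SG = 2L,
                  2L + sample_zipf(length(lex$pronoun) - 2L,
                                   spec$zipf_exponent))
    tokens <- lex$pronoun[idx]
    nominality <- typ
  } else {
    pool <- if (runif(1) < spec$sel_strength)
      lex$class_pools[[verb_cl]][[role]] else lex$noun
    w <- pool[sample_zipf(length(pool), spec$zipf_exponent)]
    tokens <- w
    if (!is.na(lex$determiner) && runif(1) < spec$det_prob)
      tokens <- c(lex$determiner, w)
    nominality <- "OTHER"
  }
  if (spec$marking == "case_suffix") {
    if (force_mark || runif(1) < spec$case_mark_prob[[role]])
      tokens <- c(tokens, lex$markers[[role]])
  } else if (spec$marking == "voice_affix" && !is.na(voice)) {
    vc <- spec$voices[[voice]]
    if (!is.na(vc$prominent))
      tokens <- c(if (role == vc$prominent) lex$markers[["subj"]] else
                    lex$markers[["nsubj"]], tokens)
    if (isTRUE(vc$agent_marker) && role == "A")
      tokens <- c(lex$markers[["agent"]], tokens)
  }
  list(tokens = tokens, nominality = nominality)
}

realize_verb <- function(spec, lex, verb_idx, voice) {
  tokens <- lex$verb[verb_idx]
  if (spec$marking == "voice_affix" && !is.na(voice) &&
      isTRUE(spec$voices[[voice]]$affix))
    tokens <- c(lex$markers[[paste0("affix_", voice)]], tokens)
  tokens
}

# Draws one annotated utterance plus its latent-draw log entry.
draw_utterance <- function(spec, lex, id, length_lambda = spec$length_lambda,
                           inventory = NULL) {
  pat <- draw_pattern(spec)
  oms <- spec$omission_prob
  if (!is.na(pat$voice) && !is.null(spec$voice_omission[[pat$voice]]))
    oms <- spec$voice_omission[[pat$voice]]
  repeat {
    omA <- runif(1) < oms[["A"]]
    omP <- runif(1) < oms[["P"]]
    if (!(omA && omP)) break
  }
  overt <- pat$full
  if (omA) overt <- gsub("A", "", overt)
  if (omP) overt <- gsub("P", "", overt)

  verb_idx <- sample_zipf(length(lex$verb), spec$zipf_exponent)
  verb_cl <- lex$verb_class[verb_idx]

  tokens <- character(0)
  verb_span <- NULL
  args <- list()
  for (ch in strsplit(overt, "")[[1]]) {
    if (ch == "V") {
      vt <- realize_verb(spec, lex, verb_idx, pat$voice)
      verb_span <- c(length(tokens), length(tokens) + length(vt))
      tokens <- c(tokens, vt)
    } else {
      a <- realize_argument(spec, lex, ch, verb_cl, pat$voice)
      args[[length(args) + 1L]] <-
        arg_span(length(tokens), length(tokens) + length(a$tokens), ch,
                 a$nominality)
      tokens <- c(tokens, a$tokens)
    }
  }
  n_adj <- rpois(1, length_lambda)
  if (n_adj > 0 && length(lex$adjuncts))
    tokens <- c(tokens, lex$adjuncts[sample_zipf(length(lex$adjuncts),
                                                 spec$zipf_exponent, n_adj)])
  list(utt = utterance(id, spec$name, tokens, verb_span, verb_cl, args,
                       inventory = inventory),
       log = data.frame(id = id, voice = pat$voice, full_pattern = pat$full,
                        omit_A = omA, omit_P = omP, overt_pattern = overt,
                        stringsAsFactors = FALSE))
}

#' Generate a child-directed-utterance corpus
#'
#' Samples `n` annotated utterances from a language spec: per utterance a
#' voice (where applicable) and a full word-order pattern are drawn, each
#' role is independently omitted with its omission probability (rejecting
#' the zero-argument outcome), and arguments/verb are realized with gold
#' spans, roles, nominality and verb class. The full latent-draw log is
#' attached as `attr(corpus, "generation_log")` and is the exact oracle
#' for pattern counts.
#'
#' @param spec an `rp_language_spec`.
#' @param n number of utterances.
#' @param seed integer seed; the lexicon is `generate_lexicon(spec, seed)`.
#' @return an `rp_corpus` with a `generation_log` attribute.
#' @export
generate_cdu_corpus <- function(spec, n, seed) {
  lex <- generate_lexicon(spec, seed)
  inv <- verb_class_inventory()
  with_seed(seed + 1L, {
    draws <- lapply(seq_len(n), function(i)
      draw_utterance(spec, lex, sprintf("%s_%06d", spec$name, i),
                     inventory = inv))
    corp <- corpus(lapply(draws, `[[`, "utt"),
                   metadata = list(generator = "rolepred",
                                   spec_name = spec$name,
                                   seed = seed, n = n))
    attr(corp, "generation_log") <- do.call(rbind, lapply(draws, `[[`, "log"))
    attr(corp, "lexicon") <- lex
    corp
  })
}

#' Generate adult-directed pretraining text
#'
#' Unannotated token sequences from the same generative grammar as
#' [generate_cdu_corpus()] (same lexicon under the same seed), with longer
#' utterances (`adu_length_lambda` adjunct noise), stopping as soon as the
#' cumulative token count reaches `n_words`.
#'
#' @param spec an `rp_language_spec`.
#' @param n_words target total token count.
#' @param seed integer seed.
#' @return list of character vectors (one utterance each), with attribute
#'   `n_tokens`.
#' @export
generate_adu_text <- function(spec, n_words, seed) {
  lex <- generate_lexicon(spec, seed)
  with_seed(seed + 2L, {
    out <- list()
    total <- 0L
    i <- 0L
    while (total < n_words) {
      i <- i + 1L
      d <- draw_utterance(spec, lex, sprintf("adu_%06d", i),
                          length_lambda = spec$adu_length_lambda,
                          inventory = NULL)
      toks <- d$utt$tokens
      out[[i]] <- toks
      total <- total + length(toks)
    }
    attr(out, "n_tokens") <- total
    out
  })
}

#' Factorial stimulus design
#'
#' @param spec the `rp_language_spec` whose lexicon and marking system the
#'   stimuli use.
#' @param factors named list of factor levels. Supported factors:
#'   `voice` (levels must be voices of the spec), `initial_role`
#'   (`"A_initial"`, `"P_initial"`), `order` (`"verb_initial"`,
#'   `"verb_medial"`, `"verb_final"`).
#' @param items_per_cell number of lexically matched items.
#' @return an object of class `rp_stimulus_design`.
#' @export
stimulus_design <- function(spec, factors, items_per_cell = 8L) {
  validate_language_spec(spec)
  for (f in names(factors)) {
    lv <- factors[[f]]
    ok <- switch(f,
      voice = !is.null(spec$voice_distribution) &&
        all(lv %in% names(spec$voice_distribution)),
      initial_role = all(lv %in% c("A_initial", "P_initial")),
      order = all(lv %in% c("verb_initial", "verb_medial", "verb_final")),
      FALSE)
    if (!ok) stop(sprintf("factor '%s' incompatible with language spec '%s'",
                          f, spec$name), call. = FALSE)
  }
  structure(list(spec = spec, factors = factors,
                 items_per_cell = as.integer(items_per_cell)),
            class = "rp_stimulus_design")
}

default_verb_position <- function(spec) {
  switch(spec$marking, case_suffix = "verb_final",
         voice_affix = if (any(vapply(spec$voices,
                                      function(v) !is.na(v$prominent), TRUE)))
           "verb_initial" else "verb_medial",
         "verb_medial")
}

#' Generate factorial experimental stimuli
#'
#' Builds a full-factorial, lexically matched stimulus corpus: every item
#' keeps the same verb and the same two full lexical arguments (drawn from
#' the verb class's role pools) across all cells; cells differ only in
#' word order, voice and marking. Case markers are always realized in
#' stimuli. The per-utterance condition labels are attached as
#' `attr(corpus, "conditions")` (a data frame with one row per utterance).
#'
#' @param design an [stimulus_design()].
#' @param seed integer seed (controls item lexicalization only).
#' @return an `rp_corpus` with a `conditions` attribute.
#' @export
generate_stimuli <- function(design, seed) {
  spec <- design$spec
  lex <- generate_lexicon(spec, seed)
  inv <- verb_class_inventory()
  # reversible items: both arguments are plausible agents, so the nouns
  # are drawn uniformly from the lexicon (no selectional cue), as in
  # comprehension experiments with two lexical arguments
  items <- with_seed(seed + 3L, {
    lapply(seq_len(design$items_per_cell), function(k) {
      vi <- sample_zipf(length(lex$verb), spec$zipf_exponent)
      pair <- sample(lex$noun, 2)
      list(verb_idx = vi, verb_class = lex$verb_class[vi],
           A = pair[1], P = pair[2])
    })
  })
  cells <- expand.grid(design$factors, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)

  utts <- list(); cond_rows <- list()
  for (ci in seq_len(max(1L, nrow(cells)))) {
    cell <- if (ncol(cells)) as.list(cells[ci, , drop = FALSE]) else list()
    voice <- if (!is.null(cell$voice)) cell$voice else
      if (!is.null(spec$voice_distribution)) names(spec$voice_distribution)[1]
      else NA_character_
    init <- if (!is.null(cell$initial_role)) substr(cell$initial_role, 1, 1)
      else if (!is.na(voice) &&
               isTRUE(spec$voices[[voice]]$agent_marker)) "P"  # passive-like
      else "A"
    ordpos <- if (!is.null(cell$order)) cell$order else
      default_verb_position(spec)
    other <- if (init == "A") "P" else "A"
    pat <- switch(ordpos,
                  verb_initial = c("V", init, other),
                  verb_medial = c(init, "V", other),
                  verb_final = c(init, other, "V"))
    # passive-style voices invert surface prominence: realized via markers
    for (k in seq_along(items)) {
      it <- items[[k]]
      tokens <- character(0); verb_span <- NULL; args <- list()
      for (ch in pat) {
        if (ch == "V") {
          vt <- realize_verb(spec, lex, it$verb_idx, voice)
          verb_span <- c(length(tokens), length(tokens) + length(vt))
          tokens <- c(tokens, vt)
        } else {
          toks <- it[[ch]]
          if (!is.na(lex$determiner) && spec$det_prob > 0)
            toks <- c(lex$determiner, toks)
          if (spec$marking == "case_suffix")
            toks <- c(toks, lex$markers[[ch]])
          if (spec$marking == "voice_affix" && !is.na(voice)) {
            vc <- spec$voices[[voice]]
            if (!is.na(vc$prominent))
              toks <- c(if (ch == vc$prominent) lex$markers[["subj"]] else
                          lex$markers[["nsubj"]], toks)
            if (isTRUE(vc$agent_marker) && ch == "A")
              toks <- c(lex$markers[["agent"]], toks)
          }
          args[[length(args) + 1L]] <-
            arg_span(length(tokens), length(tokens) + length(toks), ch, "OTHER")
          tokens <- c(tokens, toks)
        }
      }
      lab <- if (ncol(cells))
        paste(vapply(cell, as.character, ""), collapse = ".") else "all"
      id <- sprintf("stim_%03d_%s", k, lab)
      utts[[length(utts) + 1L]] <-
        utterance(id, spec$name, tokens, verb_span, it$verb_class, args,
                  inventory = inv)
      cond_rows[[length(cond_rows) + 1L]] <-
        cbind(data.frame(id = id, item = k, stringsAsFactors = FALSE),
              if (ncol(cells)) cells[ci, , drop = FALSE] else NULL,
              row.names = NULL)
    }
  }
  corp <- corpus(utts, metadata = list(generator = "rolepred_stimuli",
                                       spec_name = spec$name, seed = seed))
  attr(corp, "conditions") <- do.call(rbind, cond_rows)
  attr(corp, "lexicon") <- lex
  corp
}
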