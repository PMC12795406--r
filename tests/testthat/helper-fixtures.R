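# Shared fixtures: tiny hand-built utterances and generated corpora.

toy_inventory <- function() verb_class_inventory()

# "the fox | hunts | the chicken" — canonical transitive AVP
utt_avp <- function(id = "u1") {
  utterance(id, "toy", c("the", "fox", "hunts", "the", "chicken"),
            verb_span = c(2, 3), verb_class = "pursuit",
            arguments = list(arg_span(0, 2, "A", "OTHER"),
                             arg_span(3, 5, "P", "OTHER")))
}

# P-initial single-argument utterance (A omitted): "cake eat"
utt_pv <- function(id = "u2") {
  utterance(id, "toy", c("cake", "eat"), verb_span = c(1, 2),
            verb_class = "ingestion",
            arguments = list(arg_span(0, 1, "P", "OTHER")))
}

# build an utterance from a pattern string with single-token elements
utt_from_pattern <- function(pattern, id = pattern) {
  chars <- strsplit(pattern, "")[[1]]
  args <- list()
  verb_span <- NULL
  for (i in seq_along(chars)) {
    if (chars[i] == "V") verb_span <- c(i - 1, i)
    else args[[length(args) + 1L]] <-
        arg_span(i - 1, i, chars[i], "OTHER")
  }
  utterance(id, "toy", paste0("w", seq_along(chars)), verb_span,
            "motion", args)
}

# all overt patterns with a verb and >= 1 argument
all_overt_patterns <- function() {
  c("AV", "VA", "PV", "VP",
    "APV", "AVP", "PAV", "PVA", "VAP", "VPA")
}

# a fake trajectory with seeded random probabilities for a pattern utterance
fake_trajectory <- function(utt, seed = 1) {
  e <- rolepred:::utt_to_elements(utt, c("<unk>", "<eos>"))
  Tn <- e$n_elements
  nA <- length(utt$arguments)
  probA <- matrix(NA_real_, nA, Tn)
  set.seed(seed)
  for (j in seq_len(nA))
    for (t in seq_len(Tn))
      if (t >= e$args[j]) probA[j, t] <- runif(1)
  structure(list(id = utt$id, probA = probA, arg_elements = e$args,
                 verb_element = e$verb,
                 roles = vapply(utt$arguments, `[[`, "", "role"),
                 n_elements = Tn, elements = e$elements, nextword = NULL),
            class = "rp_role_trajectory")
}

# Independent brute-force oracle for record extraction: walk the element
# sequence of a pattern; an argument is read off at every element that is
# itself, the other argument, or the verb, from its first occurrence
# onward; flags record what has been consumed up to and including that
# element.
oracle_records <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  args <- which(chars != "V")
  verb <- which(chars == "V")
  out <- list()
  for (a in args) {
    other <- setdiff(args, a)
    for (t in seq_along(chars)) {
      if (t < a) next
      if (!(t == a || t %in% other || t == verb)) next
      out[[length(out) + 1L]] <- data.frame(
        role = chars[a], event_t = t,
        after_argument = length(other) > 0 && other <= t,
        after_verb = verb <= t, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# simulated predictability records from a beta GLMM with known effects
sim_beta_records <- function(n, beta = c(0.3, 0.8, -0.5), phi = 20,
                             sd_g = 0.3, G = 50, seed = 1,
                             av_effect = NULL) {
  with_seed(seed, {
    g <- sample(G, n, replace = TRUE)
    aa <- rbinom(n, 1, 0.5)
    av <- rbinom(n, 1, 0.5)
    role <- rbinom(n, 1, 0.5)
    u <- rnorm(G, 0, sd_g)
    eta <- beta[1] + beta[2] * aa + beta[3] * role + u[g] +
      if (!is.null(av_effect)) av_effect * av else 0
    mu <- stats::plogis(eta)
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    data.frame(p_correct = pmin(pmax(y, 1e-6), 1 - 1e-6),
               after_argument = aa == 1, after_verb = av == 1,
               role = ifelse(role == 1, "P", "A"),
               sentence_id = as.character(g), stringsAsFactors = FALSE)
  })
}

# small trained model on the deterministic-cue preset, cached per session
cached_det_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sp <- preset_language_spec("verb_final_deterministic")
    corp <- generate_cdu_corpus(sp, 600, 402)
    vocab <- build_vocab(list(corp))
    cfg <- srp_config(vocab, seed = 5, max_epochs = 6)
    idx <- with(list(), { set.seed(11); sample(length(corp$utterances)) })
    tr <- corpus(corp$utterances[idx[1:480]])
    va <- corpus(corp$utterances[idx[481:540]])
    te <- corpus(corp$utterances[idx[541:600]])
    m <- train_main(srp_init(cfg), tr, va, from_scratch = TRUE)
    cache <<- list(model = m, train = tr, val = va, test = te, corpus = corp,
                   spec = sp)
    cache
  }
})
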