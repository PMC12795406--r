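UNK_ID <- 1L
EOS_ID <- 2L

#' Build a token vocabulary
#'
#' @param sources a list whose elements are character token vectors,
#'   `rp_corpus` objects, or ADU text lists.
#' @param min_count minimum token frequency; rarer tokens map to `<unk>`.
#' @return character vector with `<unk>` and `<eos>` reserved in front.
#' @export
build_vocab <- function(sources, min_count = 1L) {
  toks <- unlist(lapply(sources, function(s) {
    if (inherits(s, "rp_corpus")) unlist(lapply(s$utterances, `[[`, "tokens"))
    else unlist(s)
  }))
  tab <- table(toks)
  keep <- names(tab)[tab >= min_count]
  c("<unk>", "<eos>", sort(keep))
}

#' Model configuration for the semantic role prediction model
#'
#' @param vocab character vector from [build_vocab()].
#' @param embedding_mode `"learned"` (trainable token embeddings),
#'   `"hash_random"` (fixed, deterministic per-surface hash vectors; no
#'   OOV problem, no download, used in tests), or `"pretrained_vectors"`
#'   (fixed vectors loaded from a word-vector text file).
#' @param embedding_dim,encoder_hidden_dim,processor_hidden_dim,classifier_hidden_dim
#'   layer sizes (positive integers).
#' @param learning_rate,batch_size,max_epochs,patience Adam optimizer and
#'   early-stopping settings.
#' @param lambda weight of the next-word loss in the joint (main) stage.
#' @param seed integer seed controlling parameter initialization, data
#'   shuffling and fold assignment.
#' @param vector_file path to a word-vector text file
#'   (`word v1 v2 ...` per line), required for `pretrained_vectors`.
#' @return a list of class `rp_srp_config`.
#' @export
srp_config <- function(vocab,
                       embedding_mode = c("learned", "hash_random",
                                          "pretrained_vectors"),
                       embedding_dim = 24L, encoder_hidden_dim = 32L,
                       processor_hidden_dim = 48L,
                       classifier_hidden_dim = 32L,
                       learning_rate = 0.01, batch_size = 16L,
                       max_epochs = 15L, patience = 3L, lambda = 1.0,
                       seed = 1L, vector_file = NULL) {
  embedding_mode <- match.arg(embedding_mode)
  stopifnot(embedding_dim > 0, encoder_hidden_dim > 0,
            processor_hidden_dim > 0, classifier_hidden_dim > 0,
            lambda >= 0, vocab[1] == "<unk>")
  structure(list(vocab = vocab, embedding_mode = embedding_mode,
                 embedding_dim = as.integer(embedding_dim),
                 encoder_hidden_dim = as.integer(encoder_hidden_dim),
                 processor_hidden_dim = as.integer(processor_hidden_dim),
                 classifier_hidden_dim = as.integer(classifier_hidden_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lambda = lambda, seed = as.integer(seed),
                 vector_file = vector_file),
            class = "rp_srp_config")
}

srp_dims <- function(config) {
  c(length(config$vocab), config$embedding_dim, config$encoder_hidden_dim,
    config$processor_hidden_dim, config$classifier_hidden_dim)
}

# parameter block layout; must mirror the C++ side exactly
srp_offsets <- function(dims) {
  V <- dims[1]; d <- dims[2]; He <- dims[3]; Hp <- dims[4]; Hc <- dims[5]
  Din <- 2 * He + Hp
  blocks <- list(Emb = c(d, V),
                 Wxe = c(4 * He, d), Whe = c(4 * He, He), be = c(4 * He, 1),
                 Wxp = c(4 * Hp, He), Whp = c(4 * Hp, Hp), bp = c(4 * Hp, 1),
                 W1n = c(Hc, Hp), b1n = c(Hc, 1), W2n = c(V, Hc),
                 b2n = c(V, 1),
                 W1r = c(Hc, Din), b1r = c(Hc, 1), W2r = c(2, Hc),
                 b2r = c(2, 1))
  off <- 0L
  out <- list()
  for (nm in names(blocks)) {
    n <- prod(blocks[[nm]])
    out[[nm]] <- list(offset = off, dim = blocks[[nm]], n = n)
    off <- off + n
  }
  attr(out, "total") <- off
  out
}

block_idx <- function(offs, nm) {
  b <- offs[[nm]]
  seq.int(b$offset + 1L, b$offset + b$n)
}

# deterministic polynomial hash of a surface string (stable across
# processes; used to seed per-word fixed embeddings in hash_random mode)
surface_hash <- function(word) {
  h <- 7
  for (b in utf8ToInt(enc2utf8(word))) h <- (h * 31 + b) %% 1000000007
  as.integer(h %% 2147483647)
}

hash_embedding <- function(vocab, d, seed) {
  E <- matrix(0, d, length(vocab))
  for (j in seq_along(vocab)) {
    E[, j] <- with_seed((surface_hash(vocab[j]) + seed) %% 2147483647,
                        rnorm(d, 0, 0.3))
  }
  E
}

read_word_vectors <- function(path, vocab, d) {
  lines <- readLines(path, encoding = "UTF-8")
  E <- matrix(0, d, length(vocab))
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    j <- match(parts[1], vocab)
    if (!is.na(j)) {
      v <- as.numeric(parts[-1])
      if (length(v) != d) stop("vector dimension mismatch in ", path,
                               call. = FALSE)
      E[, j] <- v
    }
  }
  E
}

#' Initialize a semantic role prediction model
#'
#' Weights are drawn uniformly in (-0.1, 0.1) under the config seed,
#' forget-gate biases start at 1, and both softmax output layers start at
#' zero (so an untrained model assigns exactly 0.5/0.5 to the two roles).
#'
#' @param config an [srp_config()].
#' @return an object of class `rp_srp_model`.
#' @export
srp_init <- function(config) {
  dims <- srp_dims(config)
  offs <- srp_offsets(dims)
  n <- attr(offs, "total")
  stopifnot(n == cpp_srp_param_count(dims))
  params <- with_seed(config$seed, runif(n, -0.1, 0.1))
  params[block_idx(offs, "W2n")] <- 0
  params[block_idx(offs, "b2n")] <- 0
  params[block_idx(offs, "W2r")] <- 0
  params[block_idx(offs, "b2r")] <- 0
  He <- dims[3]; Hp <- dims[4]
  be <- block_idx(offs, "be"); params[be[seq.int(He + 1, 2 * He)]] <- 1
  bp <- block_idx(offs, "bp"); params[bp[seq.int(Hp + 1, 2 * Hp)]] <- 1

  fixed_embedding <- config$embedding_mode != "learned"
  ei <- block_idx(offs, "Emb")
  if (config$embedding_mode == "hash_random") {
    params[ei] <- as.vector(hash_embedding(config$vocab, dims[2],
                                           config$seed))
  } else if (config$embedding_mode == "pretrained_vectors") {
    if (is.null(config$vector_file))
      stop("pretrained_vectors mode needs config$vector_file", call. = FALSE)
    params[ei] <- as.vector(read_word_vectors(config$vector_file,
                                              config$vocab, dims[2]))
  }
  structure(list(config = config, dims = dims, params = params,
                 fixed_embedding = fixed_embedding,
                 provenance = list(stages = character(0))),
            class = "rp_srp_model")
}

#' @export
print.rp_srp_model <- function(x, ...) {
  cat(sprintf(
    "<rp_srp_model> V=%d d=%d He=%d Hp=%d Hc=%d (%d params) [%s] stages: %s\n",
    x$dims[1], x$dims[2], x$dims[3], x$dims[4], x$dims[5], length(x$params),
    x$config$embedding_mode,
    if (length(x$provenance$stages)) paste(x$provenance$stages, collapse = "+")
    else "untrained"))
  invisible(x)
}

token_ids <- function(tokens, vocab) {
  i <- match(tokens, vocab)
  i[is.na(i)] <- UNK_ID
  as.integer(i)
}

# Partition an annotated utterance into processing elements: each argument
# span and the verb span are consumed as single elements; every other token
# is an element of its own.
utt_to_elements <- function(utt, vocab) {
  n <- length(utt$tokens)
  spans <- list(list(start = utt$verb_span[1], end = utt$verb_span[2],
                     kind = "V", arg = NA_integer_))
  for (j in seq_along(utt$arguments)) {
    a <- utt$arguments[[j]]
    spans[[length(spans) + 1L]] <-
      list(start = a$start, end = a$end, kind = a$role, arg = j)
  }
  starts <- vapply(spans, `[[`, 0L, "start")
  spans <- spans[order(starts)]
  elements <- list(); ids <- list()
  arg_elem <- integer(length(utt$arguments)); verb_elem <- NA_integer_
  pos <- 0L; si <- 1L
  while (pos < n) {
    if (si <= length(spans) && spans[[si]]$start == pos) {
      sp <- spans[[si]]
      toks <- utt$tokens[(sp$start + 1):sp$end]
      elements[[length(elements) + 1L]] <- toks
      if (sp$kind == "V") verb_elem <- length(elements)
      else arg_elem[sp$arg] <- length(elements)
      pos <- sp$end; si <- si + 1L
    } else {
      elements[[length(elements) + 1L]] <- utt$tokens[pos + 1L]
      pos <- pos + 1L
    }
  }
  Tn <- length(elements)
  nw <- c(vapply(elements[-1], function(e) token_ids(e[1], vocab), 0L),
          EOS_ID)
  list(elements = elements,
       ids = lapply(elements, token_ids, vocab = vocab),
       args = arg_elem,
       roles = match(vapply(utt$arguments, `[[`, "", "role"), ROLE_LEVELS),
       verb = verb_elem, nw = as.integer(nw), n_elements = Tn)
}

# C++-ready representation of one annotated utterance
utt_payload <- function(utt, vocab) {
  e <- utt_to_elements(utt, vocab)
  list(elements = e$ids, args = as.integer(e$args),
       roles = as.integer(e$roles), verb = as.integer(e$verb), nw = e$nw)
}

# C++-ready representation of one unannotated token sequence
seq_payload <- function(tokens, vocab) {
  ids <- token_ids(tokens, vocab)
  list(elements = as.list(ids), args = integer(0), roles = integer(0),
       verb = 0L,
       nw = c(ids[-1][seq_len(max(0, length(ids) - 1))], EOS_ID))
}

corpus_payloads <- function(corp, vocab) {
  lapply(corp$utterances, utt_payload, vocab = vocab)
}

#' Training loss of the semantic role prediction model
#'
#' Pretraining stage: mean per-position next-word cross-entropy. Main
#' stage: final-position role cross-entropy summed over the utterance's
#' arguments plus `lambda` times the next-word term. For a batch, the mean
#' over utterances is returned; the components are attached as attributes
#' `nw_loss` and `role_loss`.
#'
#' @param batch an `rp_corpus`, a list of `rp_utterance`s, or (pretrain
#'   stage) a list of token vectors.
#' @param model an `rp_srp_model`.
#' @param stage `"pretrain"` or `"main"`.
#' @return scalar loss.
#' @export
training_loss <- function(batch, model, stage = c("main", "pretrain")) {
  stage <- match.arg(stage)
  payloads <- batch_payloads(batch, model$config$vocab, stage)
  if (!length(payloads)) stop("empty batch", call. = FALSE)
  r <- cpp_srp_loss_grad(model$params, model$dims, payloads,
                         model$config$lambda,
                         if (stage == "main") 1L else 0L, FALSE)
  structure(r$loss / length(payloads),
            nw_loss = r$nw_loss / length(payloads),
            role_loss = r$role_loss / length(payloads))
}

batch_payloads <- function(batch, vocab, stage) {
  if (inherits(batch, "rp_corpus")) batch <- batch$utterances
  lapply(batch, function(b) {
    if (inherits(b, "rp_utterance")) {
      if (stage == "main" && !length(b$arguments))
        stop("main stage requires utterances with >= 1 argument",
             call. = FALSE)
      utt_payload(b, vocab)
    } else if (is.character(b)) {
      if (stage == "main")
        stop("main stage requires annotated utterances, got raw tokens",
             call. = FALSE)
      seq_payload(b, vocab)
    } else stop("unsupported batch element", call. = FALSE)
  })
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(params, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(params = params - lr * mhat / (sqrt(vhat) + eps), state = st)
}

run_epochs <- function(model, train_payloads, val_payloads, stage,
                       max_epochs, select = c("loss", "accuracy"),
                       trace = FALSE) {
  select <- match.arg(select)
  cfg <- model$config
  offs <- srp_offsets(model$dims)
  emb_idx <- if (model$fixed_embedding) block_idx(offs, "Emb") else integer(0)
  st <- adam_state(length(model$params))
  params <- model$params
  stage_i <- if (stage == "main") 1L else 0L
  n <- length(train_payloads)
  best <- list(params = params, score = Inf, epoch = 0L)
  log <- list()
  eval_split <- function(pl) {
    r <- cpp_srp_loss_grad(params, model$dims, pl, cfg$lambda, stage_i, FALSE)
    list(loss = r$loss / length(pl),
         nw = r$nw_loss / length(pl), role = r$role_loss / length(pl),
         acc = if (r$n_role > 0) r$n_correct / r$n_role else NA_real_)
  }
  v0 <- eval_split(val_payloads)
  log[[1]] <- data.frame(epoch = 0L, split = "val", loss = v0$loss,
                         nw_loss = v0$nw, role_loss = v0$role, acc = v0$acc)
  best$score <- if (select == "accuracy") -v0$acc else v0$loss
  bad <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
      r <- cpp_srp_loss_grad(params, model$dims, train_payloads[idx],
                             cfg$lambda, stage_i, TRUE)
      g <- as.numeric(r$grad) / length(idx)
      if (length(emb_idx)) g[emb_idx] <- 0
      up <- adam_step(params, g, st, cfg$learning_rate)
      params <- up$params; st <- up$state
    }
    v <- eval_split(val_payloads)
    log[[length(log) + 1L]] <-
      data.frame(epoch = ep, split = "val", loss = v$loss, nw_loss = v$nw,
                 role_loss = v$role, acc = v$acc)
    if (trace)
      message(sprintf("[%s] epoch %d val loss %.4f acc %s", stage, ep,
                      v$loss, format(v$acc, digits = 3)))
    score <- if (select == "accuracy") -v$acc else v$loss
    if (score < best$score - 1e-6) {
      best <- list(params = params, score = score, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$log <- rbind(if (!is.null(model$log)) model$log else NULL,
                     cbind(stage = stage, do.call(rbind, log)))
  model$provenance$stages <- c(model$provenance$stages, stage)
  model$provenance$best_epoch <- best$epoch
  model
}

#' Pretrain on adult-directed text (next-word prediction only)
#'
#' Trains the embeddings (in `learned` mode), the sequential encoder, the
#' sentence processor and the next-word predictor on unannotated token
#' sequences; the role classifier is untouched (its zero-initialized
#' output layer stays zero). A seeded 90/10 train/validation split drives
#' early stopping on validation next-word loss.
#'
#' @param adu list of character token vectors, e.g. from
#'   [generate_adu_text()].
#' @param config an [srp_config()].
#' @param trace print per-epoch progress.
#' @return a pretrained `rp_srp_model` with a training log in `$log`.
#' @export
pretrain <- function(adu, config, trace = FALSE) {
  if (!length(adu)) stop("empty pretraining corpus", call. = FALSE)
  model <- srp_init(config)
  payloads <- lapply(adu, seq_payload, vocab = config$vocab)
  with_seed(config$seed + 17L, {
    n <- length(payloads)
    val_n <- max(1L, floor(0.1 * n))
    vi <- sample.int(n, val_n)
    run_epochs(model, payloads[-vi], payloads[vi], "pretrain",
               config$max_epochs, select = "loss", trace = trace)
  })
}

#' Main joint training stage (role classification + next-word prediction)
#'
#' Trains all components jointly: final-position role cross-entropy plus
#' `lambda` times the next-word loss. Early stopping monitors validation
#' role accuracy; the best-epoch parameters are returned.
#'
#' @param model a pretrained (or freshly initialized, with
#'   `from_scratch = TRUE`) `rp_srp_model`.
#' @param train,val annotated `rp_corpus` objects (all utterances must
#'   have at least one argument).
#' @param from_scratch allow training without a pretraining stage.
#' @param trace print per-epoch progress.
#' @return the trained `rp_srp_model`.
#' @export
train_main <- function(model, train, val, from_scratch = FALSE,
                       trace = FALSE) {
  if (!length(train$utterances)) stop("empty training set", call. = FALSE)
  if (!("pretrain" %in% model$provenance$stages) && !from_scratch)
    stop("model is not pretrained; pass from_scratch = TRUE to override",
         call. = FALSE)
  cfg <- model$config
  tp <- corpus_payloads(train, cfg$vocab)
  vp <- corpus_payloads(val, cfg$vocab)
  with_seed(cfg$seed + 31L,
            run_epochs(model, tp, vp, "main", cfg$max_epochs,
                       select = "accuracy", trace = trace))
}

#' Incremental forward pass: the role trajectory of one utterance
#'
#' Consumes the utterance's elements in surface order (argument spans and
#' the verb span as single elements, every other token alone). At each
#' time point the role classifier re-classifies every argument seen so
#' far, independently of the other argument's classification; before the
#' verb has been encountered its input slot is a zero vector. Gold role
#' labels are not used.
#'
#' @param utt an `rp_utterance` (gold spans required).
#' @param model a (trained) `rp_srp_model`.
#' @param want_nextword also return the per-position next-word
#'   distribution over the vocabulary.
#' @return an object of class `rp_role_trajectory`: `prob` is an
#'   `n_arguments x n_elements` matrix of P(role = A), `NA` before the
#'   argument has appeared.
#' @export
incremental_forward <- function(utt, model, want_nextword = FALSE) {
  e <- utt_to_elements(utt, model$config$vocab)
  if (is.na(e$verb)) stop("utterance without verb span", call. = FALSE)
  pay <- list(elements = e$ids, args = as.integer(e$args),
              roles = as.integer(e$roles), verb = as.integer(e$verb),
              nw = e$nw)
  r <- cpp_srp_forward(model$params, model$dims, pay, want_nextword)
  structure(list(id = utt$id, probA = r$probA,
                 arg_elements = e$args, verb_element = e$verb,
                 roles = vapply(utt$arguments, `[[`, "", "role"),
                 n_elements = r$n_elements,
                 elements = e$elements,
                 nextword = if (want_nextword) r$nextword else NULL),
            class = "rp_role_trajectory")
}

#' @export
print.rp_role_trajectory <- function(x, ...) {
  cat(sprintf("<rp_role_trajectory %s> %d elements, %d argument(s)\n",
              x$id, x$n_elements, nrow(x$probA)))
  if (nrow(x$probA)) {
    m <- round(x$probA, 3)
    rownames(m) <- paste0("P(A|.) arg_", x$roles)
    colnames(m) <- vapply(x$elements, paste, "", collapse = "_")
    print(m)
  }
  invisible(x)
}

#' Encode one element (argument span or single token)
#'
#' Runs the sequential encoder over the per-token embeddings and returns
#' the fixed-length representation that the classifier sees.
#'
#' @param tokens non-empty character vector.
#' @param model an `rp_srp_model`.
#' @return numeric vector of length `encoder_hidden_dim`.
#' @export
embed_element <- function(tokens, model) {
  if (!length(tokens)) stop("empty span", call. = FALSE)
  as.numeric(cpp_srp_encode(model$params, model$dims,
                            token_ids(tokens, model$config$vocab)))
}

#' Held-out per-position evaluation with k-fold cross-validation
#'
#' Partitions the corpus into `k` folds (seeded). For each fold the
#' remaining data is split 90/10 into train/validation, a model is trained
#' (optionally warm-started from a pretrained model) and the held-out
#' utterances' trajectories are computed, so that every utterance's
#' reported trajectory comes from a model that never saw it in training.
#'
#' @param corp annotated `rp_corpus` (size >= k).
#' @param k number of folds (default 10).
#' @param config an [srp_config()].
#' @param pretrained optional pretrained `rp_srp_model` used to warm-start
#'   every fold.
#' @param trace print progress.
#' @return list with `trajectories` (named by utterance id),
#'   `fold_accuracy` (data frame: fold, n_arguments, accuracy at the final
#'   position), and `folds` (the fold assignment).
#' @export
kfold_evaluate <- function(corp, k = 10L, config, pretrained = NULL,
                           trace = FALSE) {
  n <- length(corp$utterances)
  if (n < k) stop("corpus smaller than k", call. = FALSE)
  folds <- with_seed(config$seed + 101L,
                     sample(rep_len(seq_len(k), n)))
  trajectories <- vector("list", n)
  names(trajectories) <- vapply(corp$utterances, `[[`, "", "id")
  fold_rows <- list()
  for (f in seq_len(k)) {
    test_i <- which(folds == f)
    rest <- which(folds != f)
    rest <- with_seed(config$seed + 1000L + f, sample(rest))
    val_n <- max(1L, floor(0.1 * length(rest)))
    val_i <- rest[seq_len(val_n)]
    train_i <- rest[-seq_len(val_n)]
    cfg_f <- config
    cfg_f$seed <- config$seed + 10L * f
    m0 <- if (is.null(pretrained)) srp_init(cfg_f) else {
      m <- pretrained; m$config$seed <- cfg_f$seed; m
    }
    mf <- train_main(m0, corpus(corp$utterances[train_i]),
                     corpus(corp$utterances[val_i]),
                     from_scratch = is.null(pretrained), trace = FALSE)
    nc <- 0L; na_ <- 0L
    for (i in test_i) {
      tr <- incremental_forward(corp$utterances[[i]], mf)
      trajectories[[i]] <- tr
      if (nrow(tr$probA)) {
        pA <- tr$probA[, tr$n_elements]
        pred <- ifelse(pA >= 0.5, "A", "P")
        nc <- nc + sum(pred == tr$roles)
        na_ <- na_ + length(pred)
      }
    }
    fold_rows[[f]] <- data.frame(fold = f, n_arguments = na_,
                                 accuracy = nc / na_)
    if (trace)
      message(sprintf("fold %d/%d: accuracy %.3f (n=%d)", f, k,
                      nc / na_, na_))
  }
  list(trajectories = trajectories,
       fold_accuracy = do.call(rbind, fold_rows), folds = folds)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive: config (minus the environment-dependent
#' vector file), dims, provenance and the full-precision parameter
#' vector. A loaded model reproduces bit-identical trajectories.
#'
#' @param model an `rp_srp_model`.
#' @param path file path.
#' @export
save_srp_model <- function(model, path) {
  obj <- list(config = unclass(model$config), dims = model$dims,
              fixed_embedding = model$fixed_embedding,
              provenance = model$provenance,
              params = sprintf("%.17g", model$params))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' @rdname save_srp_model
#' @export
load_srp_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$vocab <- as.character(cfg$vocab)
  class(cfg) <- "rp_srp_config"
  structure(list(config = cfg, dims = as.integer(obj$dims),
                 params = as.numeric(obj$params),
                 fixed_embedding = obj$fixed_embedding,
                 provenance = obj$provenance),
            class = "rp_srp_model")
}
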