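#' @useDynLib rolepred, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois rbinom sd quantile setNames aggregate
#' @importFrom utils head tail modifyList write.table read.table
NULL

ROLE_LEVELS <- c("A", "P")
NOMINALITY_LEVELS <- c("PRON_1SG", "PRON_2SG", "PRON_OTHER", "OTHER")

#' Verb class inventory
#'
#' Returns the inventory of verb class labels shipped with the package
#' (48 semantically defined classes in the spirit of large typological
#' databases: perception, motion, ingestion, ...). The file
#' `inst/extdata/verb_classes.txt` can be edited or replaced; unknown labels
#' are rejected when a corpus is read or constructed.
#'
#' @param path optional path to an alternative one-label-per-line file.
#' @return character vector of class labels.
#' @export
verb_class_inventory <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "verb_classes.txt", package = "rolepred")
  }
  readLines(path, encoding = "UTF-8")
}

norm_nfc <- function(x) {
  # NFC-normalize surfaces; preserve case (character-level cues may use it)
  stringi::stri_trans_nfc(enc2utf8(x))
}

#' Construct an argument span
#'
#' @param start,end 0-based half-open token indices.
#' @param role `"A"` (proto-agent) or `"P"` (proto-patient).
#' @param nominality one of `PRON_1SG`, `PRON_2SG`, `PRON_OTHER`, `OTHER`.
#' @return a list of class `rp_argspan`.
#' @export
arg_span <- function(start, end, role, nominality = "OTHER") {
  structure(list(start = as.integer(start), end = as.integer(end),
                 role = role, nominality = nominality),
            class = "rp_argspan")
}

#' Construct an annotated utterance
#'
#' One utterance with tokens, a verb span and 0-2 role-labeled argument
#' spans. All spans are 0-based half-open `[start, end)` over token indices.
#'
#' @param id unique utterance identifier (string).
#' @param language language tag.
#' @param tokens character vector of surface tokens.
#' @param verb_span integer length-2 `[start, end)` of the verb.
#' @param verb_class a label from [verb_class_inventory()].
#' @param arguments list of [arg_span()] objects with distinct roles.
#' @param validate check invariants (default `TRUE`).
#' @param inventory verb-class inventory to validate against.
#' @return a list of class `rp_utterance`.
#' @export
utterance <- function(id, language, tokens, verb_span, verb_class,
                      arguments = list(), validate = TRUE,
                      inventory = verb_class_inventory()) {
  u <- structure(list(id = as.character(id), language = as.character(language),
                      tokens = norm_nfc(as.character(tokens)),
                      verb_span = as.integer(verb_span),
                      verb_class = as.character(verb_class),
                      arguments = arguments),
                 class = "rp_utterance")
  if (validate) validate_utterance(u, inventory = inventory)
  u
}

span_ok <- function(s, e, n) {
  is.finite(s) && is.finite(e) && s >= 0 && s < e && e <= n
}

spans_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

#' Validate an annotated utterance
#'
#' Checks all structural invariants: non-empty tokens, one in-range verb
#' span, at most one A and one P argument, in-range non-overlapping
#' argument spans, known nominality and verb-class labels. Errors name the
#' utterance id and the offending field.
#'
#' @param u an `rp_utterance`.
#' @param inventory verb-class inventory (`NULL` skips the check).
#' @return `u`, invisibly.
#' @export
validate_utterance <- function(u, inventory = verb_class_inventory()) {
  fail <- function(field, msg)
    stop(sprintf("utterance '%s': invalid %s: %s", u$id, field, msg),
         call. = FALSE)
  n <- length(u$tokens)
  if (n == 0L) fail("tokens", "empty utterance")
  if (any(!nzchar(u$tokens))) fail("tokens", "empty surface string")
  if (length(u$verb_span) != 2L || !span_ok(u$verb_span[1], u$verb_span[2], n))
    fail("verb_span", sprintf("[%s) not within 0..%d",
                              paste(u$verb_span, collapse = ","), n))
  if (!is.null(inventory) && !(u$verb_class %in% inventory))
    fail("verb_class", sprintf("unknown label '%s'", u$verb_class))
  if (length(u$arguments) > 2L) fail("arguments", "more than 2 arguments")
  roles <- vapply(u$arguments, `[[`, "", "role")
  if (anyDuplicated(roles)) fail("arguments", "duplicated role")
  spans <- lapply(u$arguments, function(a) c(a$start, a$end))
  for (i in seq_along(u$arguments)) {
    a <- u$arguments[[i]]
    if (!a$role %in% ROLE_LEVELS) fail("arguments", sprintf("role '%s'", a$role))
    if (!a$nominality %in% NOMINALITY_LEVELS)
      fail("arguments", sprintf("nominality '%s'", a$nominality))
    if (!span_ok(a$start, a$end, n))
      fail("arguments", sprintf("span [%d,%d) not within 0..%d", a$start, a$end, n))
    if (spans_overlap(spans[[i]], u$verb_span))
      fail("arguments", sprintf("argument span [%d,%d) overlaps verb span",
                                a$start, a$end))
    if (i == 2L && spans_overlap(spans[[1]], spans[[2]]))
      fail("arguments", "argument spans overlap")
  }
  invisible(u)
}

#' Construct a corpus
#'
#' @param utterances list of [utterance()] objects with unique ids.
#' @param metadata free-form provenance list (generator spec hash or import
#'   source).
#' @return a list of class `rp_corpus`.
#' @export
corpus <- function(utterances, metadata = list()) {
  ids <- vapply(utterances, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate utterance ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(utterances = utterances, metadata = metadata),
            class = "rp_corpus")
}

#' @export
length.rp_corpus <- function(x) length(x$utterances)

#' @export
print.rp_corpus <- function(x, ...) {
  langs <- unique(vapply(x$utterances, `[[`, "", "language"))
  cat(sprintf("<rp_corpus> %d utterances [%s]\n", length(x),
              paste(langs, collapse = ", ")))
  invisible(x)
}

#' @export
print.rp_utterance <- function(x, ...) {
  cat(sprintf("<rp_utterance %s/%s> %s | pattern %s\n", x$language, x$id,
              paste(x$tokens, collapse = " "), word_order_pattern(x)))
  invisible(x)
}

utt_to_json <- function(u) {
  args <- lapply(u$arguments, function(a)
    list(span = c(a$start, a$end), role = jsonlite::unbox(a$role),
         nominality = jsonlite::unbox(a$nominality)))
  obj <- list(id = jsonlite::unbox(u$id),
              language = jsonlite::unbox(u$language),
              tokens = u$tokens,
              verb = u$verb_span,
              verb_class = jsonlite::unbox(u$verb_class),
              arguments = args)
  as.character(jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA))
}

utt_from_json <- function(line, inventory) {
  obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  need <- c("id", "language", "tokens", "verb", "verb_class", "arguments")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop(sprintf("utterance '%s': missing field(s) %s",
                 if (is.null(obj$id)) "<no id>" else obj$id,
                 paste(miss, collapse = ", ")), call. = FALSE)
  args <- lapply(obj$arguments, function(a)
    arg_span(a$span[[1]], a$span[[2]], a$role, a$nominality))
  utterance(obj$id, obj$language, unlist(obj$tokens),
            c(obj$verb[[1]], obj$verb[[2]]), obj$verb_class, args,
            inventory = inventory)
}

#' Write a corpus to disk
#'
#' JSONL: one header line (format marker plus metadata) followed by one
#' utterance object per line, with stable key order so that identical
#' corpora serialize to identical bytes. TSV: CoNLL-style, one token per
#' row; utterance-level fields repeated on each row.
#'
#' @param corp an `rp_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corp, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(corp, "rp_corpus"))
  if (format == "jsonl") {
    header <- as.character(jsonlite::toJSON(
      list(rolepred_corpus = jsonlite::unbox(1L), metadata = corp$metadata),
      auto_unbox = FALSE, digits = NA))
    lines <- c(header, vapply(corp$utterances, utt_to_json, ""))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  } else {
    rows <- lapply(corp$utterances, function(u) {
      n <- length(u$tokens)
      elem <- rep("-", n); nom <- rep("-", n)
      elem[(u$verb_span[1] + 1):u$verb_span[2]] <- "V"
      for (a in u$arguments) {
        elem[(a$start + 1):a$end] <- a$role
        nom[(a$start + 1):a$end] <- a$nominality
      }
      data.frame(id = u$id, language = u$language, verb_class = u$verb_class,
                 index = seq_len(n) - 1L, surface = u$tokens,
                 element = elem, nominality = nom,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
      tab <- data.frame(id = character(), language = character(),
                        verb_class = character(), index = integer(),
                        surface = character(), element = character(),
                        nominality = character())
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(tab), collapse = "\t"), con, useBytes = TRUE)
    if (nrow(tab))
      writeLines(do.call(paste, c(unname(as.list(tab)), sep = "\t")), con,
                 useBytes = TRUE)
  }
  invisible(path)
}

#' Read a corpus from disk
#'
#' Reads the JSONL or TSV schema written by [write_corpus()]. Malformed
#' records raise an error naming the utterance id and field; nothing is
#' silently dropped.
#'
#' @param path input file path.
#' @param format `"jsonl"` or `"tsv"`.
#' @param inventory verb-class inventory used for validation.
#' @return an `rp_corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "tsv"),
                        inventory = verb_class_inventory()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop("empty file (missing header): ", path, call. = FALSE)
    header <- jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE)
    if (is.null(header$rolepred_corpus))
      stop("not a rolepred corpus file: ", path, call. = FALSE)
    utts <- lapply(lines[-1], utt_from_json, inventory = inventory)
    meta <- header$metadata
    corpus(utts, if (is.null(meta)) list() else as.list(meta))
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                      colClasses = "character", encoding = "UTF-8")
    if (!nrow(tab)) return(corpus(list()))
    utts <- lapply(split(tab, factor(tab$id, levels = unique(tab$id))),
                   function(b) {
      b <- b[order(as.integer(b$index)), ]
      runs <- rle(b$element)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths
      vs <- which(runs$values == "V")
      if (length(vs) != 1L)
        stop(sprintf("utterance '%s': invalid verb span: need exactly one V block",
                     b$id[1]), call. = FALSE)
      args <- list()
      for (k in which(runs$values %in% ROLE_LEVELS)) {
        args[[length(args) + 1L]] <-
          arg_span(starts[k], ends[k], runs$values[k], b$nominality[starts[k] + 1])
      }
      utterance(b$id[1], b$language[1], b$surface, c(starts[vs], ends[vs]),
                b$verb_class[1], args, inventory = inventory)
    })
    corpus(unname(utts))
  }
}

#' Word-order pattern of an utterance
#'
#' One letter per overtly realized element (`A`, `P`, verb `V`), ordered by
#' span start; omitted arguments contribute no letter. A multi-word verb
#' contributes a single `V` positioned at its span start.
#'
#' @param utt an `rp_utterance`.
#' @return pattern string, e.g. `"AVP"` or `"PV"`.
#' @export
word_order_pattern <- function(utt) {
  starts <- c(utt$verb_span[1], vapply(utt$arguments, `[[`, 0L, "start"))
  letters <- c("V", vapply(utt$arguments, `[[`, "", "role"))
  paste(letters[order(starts)], collapse = "")
}

#' Shannon entropy of word-order patterns
#'
#' \eqn{-\sum_k p_k \log_2 p_k} over the empirical distribution of
#' [word_order_pattern()] values in the corpus.
#'
#' @param corp a non-empty `rp_corpus`.
#' @return entropy in bits (non-negative).
#' @export
word_order_entropy <- function(corp) {
  if (!length(corp$utterances)) stop("empty corpus", call. = FALSE)
  pat <- vapply(corp$utterances, word_order_pattern, "")
  p <- table(pat) / length(pat)
  -sum(p * log2(p))
}

#' Descriptive corpus statistics
#'
#' Word-order pattern counts and entropy, role proportions over overt
#' argument spans, and the fraction of each role's arguments realized as
#' first- or second-person singular pronouns.
#'
#' @param corp a non-empty `rp_corpus`.
#' @return a list of class `rp_corpus_stats` with elements
#'   `pattern_counts`, `entropy_bits`, `role_proportions`,
#'   `pronoun12_rate_by_role`, `n_utterances`, `n_arguments`.
#' @export
corpus_statistics <- function(corp) {
  if (!length(corp$utterances)) stop("empty corpus", call. = FALSE)
  pat <- vapply(corp$utterances, word_order_pattern, "")
  args <- do.call(rbind, lapply(corp$utterances, function(u) {
    if (!length(u$arguments)) return(NULL)
    data.frame(role = vapply(u$arguments, `[[`, "", "role"),
               nominality = vapply(u$arguments, `[[`, "", "nominality"),
               stringsAsFactors = FALSE)
  }))
  role_prop <- c(A = NA_real_, P = NA_real_)
  pron12 <- c(A = NA_real_, P = NA_real_)
  if (!is.null(args)) {
    tab <- table(factor(args$role, ROLE_LEVELS))
    role_prop <- as.numeric(tab) / sum(tab)
    names(role_prop) <- ROLE_LEVELS
    for (r in ROLE_LEVELS) {
      sel <- args$role == r
      if (any(sel))
        pron12[r] <- mean(args$nominality[sel] %in% c("PRON_1SG", "PRON_2SG"))
    }
  }
  structure(list(pattern_counts = c(table(pat)),
                 entropy_bits = word_order_entropy(corp),
                 role_proportions = role_prop,
                 pronoun12_rate_by_role = pron12,
                 n_utterances = length(corp$utterances),
                 n_arguments = if (is.null(args)) 0L else nrow(args)),
            class = "rp_corpus_stats")
}

#' @export
print.rp_corpus_stats <- function(x, ...) {
  cat(sprintf("<rp_corpus_stats> n=%d, entropy=%.3f bits\n", x$n_utterances,
              x$entropy_bits))
  cat("  patterns:", paste(sprintf("%s:%d", names(x$pattern_counts),
                                   x$pattern_counts), collapse = " "), "\n")
  cat(sprintf("  role proportions: A=%.3f P=%.3f\n",
              x$role_proportions["A"], x$role_proportions["P"]))
  cat(sprintf("  1st/2nd pronoun rate: A=%.3f P=%.3f\n",
              x$pronoun12_rate_by_role["A"], x$pronoun12_rate_by_role["P"]))
  invisible(x)
}
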