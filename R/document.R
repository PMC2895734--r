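#' Tokenize clinical text into character-offset spans
#'
#' Whitespace-delimited chunks are further split on punctuation, with three
#' exceptions tuned to noisy Swedish clinical text: hyphenated words
#' (`34-årig`) stay whole, multi-part numbers/dates/phone numbers
#' (`2010-05-03`, `3/5`, `08-51770000`) stay whole, and known abbreviations
#' keep their trailing period (`Univ.`, `Avd.`).  The abbreviation list is
#' shipped as plain-text data (`extdata/tokenizer/abbreviations.txt`) so it
#' can be extended without touching code.
#'
#' Offsets are 0-based, half-open, character-level.  Token substrings are
#' non-empty and whitespace-free, spans are strictly increasing and
#' non-overlapping, and the concatenation of token substrings and the
#' intervening whitespace reconstructs the input exactly.
#'
#' @param text a length-1 character string.
#' @param abbreviations character vector of abbreviation surface forms
#'   (case-insensitive, trailing period included).  Defaults to the shipped
#'   list.
#' @return An integer matrix with columns `start`, `end`, one row per token.
#' @examples
#' tok <- tokenize("Karolinska Univ. Sjukh, Huddinge")
#' substring("Karolinska Univ. Sjukh, Huddinge", tok[, 1] + 1, tok[, 2])
#' @export
tokenize <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (!nzchar(text)) return(empty)
  # leftmost-first alternation (PCRE): multi-part numbers, then words
  # (hyphen/period-joined alnum runs, optional trailing period), then any
  # other non-space character
  pat <- paste0(
    "\\d+(?:[./:\\-]\\d+)+",                    # 2010-05-03, 3/5, 08-517...
    "|[\\p{L}\\p{N}]+(?:[-.][\\p{L}\\p{N}]+)*\\.?", # words, 34-årig, t.ex.
    "|\\S"                                      # isolated punctuation
  )
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L                    # to 0-based
  len <- attr(m, "match.length")
  toks <- substring(text, start + 1L, start + len)
  ab <- tolower(abbreviations)
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(toks)) {
    tk <- toks[i]; s <- start[i]; e <- start[i] + len[i]
    if (endsWith(tk, ".") && nchar(tk) > 1L && !(tolower(tk) %in% ab)) {
      # split the sentence-final period off non-abbreviations
      out_s <- c(out_s, s, e - 1L); out_e <- c(out_e, e - 1L, e)
    } else {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
    }
  }
  cbind(start = out_s, end = out_e)
}

#' @describeIn tokenize The shipped abbreviation list.
#' @export
default_abbreviations <- function() {
  path <- system.file("extdata", "tokenizer", "abbreviations.txt",
                      package = "phigold")
  if (!nzchar(path)) return(character())
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Documents and corpora
#'
#' A `phi_document` is a unit of clinical text: an identifier, the raw text,
#' and its token spans (0-based, half-open character offsets).  A
#' `phi_corpus` is a named list of documents keyed by `doc_id`.
#'
#' @param doc_id length-1 character identifier.
#' @param text the document text.
#' @param tokens optional token span matrix; computed with [tokenize()] when
#'   omitted.
#' @return `phi_document()` returns a `phi_document`; `phi_corpus()` a
#'   `phi_corpus`.
#' @export
phi_document <- function(doc_id, text, tokens = tokenize(text)) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  tokens <- as.matrix(tokens)
  storage.mode(tokens) <- "integer"
  if (nrow(tokens)) {
    stopifnot(all(tokens[, 1] < tokens[, 2]),
              all(tokens[, 2] <= nchar(text)),
              all(tokens[, 1] >= 0L))
    if (nrow(tokens) > 1L)
      stopifnot(all(tokens[-1L, 1] >= tokens[-nrow(tokens), 2]))
  }
  structure(list(doc_id = doc_id, text = text, tokens = tokens),
            class = "phi_document")
}

#' @param docs a list of `phi_document` objects.
#' @rdname phi_document
#' @export
phi_corpus <- function(docs) {
  stopifnot(all(vapply(docs, inherits, logical(1), "phi_document")))
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  stopifnot(!anyDuplicated(ids))
  structure(setNames(docs, ids), class = "phi_corpus")
}

#' @export
print.phi_document <- function(x, ...) {
  cat("<phi_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

#' @export
print.phi_corpus <- function(x, ...) {
  nt <- sum(vapply(x, function(d) nrow(d$tokens), integer(1)))
  cat("<phi_corpus> ", length(x), " documents, ", nt, " tokens\n", sep = "")
  invisible(x)
}

# token surface strings of a document
doc_token_strings <- function(doc) {
  if (!nrow(doc$tokens)) return(character())
  substring(doc$text, doc$tokens[, 1] + 1L, doc$tokens[, 2])
}
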