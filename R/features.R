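#' Token feature extraction for the CRF
#'
#' Deterministic per-token feature strings: lowercased word identity, word
#' shape (uppercase -> `X`, lowercase -> `x`, digit -> `d`, other characters
#' kept; plus a run-compressed variant), character n-grams from the token
#' start and end up to `char_ngram_max` (default 6), simple orthographic
#' flags, and neighbouring-token identities within `context_window`.  No
#' document-global state is used: identical tokens in identical contexts
#' always yield identical feature maps.
#'
#' @param char_ngram_max maximum character n-gram length (>= 1).
#' @param use_word_identity,use_word_shape,use_prefix_suffix feature-family
#'   switches.
#' @param context_window neighbour tokens on each side (0 disables context
#'   features).
#' @return `feature_config()` returns a `feature_config` list.
#' @export
feature_config <- function(char_ngram_max = 6L, use_word_identity = TRUE,
                           use_word_shape = TRUE, use_prefix_suffix = TRUE,
                           context_window = 1L) {
  stopifnot(char_ngram_max >= 1L, context_window >= 0L)
  structure(list(char_ngram_max = as.integer(char_ngram_max),
                 use_word_identity = use_word_identity,
                 use_word_shape = use_word_shape,
                 use_prefix_suffix = use_prefix_suffix,
                 context_window = as.integer(context_window)),
            class = "feature_config")
}

word_shape <- function(x) {
  s <- gsub("\\p{Lu}", "X", x, perl = TRUE)
  s <- gsub("\\p{Ll}", "x", s, perl = TRUE)
  gsub("\\p{N}", "d", s, perl = TRUE)
}

#' @param tokens character vector of token surface strings (one document).
#' @param cfg a `feature_config`.
#' @describeIn feature_config Extract features; returns a list (one element
#'   per token) of character vectors of feature strings.
#' @export
extract_features <- function(tokens, cfg = feature_config()) {
  stopifnot(length(tokens) >= 1L)
  n <- length(tokens)
  lower <- tolower(tokens)
  # one vectorised row per feature family; NA marks "absent for this token"
  rows <- list()
  add <- function(v) rows[[length(rows) + 1L]] <<- v
  if (cfg$use_word_identity) add(paste0("w=", lower))
  if (cfg$use_word_shape) {
    sh <- word_shape(tokens)
    add(paste0("sh=", sh))
    add(paste0("shc=", gsub("(.)\\1+", "\\1", sh)))
  }
  nc <- nchar(lower)
  if (cfg$use_prefix_suffix) {
    for (k in seq_len(cfg$char_ngram_max)) {
      ok <- nc >= k
      add(ifelse(ok, paste0("p", k, "=", substring(lower, 1L, k)), NA))
      add(ifelse(ok, paste0("s", k, "=", substring(lower, nc - k + 1L, nc)),
                 NA))
    }
  }
  add(ifelse(grepl("\\p{N}", tokens, perl = TRUE), "hasdigit", NA))
  add(ifelse(grepl("[^\\p{L}\\p{N}]", tokens, perl = TRUE), "haspunct", NA))
  add(ifelse(grepl("^\\p{Lu}", tokens, perl = TRUE), "initcap", NA))
  if (cfg$context_window > 0L) {
    for (off in seq_len(cfg$context_window)) {
      prev <- seq_len(n) - off
      add(c(rep(paste0("[-", off, "]BOS"), min(off, n)),
            paste0("[-", off, "]w=", lower[prev[prev >= 1L]])))
      nxt <- seq_len(n) + off
      add(c(paste0("[+", off, "]w=", lower[nxt[nxt <= n]]),
            rep(paste0("[+", off, "]EOS"), min(off, n))))
    }
  }
  add(rep("bias", n))
  m <- do.call(rbind, rows)
  lapply(seq_len(n), function(i) {
    col <- m[, i]
    col[!is.na(col)]
  })
}
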