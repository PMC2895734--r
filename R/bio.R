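#' BIO (IOB2) encoding and decoding of span annotations
#'
#' `encode_bio()` turns a document plus a flat (non-overlapping) annotation
#' set into a per-token tag sequence: tokens intersecting an annotation get
#' `B-<label>` on the first token and `I-<label>` on the rest; everything
#' else is `O`.  Annotations that are not token-aligned are snapped outward
#' to enclosing token boundaries first (the refined annotation guideline
#' forbids sub-token annotation); the number of snapped spans is returned as
#' an attribute.  If snapping makes two differently-labelled annotations
#' collide, encoding fails — such conflicts must be resolved upstream.
#'
#' `decode_bio()` is the inverse: maximal `B-X (I-X)*` runs become
#' annotations with character offsets taken from the first and last token.
#' Ill-formed sequences are repaired IOB2-style: an `I-X` following `O`,
#' the sequence start, or a different label is treated as `B-X`, so output
#' from any CRF engine decodes cleanly.
#'
#' @param doc a [phi_document()].
#' @param set an [annotation_set()] restricted to (or containing) this
#'   document's annotations.
#' @return `encode_bio()`: data frame with columns `token`, `tag`, `start`,
#'   `end` (one row per token) and attribute `n_snapped`.
#' @examples
#' d <- phi_document("d1", "Anna Svensson kom in.")
#' s <- annotation_set(data.frame(doc_id = "d1", start = 5L, end = 13L,
#'                                label = "Last_Name"), source = "gold")
#' encode_bio(d, s)$tag
#' @export
encode_bio <- function(doc, set) {
  stopifnot(inherits(doc, "phi_document"))
  sub <- set[set$doc_id == doc$doc_id, , drop = FALSE]
  toks <- doc$tokens
  tags <- rep("O", nrow(toks))
  n_snapped <- 0L
  if (nrow(sub)) {
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping annotations cannot be BIO-encoded; resolve upstream")
    owner <- integer(nrow(toks))          # 0 = unclaimed
    for (i in seq_len(nrow(sub))) {
      hit <- which(toks[, 1] < sub$end[i] & toks[, 2] > sub$start[i])
      if (!length(hit)) next
      if (toks[hit[1L], 1L] != sub$start[i] ||
          toks[hit[length(hit)], 2L] != sub$end[i])
        n_snapped <- n_snapped + 1L
      if (any(owner[hit] != 0L))
        stop("annotations overlap after snapping to token boundaries in ",
             doc$doc_id, "; resolve upstream")
      owner[hit] <- i
      tags[hit] <- paste0("I-", sub$label[i])
      tags[hit[1L]] <- paste0("B-", sub$label[i])
    }
  }
  out <- data.frame(token = doc_token_strings(doc), tag = tags,
                    start = if (nrow(toks)) toks[, 1] else integer(),
                    end = if (nrow(toks)) toks[, 2] else integer(),
                    stringsAsFactors = FALSE)
  attr(out, "n_snapped") <- n_snapped
  out
}

#' @param tagged a data frame as returned by `encode_bio()` (columns `tag`,
#'   `start`, `end`).
#' @param doc_id document identifier for the decoded annotations.
#' @param source source identifier for the decoded annotations.
#' @describeIn encode_bio Decode a tag sequence back to an annotation set.
#' @export
decode_bio <- function(tagged, doc_id, source = "system") {
  tags <- tagged$tag
  bad <- !grepl("^(O|[BI]-.+)$", tags)
  if (any(bad)) stop("unknown tag string: ", tags[which(bad)[1L]])
  rows <- list()
  open_lab <- NULL; open_start <- NA_integer_; open_end <- NA_integer_
  close_run <- function() {
    if (!is.null(open_lab))
      rows[[length(rows) + 1L]] <<- data.frame(
        doc_id = doc_id, start = open_start, end = open_end,
        label = open_lab, source = source, stringsAsFactors = FALSE)
    open_lab <<- NULL
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") { close_run(); next }
    lab <- substring(t, 3L)
    begin <- startsWith(t, "B-") || is.null(open_lab) || lab != open_lab
    if (begin) {
      close_run()
      open_lab <- lab; open_start <- tagged$start[i]
    }
    open_end <- tagged$end[i]
  }
  close_run()
  annotation_set(do.call(rbind, c(rows, list(NULL))), validate = FALSE)
}

#' @param corpus a [phi_corpus()].
#' @describeIn encode_bio Encode every corpus document; returns a named list
#'   of encoded data frames.
#' @export
encode_bio_corpus <- function(corpus, set) {
  lapply(corpus, function(d) encode_bio(d, set))
}
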