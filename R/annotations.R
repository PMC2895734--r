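#' Annotation sets and annotation studies
#'
#' An `annotation_set` holds one source's (annotator's or system's) PHI span
#' annotations as a data frame with columns `doc_id`, `start`, `end`,
#' `label`, `source`.  Offsets are 0-based half-open character positions.
#' Within one set, annotations over the same document must not overlap
#' (flat, non-nested annotation) and exact duplicates are forbidden.
#'
#' An `annotation_study` bundles a corpus with one annotation set per
#' annotator (and optionally the generating gold set, when the study is
#' synthetic): the unit that consensus building and agreement statistics
#' operate on.
#'
#' @param df data frame with columns `doc_id`, `start`, `end`, `label`
#'   (`source` optional if given as argument).
#' @param source length-1 source identifier; overrides any `source` column.
#' @param validate check span sanity and the non-overlap invariant.
#' @return An `annotation_set`: a data frame sorted by (doc_id, start, end).
#' @examples
#' a <- annotation_set(data.frame(doc_id = "d1", start = 0L, end = 4L,
#'                                label = "First_Name"), source = "ann1")
#' nrow(a)
#' @export
annotation_set <- function(df, source = NULL, validate = TRUE) {
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(doc_id = character(), start = integer(),
                     end = integer(), label = character(),
                     source = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(source)) df$source <- rep(as.character(source), nrow(df))
  need <- c("doc_id", "start", "end", "label", "source")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  df$doc_id <- as.character(df$doc_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$label <- as.character(df$label)
  df$source <- as.character(df$source)
  df <- df[order(df$doc_id, df$start, df$end, df$label), , drop = FALSE]
  rownames(df) <- NULL
  if (validate && nrow(df)) {
    stopifnot(all(df$start < df$end), all(df$start >= 0L))
    if (anyDuplicated(df[c("doc_id", "start", "end", "label", "source")]))
      stop("duplicate annotation (same doc_id/start/end/label/source)")
    for (d in unique(df$doc_id)) {
      for (src in unique(df$source)) {
        sub <- df[df$doc_id == d & df$source == src, , drop = FALSE]
        if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
          stop("overlapping annotations in document ", d, " from source ", src)
      }
    }
  }
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", nrow(x), " annotations, ",
      length(unique(x$doc_id)), " documents, source(s): ",
      paste(unique(x$source), collapse = ", "), "\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}

# rbind annotation sets, keeping the class
bind_annotation_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "data.frame")) sets <- sets[[1]]
  annotation_set(do.call(rbind, lapply(sets, as.data.frame)), validate = FALSE)
}

#' @param corpus a [phi_corpus()].
#' @param sets named list of `annotation_set`s, one per annotator.
#' @param gold optional gold `annotation_set` (synthetic studies).
#' @rdname annotation_set
#' @export
annotation_study <- function(corpus, sets, gold = NULL) {
  stopifnot(inherits(corpus, "phi_corpus"),
            is.list(sets), length(sets) >= 2L,
            all(vapply(sets, inherits, logical(1), "annotation_set")))
  srcs <- vapply(sets, function(s)
    if (nrow(s)) s$source[1] else NA_character_, character(1))
  if (is.null(names(sets))) names(sets) <- ifelse(is.na(srcs),
                                                  paste0("annotator", seq_along(sets)), srcs)
  ids <- names(corpus)
  for (s in sets)
    if (nrow(s) && !all(s$doc_id %in% ids))
      stop("annotation set refers to documents absent from the corpus")
  structure(list(corpus = corpus, sets = sets, gold = gold),
            class = "annotation_study")
}

#' @export
print.annotation_study <- function(x, ...) {
  cat("<annotation_study> ", length(x$corpus), " documents, ",
      length(x$sets), " annotators (",
      paste(vapply(x$sets, nrow, integer(1)), collapse = "/"),
      " annotations)\n", sep = "")
  invisible(x)
}

# snap a span outward to enclosing token boundaries; returns c(start, end)
# or NULL when the span touches no token (pure-whitespace span)
snap_span <- function(start, end, tokens) {
  if (!nrow(tokens)) return(NULL)
  hit <- which(tokens[, 1] < end & tokens[, 2] > start)
  if (!length(hit)) return(NULL)
  c(tokens[hit[1L], 1L], tokens[hit[length(hit)], 2L])
}

# snap every annotation in a set to token boundaries; merges same-label
# overlaps created by snapping, trims later different-label overlaps.
# Returns list(set, n_snapped).
snap_set_to_tokens <- function(set, corpus) {
  if (!nrow(set)) return(list(set = set, n_snapped = 0L))
  df <- as.data.frame(set)
  n_snapped <- 0L
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    doc <- corpus[[df$doc_id[i]]]
    if (is.null(doc)) stop("unknown document: ", df$doc_id[i])
    sp <- snap_span(df$start[i], df$end[i], doc$tokens)
    if (is.null(sp)) { keep[i] <- FALSE; next }
    if (sp[1] != df$start[i] || sp[2] != df$end[i]) n_snapped <- n_snapped + 1L
    df$start[i] <- sp[1]; df$end[i] <- sp[2]
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$doc_id, df$start, df$end), , drop = FALSE]
  # resolve overlaps introduced by snapping
  out <- df[0, ]
  for (d in unique(df$doc_id)) {
    sub <- df[df$doc_id == d, , drop = FALSE]
    i <- 1L
    while (i <= nrow(sub)) {
      cur <- sub[i, ]
      j <- i + 1L
      while (j <= nrow(sub) && sub$start[j] < cur$end) {
        if (sub$label[j] == cur$label) {
          cur$end <- max(cur$end, sub$end[j])   # merge same-label
          sub <- sub[-j, , drop = FALSE]
        } else {
          sub$start[j] <- cur$end               # trim later different-label
          if (sub$start[j] >= sub$end[j]) sub <- sub[-j, , drop = FALSE]
          else j <- j + 1L
        }
      }
      out <- rbind(out, cur)
      i <- i + 1L
    }
  }
  list(set = annotation_set(out, validate = FALSE), n_snapped = n_snapped)
}
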