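#' Read and write BRAT-style standoff annotation
#'
#' Standoff files use one line per annotation:
#' `T<n>\t<LABEL> <start> <end>\t<surface>`, offsets 0-based half-open over
#' the paired `.txt` file.  On read, every annotation's surface field is
#' checked against the text slice it points at; mismatches and out-of-range
#' offsets are errors naming the offending line.  When one standoff file
#' carries several documents, sections are introduced by `#doc <doc_id>`
#' comment lines.
#'
#' @param ann_path path to the `.ann` standoff file.
#' @param text_path path to the paired `.txt` file.
#' @param doc_id document identifier; defaults to the text file's base name.
#' @param source source identifier for the resulting set.
#' @return `read_standoff()` returns `list(document, set)`.
#' @export
read_standoff <- function(ann_path, text_path, doc_id = NULL,
                          source = "annotator") {
  if (is.null(doc_id))
    doc_id <- sub("\\.txt$", "", basename(text_path))
  text <- paste(readLines(text_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  doc <- phi_document(doc_id, text)
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("malformed standoff line ", i, ": ", lines[i])
    head_parts <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(head_parts) != 3L)
      stop("malformed standoff line ", i, ": ", lines[i])
    start <- suppressWarnings(as.integer(head_parts[2]))
    end <- suppressWarnings(as.integer(head_parts[3]))
    if (is.na(start) || is.na(end) || start < 0L || end > nchar(text) ||
        start >= end)
      stop("offset out of range on standoff line ", i, ": ", lines[i])
    surface <- if (length(parts) >= 3L) parts[3] else NA_character_
    # surfaces are single-line in the file; newlines map to spaces
    slice <- gsub("\n", " ", substring(text, start + 1L, end), fixed = TRUE)
    if (!is.na(surface) && surface != slice)
      stop("surface mismatch on standoff line ", i, ": file says ",
           dQuote(surface), " but text is ", dQuote(slice))
    data.frame(doc_id = doc_id, start = start, end = end,
               label = head_parts[1], source = source,
               stringsAsFactors = FALSE)
  })
  set <- annotation_set(do.call(rbind, c(rows, list(NULL))), validate = FALSE)
  list(document = doc, set = set)
}

#' @param set an [annotation_set()].
#' @param path output `.ann` path.
#' @param corpus optional [phi_corpus()] used to fill the surface field;
#'   without it the surface column is omitted.
#' @describeIn read_standoff Write a set (one or many documents) to a
#'   standoff file, annotations ordered by (doc_id, start, end); multi-doc
#'   sets get `#doc` section headers.
#' @export
write_standoff <- function(set, path, corpus = NULL) {
  df <- as.data.frame(set)
  df <- df[order(df$doc_id, df$start, df$end), , drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  ids <- unique(df$doc_id)
  multi <- length(ids) > 1L
  k <- 0L
  for (d in ids) {
    if (multi) writeLines(paste0("#doc ", d), con)
    sub <- df[df$doc_id == d, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      k <- k + 1L
      surf <- if (!is.null(corpus) && !is.null(corpus[[d]]))
        gsub("\n", " ",
             substring(corpus[[d]]$text, sub$start[i] + 1L, sub$end[i]),
             fixed = TRUE) else NULL
      line <- paste0("T", k, "\t", sub$label[i], " ", sub$start[i], " ",
                     sub$end[i])
      if (!is.null(surf)) line <- paste0(line, "\t", surf)
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Write and read a corpus as `.txt`/`.ann` file pairs
#'
#' One `<doc_id>.txt` per document; for each annotation set one
#' `<doc_id>.<source>.ann` standoff file.
#'
#' @param corpus a [phi_corpus()].
#' @param dir output directory (created if needed).
#' @param sets named list of [annotation_set()]s to write alongside.
#' @return `write_corpus_files()` returns `dir`; `read_corpus_files()` a
#'   list with `corpus` and `sets`.
#' @export
write_corpus_files <- function(corpus, dir, sets = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(corpus)) {
    writeLines(corpus[[d]]$text, file.path(dir, paste0(d, ".txt")),
               useBytes = FALSE)
    for (nm in names(sets)) {
      sub <- sets[[nm]][sets[[nm]]$doc_id == d, , drop = FALSE]
      write_standoff(annotation_set(as.data.frame(sub), validate = FALSE),
                     file.path(dir, paste0(d, ".", nm, ".ann")), corpus)
    }
  }
  invisible(dir)
}

#' @rdname write_corpus_files
#' @export
read_corpus_files <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- list(); sets <- list()
  for (tp in txts) {
    did <- sub("\\.txt$", "", basename(tp))
    anns <- list.files(dir, pattern = paste0("^", did, "\\..*\\.ann$"),
                       full.names = TRUE)
    doc <- NULL
    for (ap in anns) {
      src <- sub("\\.ann$", "", sub(paste0("^", did, "\\."), "", basename(ap)))
      r <- read_standoff(ap, tp, doc_id = did, source = src)
      doc <- r$document
      sets[[src]] <- if (is.null(sets[[src]])) r$set else
        bind_annotation_sets(sets[[src]], r$set)
    }
    if (is.null(doc)) {
      text <- paste(readLines(tp, encoding = "UTF-8", warn = FALSE),
                    collapse = "\n")
      doc <- phi_document(did, text)
    }
    docs[[did]] <- doc
  }
  list(corpus = phi_corpus(docs), sets = sets)
}

#' Read and write CoNLL-style token/tag files
#'
#' Two tab-separated columns (token, BIO tag), one token per line, a blank
#' line between documents, and a `# doc_id = <id>` comment opening each
#' document — the interchange format for CRF engines.
#'
#' @param corpus a [phi_corpus()].
#' @param set an [annotation_set()] supplying the tags (via [encode_bio()]).
#' @param path output path.
#' @return `write_conll()` returns `path` invisibly; `read_conll()` a list of
#'   per-document data frames with columns `token`, `tag`.
#' @export
write_conll <- function(corpus, set, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  first <- TRUE
  for (d in names(corpus)) {
    if (!first) writeLines("", con)
    first <- FALSE
    writeLines(paste0("# doc_id = ", d), con)
    sub <- annotation_set(
      as.data.frame(set[set$doc_id == d, , drop = FALSE]), validate = FALSE)
    tt <- encode_bio(corpus[[d]], sub)
    if (nrow(tt)) writeLines(paste0(tt$token, "\t", tt$tag), con)
  }
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list(); cur_id <- NULL; tok <- character(); tag <- character()
  flush_doc <- function() {
    if (!is.null(cur_id))
      out[[cur_id]] <<- data.frame(token = tok, tag = tag,
                                   stringsAsFactors = FALSE)
    tok <<- character(); tag <<- character()
  }
  for (ln in lines) {
    if (startsWith(ln, "# doc_id = ")) {
      flush_doc()
      cur_id <- sub("^# doc_id = ", "", ln)
    } else if (!nzchar(trimws(ln))) {
      # document separator; doc flushed when the next header arrives
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed CoNLL line: ", ln)
      tok <- c(tok, parts[1]); tag <- c(tag, parts[2])
    }
  }
  flush_doc()
  out
}
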