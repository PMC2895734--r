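#' Exact and partial span-match evaluation
#'
#' Two matching modes are used throughout de-identification evaluation:
#'
#' * **exact** — a prediction is correct iff some gold annotation has the
#'   identical token-aligned span *and* the same label;
#' * **partial** — a prediction is correct iff it overlaps a same-label gold
#'   annotation at the character level (minimum overlap fraction
#'   configurable; default any overlap).
#'
#' Matching is one-to-one: each gold annotation credits at most one
#' prediction and vice versa.  Because both sets are internally
#' non-overlapping, the left-to-right sweep used here attains the maximum
#' one-to-one matching in both modes.  Counts follow the
#' annotated/retrieved/relevant convention: `annotated` is the gold count,
#' `retrieved` the system count, `relevant` the correctly retrieved count.
#'
#' @param gold gold [annotation_set()] (internally non-overlapping).
#' @param pred system/response [annotation_set()].
#' @param mode `"exact"` or `"partial"`.
#' @param corpus optional [phi_corpus()]; when supplied, spans are snapped
#'   outward to token boundaries before exact matching (token-level exact
#'   match).
#' @param min_overlap minimum character-overlap fraction (of the shorter
#'   span) for a partial match; 0 means any overlap counts.
#' @return `count_matches()` returns a `match_counts` object: a list with
#'   `per_class` (data frame `label`/`annotated`/`retrieved`/`relevant`),
#'   `overall` (named vector), and `mode`.
#' @examples
#' g <- annotation_set(data.frame(doc_id = "d", start = 0L, end = 9L,
#'                                label = "Location"), source = "gold")
#' p <- annotation_set(data.frame(doc_id = "d", start = 0L, end = 5L,
#'                                label = "Location"), source = "sys")
#' count_matches(g, p, "exact")$overall
#' count_matches(g, p, "partial")$overall
#' @export
count_matches <- function(gold, pred, mode = c("exact", "partial"),
                          corpus = NULL, min_overlap = 0) {
  mode <- match.arg(mode)
  m <- match_annotations(gold, pred, mode, corpus, min_overlap)
  g <- m$gold; p <- m$pred
  labs <- sort(unique(c(g$label, p$label)))
  per <- data.frame(label = labs,
                    annotated = vapply(labs, function(l) sum(g$label == l), integer(1)),
                    retrieved = vapply(labs, function(l) sum(p$label == l), integer(1)),
                    relevant = vapply(labs, function(l)
                      sum(p$matched & p$label == l), integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  overall <- c(annotated = nrow(g), retrieved = nrow(p),
               relevant = sum(p$matched))
  structure(list(per_class = per, overall = overall, mode = mode),
            class = "match_counts")
}

# shared matching core; returns gold and pred data frames with a `matched`
# flag (and, for pred, the index of the matched gold row)
match_annotations <- function(gold, pred, mode, corpus = NULL,
                              min_overlap = 0) {
  g <- as.data.frame(gold); p <- as.data.frame(pred)
  check_no_overlap(g, "gold"); check_no_overlap(p, "pred")
  if (!is.null(corpus)) {
    g <- as.data.frame(snap_set_to_tokens(annotation_set(g, validate = FALSE),
                                          corpus)$set)
    p <- as.data.frame(snap_set_to_tokens(annotation_set(p, validate = FALSE),
                                          corpus)$set)
  }
  g$matched <- rep(FALSE, nrow(g)); p$matched <- rep(FALSE, nrow(p))
  p$gold_idx <- rep(NA_integer_, nrow(p))
  for (d in unique(c(g$doc_id, p$doc_id))) {
    for (l in unique(c(g$label[g$doc_id == d], p$label[p$doc_id == d]))) {
      gi <- which(g$doc_id == d & g$label == l)
      pi <- which(p$doc_id == d & p$label == l)
      gi <- gi[order(g$start[gi], g$end[gi])]
      pi <- pi[order(p$start[pi], p$end[pi])]
      if (mode == "exact") {
        key_g <- paste(g$start[gi], g$end[gi])
        key_p <- paste(p$start[pi], p$end[pi])
        hit <- match(key_p, key_g)
        ok <- !is.na(hit)
        p$matched[pi[ok]] <- TRUE
        p$gold_idx[pi[ok]] <- gi[hit[ok]]
        g$matched[gi[hit[ok]]] <- TRUE
      } else {
        i <- 1L; j <- 1L
        while (i <= length(gi) && j <= length(pi)) {
          a <- gi[i]; b <- pi[j]
          ov <- min(g$end[a], p$end[b]) - max(g$start[a], p$start[b])
          shorter <- min(g$end[a] - g$start[a], p$end[b] - p$start[b])
          if (ov > 0 && (min_overlap <= 0 || ov / shorter >= min_overlap)) {
            g$matched[a] <- TRUE; p$matched[b] <- TRUE; p$gold_idx[b] <- a
            i <- i + 1L; j <- j + 1L
          } else if (g$end[a] <= p$end[b]) i <- i + 1L else j <- j + 1L
        }
      }
    }
  }
  list(gold = g, pred = p)
}

check_no_overlap <- function(df, what) {
  if (nrow(df) < 2L) return(invisible())
  df <- df[order(df$doc_id, df$start), , drop = FALSE]
  same <- df$doc_id[-1L] == df$doc_id[-nrow(df)]
  if (any(same & df$start[-1L] < df$end[-nrow(df)]))
    stop(what, " set contains overlapping annotations")
  invisible()
}

#' @export
print.match_counts <- function(x, ...) {
  cat("<match_counts> mode=", x$mode, " annotated=", x$overall["annotated"],
      " retrieved=", x$overall["retrieved"],
      " relevant=", x$overall["relevant"], "\n", sep = "")
  invisible(x)
}

#' Precision, recall and F-score from match counts
#'
#' `P = relevant / retrieved`, `R = relevant / annotated`,
#' `F = 2PR / (P + R)`.  Zero denominators are reported as 0 and flagged in
#' the `undefined` column rather than propagating NaN.
#'
#' @param counts a `match_counts` object from [count_matches()], or a named
#'   vector with `annotated`, `retrieved`, `relevant`.
#' @return A data frame with one row per class plus `micro` (pooled counts)
#'   and `macro` (mean of per-class scores) rows; columns `label`,
#'   `annotated`, `retrieved`, `relevant`, `precision`, `recall`, `f`,
#'   `undefined`.
#' @export
compute_prf <- function(counts) {
  if (inherits(counts, "match_counts")) {
    per <- counts$per_class
    overall <- counts$overall
  } else {
    overall <- counts[c("annotated", "retrieved", "relevant")]
    per <- data.frame(label = character(), annotated = integer(),
                      retrieved = integer(), relevant = integer())
  }
  prf1 <- function(ann, ret, rel) {
    und <- ret == 0 || ann == 0
    p <- if (ret > 0) rel / ret else 0
    r <- if (ann > 0) rel / ann else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f = f, undefined = as.numeric(und))
  }
  if (nrow(per)) {
    rows <- lapply(seq_len(nrow(per)), function(i)
      prf1(per$annotated[i], per$retrieved[i], per$relevant[i]))
    out <- cbind(per, as.data.frame(do.call(rbind, rows)))
  } else {
    out <- cbind(per, data.frame(precision = numeric(0), recall = numeric(0),
                                 f = numeric(0), undefined = numeric(0)))
  }
  micro <- prf1(overall[["annotated"]], overall[["retrieved"]],
                overall[["relevant"]])
  macro <- if (nrow(out))
    c(precision = mean(out$precision), recall = mean(out$recall),
      f = mean(out$f), undefined = as.numeric(any(out$undefined > 0)))
  else micro
  agg <- data.frame(label = c("micro", "macro"),
                    annotated = overall[["annotated"]],
                    retrieved = overall[["retrieved"]],
                    relevant = overall[["relevant"]])
  agg <- cbind(agg, rbind(micro, macro))
  rownames(agg) <- NULL
  rbind(out, agg)
}

#' Per-class evaluation report
#'
#' One row per class (plus micro and macro aggregates) for both exact and
#' partial matching, following the annotated/retrieved/relevant column
#' layout used in de-identification result tables.
#'
#' @inheritParams count_matches
#' @param scheme optional [get_scheme()] result applied to both sets first.
#' @return An `eval_report`: data frame with the [compute_prf()] columns
#'   plus `mode`.
#' @export
per_class_report <- function(gold, pred, corpus = NULL, scheme = NULL,
                             min_overlap = 0) {
  if (!is.null(scheme)) {
    gold <- apply_scheme(gold, scheme)
    pred <- apply_scheme(pred, scheme)
  }
  out <- do.call(rbind, lapply(c("exact", "partial"), function(m) {
    prf <- compute_prf(count_matches(gold, pred, m, corpus, min_overlap))
    prf$mode <- m
    prf
  }))
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f <- round(df$f, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @param report an `eval_report` from [per_class_report()].
#' @param path output path (`.tsv` or `.json`).
#' @describeIn per_class_report Write a report as TSV
#'   (Annotated/Retrieved/Relevant column layout) or, for a `.json` path,
#'   as a machine-readable JSON summary.
#' @export
write_eval_report <- function(report, path) {
  df <- as.data.frame(report)
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing JSON reports requires the jsonlite package")
    jsonlite::write_json(split(df[setdiff(names(df), "mode")], df$mode),
                         path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' False-positive audit listing
#'
#' Every prediction left unmatched in exact mode, with its surface string
#' and surrounding context, in deterministic (doc_id, start) order.  The
#' audit exists so a human can re-adjudicate system-found instances: in
#' practice a fraction of a de-identifier's "false positives" are true PHI
#' the annotators missed.
#'
#' @inheritParams count_matches
#' @param corpus the [phi_corpus()] supplying text for surface/context.
#' @param context_chars characters of context on each side.
#' @return Data frame with columns `doc_id`, `start`, `end`, `label`,
#'   `surface`, `context`; `nrow` equals `retrieved - relevant` in exact
#'   mode.
#' @export
fp_audit <- function(gold, pred, corpus, context_chars = 40L) {
  m <- match_annotations(gold, pred, "exact", corpus = corpus)
  p <- m$pred[!m$pred$matched, , drop = FALSE]
  p <- p[order(p$doc_id, p$start), , drop = FALSE]
  if (!nrow(p))
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), label = character(),
                      surface = character(), context = character(),
                      stringsAsFactors = FALSE))
  surface <- character(nrow(p)); context <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    txt <- corpus[[p$doc_id[i]]]$text
    surface[i] <- substring(txt, p$start[i] + 1L, p$end[i])
    a <- max(0L, p$start[i] - context_chars)
    b <- min(nchar(txt), p$end[i] + context_chars)
    context[i] <- gsub("\n", " ", substring(txt, a + 1L, b), fixed = TRUE)
  }
  data.frame(doc_id = p$doc_id, start = p$start, end = p$end,
             label = p$label, surface = surface, context = context,
             stringsAsFactors = FALSE)
}
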