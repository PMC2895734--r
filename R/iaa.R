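#' Inter-annotator agreement F-scores
#'
#' Agreement between two annotators is measured as an F-score: one set is
#' treated as the reference and the other as the response, with matching in
#' exact (token-level span + label) or partial (character overlap + label)
#' mode.  Since `P(a,b) = R(b,a)`, the F-score is symmetric in the two
#' annotators.  The headline average is the micro-average over all
#' instances; per-class (macro) scores are also available via
#' [per_class_report()].
#'
#' @param a,b two [annotation_set()]s over the same documents.
#' @param mode `"exact"` or `"partial"`.
#' @param corpus optional [phi_corpus()] for token-level exact matching.
#' @return `pairwise_iaa()` returns a named vector `precision`, `recall`,
#'   `f`.  When both sets are empty, all three are `NaN` with a warning.
#' @examples
#' a <- annotation_set(data.frame(doc_id = "d", start = c(0L, 10L),
#'                                end = c(4L, 14L), label = c("X", "Y")), "a")
#' b <- annotation_set(data.frame(doc_id = "d", start = 0L, end = 4L,
#'                                label = "X"), "b")
#' pairwise_iaa(a, b)   # P = 1, R = 0.5, F = 2/3
#' @export
pairwise_iaa <- function(a, b, mode = c("exact", "partial"), corpus = NULL) {
  mode <- match.arg(mode)
  if (!nrow(a) && !nrow(b)) {
    warning("both annotation sets are empty; agreement is undefined")
    return(c(precision = NaN, recall = NaN, f = NaN))
  }
  cm <- count_matches(a, b, mode, corpus)
  ov <- cm$overall
  p <- if (ov[["retrieved"]] > 0) ov[["relevant"]] / ov[["retrieved"]] else 0
  r <- if (ov[["annotated"]] > 0) ov[["relevant"]] / ov[["annotated"]] else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

#' @param study an [annotation_study()].
#' @describeIn pairwise_iaa Symmetric matrix of pairwise F-scores over all
#'   annotators (diagonal 1), with per-annotator totals as attribute
#'   `totals` and the mean off-diagonal agreement as attribute `mean_f`.
#' @export
pairwise_matrix <- function(study, mode = c("exact", "partial")) {
  mode <- match.arg(mode)
  sets <- study$sets
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    f <- pairwise_iaa(sets[[i]], sets[[j]], mode, study$corpus)[["f"]]
    m[i, j] <- f; m[j, i] <- f
  }
  attr(m, "totals") <- vapply(sets, nrow, integer(1))
  attr(m, "mean_f") <- if (n > 1L) mean(m[upper.tri(m)]) else NaN
  m
}

#' Agreement table over annotated instance clusters
#'
#' Instances are clustered across annotators by span overlap (the same
#' clustering the automatic consensus uses); each row reports, per PHI
#' class, how many annotators assigned that class to the instance, plus the
#' instance span and the number of judging annotators.
#'
#' @param study an [annotation_study()].
#' @param min_overlap passed to [cluster_annotations()].
#' @return An `agreement_table`: data frame with `doc_id`, `start`, `end`
#'   (the cluster hull), `n_annotators`, one count column per observed
#'   class, and attribute `totals` (per-annotator annotation counts).
#' @export
agreement_table <- function(study, min_overlap = 0) {
  clusters <- cluster_annotations(study, min_overlap)
  labs <- sort(unique(unlist(lapply(clusters, function(cl) cl$label))))
  rows <- lapply(clusters, function(cl) {
    votes <- vapply(unique(cl$source), function(src) {
      sub <- cl[cl$source == src, , drop = FALSE]
      sub$label[order(-(sub$end - sub$start), sub$start)[1L]]
    }, character(1))
    counts <- vapply(labs, function(l) sum(votes == l), integer(1))
    cbind(data.frame(doc_id = cl$doc_id[1L], start = min(cl$start),
                     end = max(cl$end),
                     n_annotators = length(unique(cl$source)),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE))
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out))
    out <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), n_annotators = integer())
  attr(out, "totals") <- vapply(study$sets, nrow, integer(1))
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' @param x an `agreement_table` or matrix.
#' @param path output CSV path.
#' @describeIn agreement_table CSV export for agreement tables and pairwise
#'   matrices.
#' @export
write_agreement_csv <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(annotator = rownames(x), as.data.frame(x),
                     total = attr(x, "totals"))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
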