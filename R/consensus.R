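#' Automatic consensus gold standard
#'
#' The automatic consensus takes the union of all annotators' annotations —
#' high recall being preferable to high precision for de-identification —
#' and resolves disagreements per *overlap cluster*: annotations from any
#' annotator whose character spans intersect, chained transitively, form
#' one instance.  Each cluster contributes exactly one consensus
#' annotation:
#'
#' * **span** — the longest member span (ties: smallest start);
#' * **label** — strict majority of annotator votes when one exists;
#'   otherwise, if the candidate labels form a chain in the label
#'   specificity order (e.g. `First_Name` vs `Clinician_First_Name`), the
#'   most specific; otherwise a fixed deterministic tie-break order;
#' * instances annotated by only one annotator (singletons) are included by
#'   default.
#'
#' @param study an [annotation_study()].
#' @param policy a `resolution_policy()`.
#' @return `build_automatic_consensus()` returns an [annotation_set()] with
#'   source `"consensus"` and attribute `audit`, a per-cluster data frame
#'   recording members, votes and the decision path.
#' @examples
#' # three annotators agreeing exactly reproduce themselves
#' d <- phi_document("d", "Anna kom in")
#' sets <- lapply(1:3, function(i)
#'   annotation_set(data.frame(doc_id = "d", start = 0L, end = 4L,
#'                             label = "First_Name"), paste0("a", i)))
#' s <- annotation_study(phi_corpus(list(d)), sets)
#' build_automatic_consensus(s)
#' @export
build_automatic_consensus <- function(study, policy = resolution_policy()) {
  clusters <- cluster_annotations(study, policy$min_overlap)
  rows <- list(); audit <- list()
  for (cl in clusters) {
    n_src <- length(unique(cl$source))
    if (!policy$include_singletons && n_src < 2L) next
    sp <- resolve_span(cl)
    lab <- resolve_label(cl, policy)
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = cl$doc_id[1L], start = sp[1L], end = sp[2L],
      label = lab$label, source = "consensus", stringsAsFactors = FALSE)
    audit[[length(audit) + 1L]] <- data.frame(
      doc_id = cl$doc_id[1L], start = sp[1L], end = sp[2L],
      label = lab$label, n_members = nrow(cl), n_annotators = n_src,
      members = paste(sprintf("%s:%d-%d:%s", cl$source, cl$start, cl$end,
                              cl$label), collapse = ";"),
      decision = lab$decision, stringsAsFactors = FALSE)
  }
  out <- annotation_set(do.call(rbind, c(rows, list(NULL))), validate = FALSE)
  attr(out, "audit") <- do.call(rbind, c(audit, list(NULL)))
  out
}

#' @param specificity named vector mapping specific -> generic labels;
#'   defaults to the shipped catalog's relation.
#' @param tie_break total order over labels used when neither majority nor
#'   specificity decides; defaults to the catalog label order.
#' @param include_singletons include clusters seen by a single annotator.
#' @param min_overlap minimum character-overlap fraction (of the shorter
#'   span) for two annotations to count as the same instance; 0 means any
#'   overlap.
#' @describeIn build_automatic_consensus Resolution policy object.
#' @export
resolution_policy <- function(specificity = default_catalog()$specificity,
                              tie_break = default_catalog()$labels,
                              include_singletons = TRUE,
                              min_overlap = 0) {
  structure(list(specificity = specificity, tie_break = tie_break,
                 include_singletons = include_singletons,
                 min_overlap = min_overlap),
            class = "resolution_policy")
}

#' Cluster annotations across annotators by span overlap
#'
#' Maximal connected components under "character spans intersect" (chained
#' transitively), computed per document over the union of all annotators'
#' sets.  Every input annotation lands in exactly one cluster.
#'
#' @param study an [annotation_study()] (or a list of annotation sets).
#' @param min_overlap minimum overlap fraction for two spans to connect.
#' @return List of data frames, one per cluster, rows = member annotations.
#' @export
cluster_annotations <- function(study, min_overlap = 0) {
  sets <- if (inherits(study, "annotation_study")) study$sets else study
  df <- as.data.frame(bind_annotation_sets(sets))
  if (!nrow(df)) return(list())
  df <- df[order(df$doc_id, df$start, df$end), , drop = FALSE]
  out <- list()
  for (d in unique(df$doc_id)) {
    sub <- df[df$doc_id == d, , drop = FALSE]
    cid <- integer(nrow(sub))
    cur <- 0L; reach <- -Inf
    for (i in seq_len(nrow(sub))) {
      connects <- sub$start[i] < reach
      if (connects && min_overlap > 0) {
        # against the running component we use plain intersection for the
        # chain, but a fractional threshold applies pairwise: keep the
        # chain if any earlier member of the component clears it
        js <- which(cid == cur)
        connects <- any(vapply(js, function(j) {
          ov <- min(sub$end[j], sub$end[i]) - max(sub$start[j], sub$start[i])
          shorter <- min(sub$end[j] - sub$start[j], sub$end[i] - sub$start[i])
          ov > 0 && ov / shorter >= min_overlap
        }, logical(1)))
      }
      if (!connects) { cur <- cur + 1L; reach <- -Inf }
      cid[i] <- cur
      reach <- max(reach, sub$end[i])
    }
    for (k in unique(cid))
      out[[length(out) + 1L]] <- sub[cid == k, , drop = FALSE]
  }
  out
}

#' @param cluster one cluster data frame from [cluster_annotations()].
#' @describeIn build_automatic_consensus Longest member span; equal lengths
#'   broken by smallest start.
#' @export
resolve_span <- function(cluster) {
  stopifnot(nrow(cluster) >= 1L)
  len <- cluster$end - cluster$start
  i <- order(-len, cluster$start)[1L]
  c(cluster$start[i], cluster$end[i])
}

#' @describeIn build_automatic_consensus Majority / specificity / tie-break
#'   label resolution; returns `list(label, decision)`.
#' @export
resolve_label <- function(cluster, policy = resolution_policy()) {
  stopifnot(nrow(cluster) >= 1L)
  # one vote per annotator: an annotator chained into a cluster with several
  # members votes with its longest member's label
  votes <- vapply(unique(cluster$source), function(src) {
    sub <- cluster[cluster$source == src, , drop = FALSE]
    sub$label[order(-(sub$end - sub$start), sub$start)[1L]]
  }, character(1))
  tab <- sort(table(votes), decreasing = TRUE)
  cand <- names(tab)
  if (length(cand) == 1L)
    return(list(label = cand, decision = "unanimous"))
  if (tab[1L] > tab[2L])
    return(list(label = cand[1L], decision = "majority"))
  # tied: restrict to the tied top labels
  cand <- cand[tab == tab[1L]]
  cat_ <- label_catalog(unique(c(cand, policy$tie_break,
                                 names(policy$specificity),
                                 unname(policy$specificity))),
                        policy$specificity)
  chain <- all(vapply(cand, function(a) all(vapply(cand, function(b)
    label_is_ancestor(a, b, cat_) || label_is_ancestor(b, a, cat_),
    logical(1))), logical(1)))
  if (chain) {
    depth <- vapply(cand, label_depth, integer(1), catalog = cat_)
    return(list(label = cand[which.max(depth)], decision = "specificity"))
  }
  ord <- match(cand, policy$tie_break)
  ord[is.na(ord)] <- length(policy$tie_break) + rank(cand[is.na(ord)])
  list(label = cand[which.min(ord)], decision = "tie_break")
}
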