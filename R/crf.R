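#' Fit a linear-chain CRF de-identifier
#'
#' `crf_deid()` trains a first-order linear-chain conditional random field
#' over BIO-encoded token tags: per-token feature functions (see
#' [feature_config()]) paired with every tag, plus tag-transition weights
#' including a virtual begin-of-sequence state.  The L2-penalised negative
#' log-likelihood is minimised with L-BFGS; the gradient comes from exact
#' forward-backward marginals, so training is deterministic given the data.
#'
#' @param corpus a [phi_corpus()] of training documents.
#' @param annotations gold [annotation_set()] over the corpus.
#' @param scheme optional class scheme (object or registered name) applied
#'   to the annotations before encoding.
#' @param features a [feature_config()].
#' @param c2 L2 penalty weight (`0.5 * c2 * ||w||^2`).
#' @param maxit maximum L-BFGS iterations.
#' @return An object of class `crf_deid` with components `weights`, `vocab`
#'   (feature strings), `tags` (BIO tag set), `features`, `c2`,
#'   `convergence`, `nll` and `scheme_name`; usable with [predict()],
#'   [coef()], `print()` and `summary()`.
#' @examples
#' \donttest{
#' st <- generate_gold_corpus(synth_config(n_documents = 8, seed = 3))
#' fit <- crf_deid(st$corpus, st$gold, scheme = "manual_gs", maxit = 40)
#' pred <- predict(fit, st$corpus)
#' }
#' @export
crf_deid <- function(corpus, annotations, scheme = NULL,
                     features = feature_config(), c2 = 1.0, maxit = 100L) {
  stopifnot(inherits(corpus, "phi_corpus"))
  if (!length(corpus)) stop("cannot train on an empty corpus")
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  if (!is.null(scheme)) annotations <- apply_scheme(annotations, scheme)
  if (!nrow(annotations)) stop("no training annotations")
  enc <- lapply(corpus, function(d) encode_bio(d, annotations))
  enc <- enc[vapply(enc, nrow, integer(1)) > 0L]
  if (!length(enc)) stop("no non-empty training documents")
  tags <- sort(unique(c("O", unlist(lapply(enc, `[[`, "tag")))))
  dat <- build_crf_data(enc, features, vocab = NULL)
  y <- match(unlist(lapply(enc, `[[`, "tag")), tags) - 1L
  L <- length(tags)
  n_par <- length(dat$vocab) * L + (L + 1L) * L
  cache <- new.env(parent = emptyenv())
  evaluate <- function(p) {
    if (is.null(cache$par) || !identical(p, cache$par)) {
      cache$res <- crf_nll_grad(p, length(dat$vocab), L, dat$feat_idx,
                                dat$tok_ptr, dat$seq_ptr, y, c2)
      cache$par <- p
    }
    cache$res
  }
  opt <- stats::optim(numeric(n_par),
                      fn = function(p) evaluate(p)$value,
                      gr = function(p) evaluate(p)$gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  structure(list(weights = opt$par, vocab = dat$vocab, tags = tags,
                 features = features, c2 = c2, nll = opt$value,
                 convergence = opt$convergence,
                 n_train_docs = length(enc),
                 n_train_tokens = length(y),
                 scheme_name = if (is.null(scheme)) NA_character_
                 else scheme$name),
            class = "crf_deid")
}

# flatten encoded documents into the index structure the C++ core expects;
# with a fixed vocab (prediction) unseen features are dropped
build_crf_data <- function(enc, features, vocab = NULL) {
  feats <- lapply(enc, function(e) extract_features(e$token, features))
  n_tok_per_doc <- vapply(feats, length, integer(1))
  flat <- unlist(feats, recursive = FALSE, use.names = FALSE)
  all_feats <- unlist(flat, use.names = FALSE)
  n_per_tok <- vapply(flat, length, integer(1))
  if (is.null(vocab)) {
    vocab <- sort(unique(all_feats))
    idx <- match(all_feats, vocab)
  } else {
    idx <- match(all_feats, vocab)
  }
  keep <- !is.na(idx)
  # recompute per-token counts after dropping unseen features
  tok_of_feat <- rep.int(seq_along(n_per_tok), n_per_tok)
  n_kept <- tabulate(tok_of_feat[keep], nbins = length(n_per_tok))
  list(vocab = vocab,
       feat_idx = as.integer(idx[keep] - 1L),
       tok_ptr = as.integer(c(0L, cumsum(n_kept))),
       seq_ptr = as.integer(c(0L, cumsum(n_tok_per_doc))))
}

#' @export
print.crf_deid <- function(x, ...) {
  cat("Linear-chain CRF de-identifier\n")
  cat("  tags:     ", length(x$tags), " (",
      paste(head(x$tags, 6), collapse = ", "),
      if (length(x$tags) > 6) ", ..." else "", ")\n", sep = "")
  cat("  features: ", length(x$vocab), " (n-grams up to ",
      x$features$char_ngram_max, ", context window ",
      x$features$context_window, ")\n", sep = "")
  cat("  trained:  ", x$n_train_docs, " documents / ", x$n_train_tokens,
      " tokens; penalised NLL ", format(x$nll, digits = 6), "\n", sep = "")
  if (!is.na(x$scheme_name)) cat("  scheme:   ", x$scheme_name, "\n", sep = "")
  invisible(x)
}

#' @export
summary.crf_deid <- function(object, n = 10L, ...) {
  print(object)
  L <- length(object$tags)
  emit <- matrix(object$weights[seq_len(length(object$vocab) * L)],
                 ncol = L, byrow = TRUE,
                 dimnames = list(object$vocab, object$tags))
  top <- sort(apply(abs(emit), 1L, max), decreasing = TRUE)
  cat("  strongest features:\n")
  for (f in names(head(top, n))) {
    l <- object$tags[which.max(abs(emit[f, ]))]
    cat(sprintf("    %-28s %-14s %+.3f\n", f, l, emit[f, l]))
  }
  invisible(object)
}

#' @export
coef.crf_deid <- function(object, ...) {
  L <- length(object$tags)
  nf <- length(object$vocab)
  list(emission = matrix(object$weights[seq_len(nf * L)], ncol = L,
                         byrow = TRUE,
                         dimnames = list(object$vocab, object$tags)),
       transition = matrix(object$weights[nf * L + seq_len((L + 1L) * L)],
                           ncol = L, byrow = TRUE,
                           dimnames = list(c(object$tags, "<BOS>"),
                                           object$tags)))
}

#' Predict PHI annotations with a fitted CRF
#'
#' Runs Viterbi decoding over each document and converts the BIO tag
#' sequence back to character-offset annotations with [decode_bio()]
#' (orphan `I-` tags are repaired), so the output is token-aligned and
#' non-overlapping by construction.
#'
#' @param object a fitted [crf_deid()] model.
#' @param corpus a [phi_corpus()] to annotate.
#' @param source source identifier for the returned set.
#' @param ... unused.
#' @return An [annotation_set()].
#' @export
predict.crf_deid <- function(object, corpus, source = "crf", ...) {
  stopifnot(inherits(corpus, "phi_corpus"))
  docs <- corpus[vapply(corpus, function(d) nrow(d$tokens), integer(1)) > 0L]
  if (!length(docs)) return(annotation_set(NULL))
  enc <- lapply(docs, function(d)
    data.frame(token = doc_token_strings(d),
               start = d$tokens[, 1], end = d$tokens[, 2],
               stringsAsFactors = FALSE))
  dat <- build_crf_data(enc, object$features, vocab = object$vocab)
  L <- length(object$tags)
  path <- crf_viterbi(object$weights, length(object$vocab), L,
                      dat$feat_idx, dat$tok_ptr, dat$seq_ptr)
  tags <- object$tags[path + 1L]
  sets <- vector("list", length(docs))
  at <- 0L
  for (i in seq_along(docs)) {
    e <- enc[[i]]
    e$tag <- tags[at + seq_len(nrow(e))]
    at <- at + nrow(e)
    sets[[i]] <- decode_bio(e, doc_id = names(docs)[i], source = source)
  }
  bind_annotation_sets(sets)
}

#' Document-level k-fold cross-validation
#'
#' Documents are partitioned into `k` folds of near-equal size (differing
#' by at most one, seeded shuffle); each fold is evaluated with a model
#' trained on the remaining folds, so no document contributes to both
#' training and testing.  Per-fold reports and the pooled aggregate over
#' all held-out predictions are returned.
#'
#' @inheritParams crf_deid
#' @param k number of folds (`2 <= k <=` number of documents).
#' @param seed seed fixing the fold shuffle.
#' @return A `crf_cv` list: `folds` (doc -> fold), `fold_reports`,
#'   `aggregate` (an [per_class_report()] over pooled predictions),
#'   `exact_f` and `partial_f` (overall micro F), and `predictions`.
#' @export
cross_validate <- function(corpus, annotations, k = 4L, scheme = NULL,
                           features = feature_config(), c2 = 1.0,
                           maxit = 100L, seed = 1L) {
  if (k < 2L || k > length(corpus))
    stop("k must be between 2 and the number of documents")
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  if (!is.null(scheme)) annotations <- apply_scheme(annotations, scheme)
  folds <- make_folds(names(corpus), k, seed)
  fold_reports <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- names(folds)[folds == f]
    train_ids <- setdiff(names(corpus), test_ids)
    fit <- crf_deid(phi_corpus(corpus[train_ids]),
                    annotation_set(as.data.frame(
                      annotations[annotations$doc_id %in% train_ids, ]),
                      validate = FALSE),
                    scheme = NULL, features = features, c2 = c2,
                    maxit = maxit)
    test_corpus <- phi_corpus(corpus[test_ids])
    p <- predict(fit, test_corpus)
    g <- annotation_set(as.data.frame(
      annotations[annotations$doc_id %in% test_ids, ]), validate = FALSE)
    fold_reports[[f]] <- per_class_report(g, p, corpus = test_corpus)
    preds[[f]] <- p
  }
  pooled <- bind_annotation_sets(preds)
  aggregate <- per_class_report(annotations, pooled, corpus = corpus)
  agg <- as.data.frame(aggregate)
  structure(list(folds = folds, fold_reports = fold_reports,
                 aggregate = aggregate,
                 exact_f = agg$f[agg$label == "micro" & agg$mode == "exact"],
                 partial_f = agg$f[agg$label == "micro" & agg$mode == "partial"],
                 predictions = pooled, k = k, seed = seed),
            class = "crf_cv")
}

#' @export
print.crf_cv <- function(x, ...) {
  cat("<crf_cv> ", x$k, "-fold cross-validation: exact F = ",
      round(x$exact_f, 3), ", partial F = ", round(x$partial_f, 3),
      "\n", sep = "")
  invisible(x)
}

#' @param doc_ids document identifiers to partition.
#' @describeIn cross_validate Seeded fold assignment; returns a named
#'   integer vector (doc_id -> fold), fold sizes differing by at most 1.
#' @export
make_folds <- function(doc_ids, k, seed = 1L) {
  set.seed(seed)
  shuffled <- sample(doc_ids)
  v <- setNames(rep_len(seq_len(k), length(doc_ids)), shuffled)
  v[doc_ids]
}
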