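# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately share no code with the package: clustering is
# done by explicit graph search, matching by augmenting-path maximum
# bipartite matching, and consensus resolution by a direct literal
# re-implementation of the rules.

# a document of n single-letter tokens: "a b c ..." -> token i spans
# [2i, 2i+1), i 0-based
grid_doc <- function(n = 12L, doc_id = "g") {
  phi_document(doc_id, paste(letters[seq_len(n)], collapse = " "))
}

# char span of token range [i, j] (0-based inclusive) in a grid doc
grid_span <- function(i, j = i) c(2L * i, 2L * j + 1L)

mk_set <- function(rows, source, doc_id = "g") {
  if (is.null(rows) || !nrow(rows)) return(annotation_set(NULL, source))
  rows$doc_id <- doc_id
  annotation_set(rows, source = source)
}

# random non-overlapping token-aligned annotation data frame over a grid doc
random_grid_rows <- function(n_ann, n_tok = 12L, labels = c("X", "Y"),
                             max_len = 3L) {
  if (n_ann == 0L) return(NULL)
  rows <- NULL
  occupied <- rep(FALSE, n_tok)
  for (k in seq_len(n_ann * 4L)) {
    if (!is.null(rows) && nrow(rows) >= n_ann) break
    len <- sample.int(max_len, 1L)
    i <- sample.int(n_tok - len + 1L, 1L) - 1L
    idx <- (i + 1L):(i + len)
    if (any(occupied[idx])) next
    occupied[idx] <- TRUE
    sp <- grid_span(i, i + len - 1L)
    rows <- rbind(rows, data.frame(start = sp[1], end = sp[2],
                                   label = sample(labels, 1L),
                                   stringsAsFactors = FALSE))
  }
  rows
}

# ---- oracle: maximum one-to-one matching ---------------------------------

# augmenting-path maximum bipartite matching on a logical compat matrix
max_matching_size <- function(compat) {
  ng <- nrow(compat); np <- ncol(compat)
  if (!ng || !np) return(0L)
  match_p <- rep(0L, np)
  try_assign <- function(g, seen) {
    for (p in which(compat[g, ])) {
      if (seen[p]) next
      seen[p] <- TRUE
      if (match_p[p] == 0L) { match_p[p] <<- g; return(list(TRUE, seen)) }
      res <- try_assign(match_p[p], seen)
      seen <- res[[2]]
      if (res[[1]]) { match_p[p] <<- g; return(list(TRUE, seen)) }
    }
    list(FALSE, seen)
  }
  n <- 0L
  for (g in seq_len(ng)) {
    if (try_assign(g, rep(FALSE, np))[[1]]) n <- n + 1L
  }
  n
}

oracle_relevant <- function(gold, pred, mode) {
  g <- as.data.frame(gold); p <- as.data.frame(pred)
  if (!nrow(g) || !nrow(p)) return(0L)
  compat <- matrix(FALSE, nrow(g), nrow(p))
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
    if (g$doc_id[i] != p$doc_id[j] || g$label[i] != p$label[j]) next
    compat[i, j] <- if (mode == "exact")
      g$start[i] == p$start[j] && g$end[i] == p$end[j]
    else
      min(g$end[i], p$end[j]) > max(g$start[i], p$start[j])
  }
  max_matching_size(compat)
}

# ---- oracle: automatic consensus -----------------------------------------

oracle_consensus <- function(sets, specificity, tie_break,
                             include_singletons = TRUE) {
  df <- do.call(rbind, lapply(sets, as.data.frame))
  if (is.null(df) || !nrow(df))
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), label = character()))
  out <- NULL
  for (d in unique(df$doc_id)) {
    sub <- df[df$doc_id == d, , drop = FALSE]
    n <- nrow(sub)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- min(sub$end[i], sub$end[j]) > max(sub$start[i], sub$start[j])
    comp <- rep(0L, n); c_id <- 0L
    for (i in seq_len(n)) {
      if (comp[i] != 0L) next
      c_id <- c_id + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] != 0L) next
        comp[v] <- c_id
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
    for (k in seq_len(c_id)) {
      cl <- sub[comp == k, , drop = FALSE]
      if (!include_singletons && length(unique(cl$source)) < 2L) next
      len <- cl$end - cl$start
      best <- which(len == max(len))
      best <- best[which.min(cl$start[best])]
      # one vote per annotator: longest member's label, ties smallest start
      votes <- character()
      for (src in unique(cl$source)) {
        m <- cl[cl$source == src, , drop = FALSE]
        ml <- m$end - m$start
        b <- which(ml == max(ml)); b <- b[which.min(m$start[b])]
        votes <- c(votes, m$label[b])
      }
      tab <- table(votes)
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) == 1L) lab <- winners
      else {
        anc <- function(a, b) {       # a ancestor-of-or-equal b
          cur <- b
          repeat {
            if (cur == a) return(TRUE)
            if (!cur %in% names(specificity)) return(FALSE)
            cur <- unname(specificity[[cur]])
          }
        }
        chain <- all(outer(winners, winners,
                           Vectorize(function(a, b) anc(a, b) || anc(b, a))))
        if (chain) {
          depth <- vapply(winners, function(l) {
            d0 <- 0L
            while (l %in% names(specificity)) {
              l <- unname(specificity[[l]]); d0 <- d0 + 1L
            }
            d0
          }, integer(1))
          lab <- winners[which.max(depth)]
        } else {
          ord <- match(winners, tie_break)
          ord[is.na(ord)] <- length(tie_break) + rank(winners[is.na(ord)])
          lab <- winners[which.min(ord)]
        }
      }
      out <- rbind(out, data.frame(doc_id = d, start = cl$start[best],
                                   end = cl$end[best], label = lab,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$doc_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

consensus_as_plain <- function(cons) {
  df <- as.data.frame(cons)[c("doc_id", "start", "end", "label")]
  df <- df[order(df$doc_id, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# small calibrated study reused across tests (cached per session)
tiny_study <- local({
  cache <- list()
  function(n_documents = 20L, seed = 5L) {
    key <- paste(n_documents, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- build_annotation_study(
        synth_config(n_documents = n_documents, seed = seed))
    cache[[key]]
  }
})
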