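# Exact/partial matching, P/R/F bookkeeping, false-positive audit

test_that("exact and partial modes implement the match definitions", {
  g <- mk_set(data.frame(start = 0L, end = 9L, label = "Location"), "g")
  p <- mk_set(data.frame(start = 0L, end = 5L, label = "Location"), "p")
  expect_identical(unname(count_matches(g, p, "exact")$overall["relevant"]), 0L)
  expect_identical(unname(count_matches(g, p, "partial")$overall["relevant"]), 1L)

  # label identity is required in both modes
  pw <- mk_set(data.frame(start = 0L, end = 9L, label = "Town"), "p")
  expect_identical(unname(count_matches(g, pw, "partial")$overall["relevant"]), 0L)

  # perfect prediction
  cm <- count_matches(g, g, "exact")
  expect_true(all(cm$overall == 1L))
})

test_that("overlapping inputs are rejected", {
  bad <- annotation_set(data.frame(doc_id = "g", start = c(0L, 3L),
                                   end = c(5L, 8L), label = "X",
                                   source = "s"), validate = FALSE)
  ok <- mk_set(data.frame(start = 0L, end = 2L, label = "X"), "p")
  expect_error(count_matches(bad, ok, "exact"), "overlapping")
})

test_that("precision/recall/F closed forms and zero conventions", {
  prf <- compute_prf(c(annotated = 2, retrieved = 2, relevant = 1))
  mi <- prf[prf$label == "micro", ]
  expect_equal(c(mi$precision, mi$recall, mi$f), c(0.5, 0.5, 0.5))

  prf2 <- compute_prf(c(annotated = 2, retrieved = 1, relevant = 1))
  mi2 <- prf2[prf2$label == "micro", ]
  expect_equal(c(mi2$precision, mi2$recall, mi2$f), c(1, 0.5, 2 / 3))

  prf3 <- compute_prf(c(annotated = 3, retrieved = 0, relevant = 0))
  mi3 <- prf3[prf3$label == "micro", ]
  expect_equal(c(mi3$precision, mi3$recall, mi3$f), c(0, 0, 0))
  expect_identical(mi3$undefined, 1)
})

test_that("matching equals the optimal bipartite oracle on random pairs", {
  set.seed(123)
  for (rep in 1:1000) {
    g <- mk_set(random_grid_rows(sample(0:6, 1), labels = c("X", "Y")), "g")
    p <- mk_set(random_grid_rows(sample(0:6, 1), labels = c("X", "Y")), "p")
    for (mode in c("exact", "partial")) {
      got <- unname(count_matches(g, p, mode)$overall["relevant"])
      expect_identical(got, oracle_relevant(g, p, mode))
      # bookkeeping: relevant <= min(annotated, retrieved)
      expect_lte(got, min(nrow(g), nrow(p)))
    }
    # symmetry of the relevant count
    expect_identical(
      unname(count_matches(g, p, "partial")$overall["relevant"]),
      unname(count_matches(p, g, "partial")$overall["relevant"]))
  }
})

test_that("per-class report micro equals pooled counts and macro averages", {
  st <- tiny_study(6L, seed = 12L)
  pred <- st$sets[[2]]
  rep_ <- per_class_report(st$gold, pred, corpus = st$corpus)
  df <- as.data.frame(rep_)
  for (m in c("exact", "partial")) {
    sub <- df[df$mode == m & !df$label %in% c("micro", "macro"), ]
    mi <- df[df$mode == m & df$label == "micro", ]
    expect_identical(sum(sub$annotated), mi$annotated)
    expect_identical(sum(sub$retrieved), mi$retrieved)
    expect_identical(sum(sub$relevant), mi$relevant)
    p <- mi$relevant / mi$retrieved
    r <- mi$relevant / mi$annotated
    expect_equal(mi$f, 2 * p * r / (p + r))
    ma <- df[df$mode == m & df$label == "macro", ]
    expect_equal(ma$f, mean(sub$f))
  }
  # all-O predictions retrieve nothing
  rep0 <- per_class_report(st$gold, annotation_set(NULL, "p"),
                           corpus = st$corpus)
  expect_true(all(as.data.frame(rep0)$retrieved == 0L))
})

test_that("partial scores dominate exact scores everywhere", {
  set.seed(55)
  for (rep in 1:200) {
    g <- mk_set(random_grid_rows(sample(1:6, 1), labels = c("X", "Y")), "g")
    p <- mk_set(random_grid_rows(sample(1:6, 1), labels = c("X", "Y")), "p")
    e <- compute_prf(count_matches(g, p, "exact"))
    q <- compute_prf(count_matches(g, p, "partial"))
    for (lab in c("micro")) {
      expect_gte(q$precision[q$label == lab] + 1e-12,
                 e$precision[e$label == lab])
      expect_gte(q$recall[q$label == lab] + 1e-12, e$recall[e$label == lab])
      expect_gte(q$f[q$label == lab] + 1e-12, e$f[e$label == lab])
    }
  }
})

test_that("scheme coarsening never decreases relevant counts", {
  merge_xy <- class_scheme("xy", c(X = "Z", Y = "Z"),
                           source_labels = c("X", "Y"))
  set.seed(77)
  for (rep in 1:200) {
    g <- mk_set(random_grid_rows(sample(1:6, 1), labels = c("X", "Y")), "g")
    p <- mk_set(random_grid_rows(sample(1:6, 1), labels = c("X", "Y")), "p")
    for (mode in c("exact", "partial")) {
      before <- unname(count_matches(g, p, mode)$overall["relevant"])
      after <- unname(count_matches(apply_scheme(g, merge_xy),
                                    apply_scheme(p, merge_xy),
                                    mode)$overall["relevant"])
      expect_gte(after, before)
    }
  }
})

test_that("reports export to TSV and JSON faithfully", {
  st <- tiny_study(6L, seed = 12L)
  rep_ <- per_class_report(st$gold, st$sets[[1]], corpus = st$corpus)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep_, tsv)
  back <- utils::read.delim(tsv)
  expect_identical(nrow(back), nrow(as.data.frame(rep_)))
  expect_identical(back$relevant, as.data.frame(rep_)$relevant)
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, js)
  parsed <- jsonlite::read_json(js)
  expect_setequal(names(parsed), c("exact", "partial"))
  expect_identical(length(parsed$exact),
                   sum(as.data.frame(rep_)$mode == "exact"))
})

test_that("the false-positive audit lists exactly the unmatched predictions", {
  st <- tiny_study(6L, seed = 12L)
  pred <- st$sets[[3]]
  audit <- fp_audit(st$gold, pred, st$corpus)
  cm <- count_matches(st$gold, pred, "exact", corpus = st$corpus)
  expect_identical(nrow(audit),
                   unname(cm$overall["retrieved"] - cm$overall["relevant"]))
  # deterministic order, surface matches the text
  expect_false(is.unsorted(order(audit$doc_id, audit$start)))
  for (i in head(seq_len(nrow(audit)), 10)) {
    txt <- st$corpus[[audit$doc_id[i]]]$text
    expect_identical(audit$surface[i],
                     substring(txt, audit$start[i] + 1, audit$end[i]))
  }
  # perfect prediction -> empty audit
  expect_identical(nrow(fp_audit(st$gold, st$gold, st$corpus)), 0L)
})
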