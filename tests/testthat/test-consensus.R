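# Automatic consensus: clustering, span/label resolution, invariants

test_that("clustering chains transitive overlaps", {
  d <- grid_doc(12L)
  sets <- list(
    mk_set(data.frame(start = 0L, end = 5L, label = "X"), "a1"),
    mk_set(data.frame(start = 4L, end = 9L, label = "X"), "a2"),
    mk_set(data.frame(start = 8L, end = 12L, label = "X"), "a3"))
  cl <- cluster_annotations(annotation_study(phi_corpus(list(d)), sets))
  expect_identical(length(cl), 1L)
  expect_identical(nrow(cl[[1]]), 3L)

  # disjoint spans -> singletons; identical -> one cluster of 3
  sets2 <- list(
    mk_set(data.frame(start = 0L, end = 1L, label = "X"), "a1"),
    mk_set(data.frame(start = 4L, end = 5L, label = "X"), "a2"),
    mk_set(data.frame(start = 8L, end = 9L, label = "X"), "a3"))
  expect_identical(length(cluster_annotations(
    annotation_study(phi_corpus(list(d)), sets2))), 3L)

  same <- lapply(1:3, function(i)
    mk_set(data.frame(start = 2L, end = 6L, label = "X"), paste0("a", i)))
  cl3 <- cluster_annotations(annotation_study(phi_corpus(list(d)), same))
  expect_identical(length(cl3), 1L)
  expect_identical(nrow(cl3[[1]]), 3L)
})

test_that("span resolution picks the longest span, ties to smallest start", {
  cl <- data.frame(doc_id = "g", start = c(0L, 0L), end = c(5L, 9L),
                   label = "X", source = c("a", "b"))
  expect_identical(resolve_span(cl), c(0L, 9L))
  single <- data.frame(doc_id = "g", start = 3L, end = 7L, label = "X",
                       source = "a")
  expect_identical(resolve_span(single), c(3L, 7L))
  tie <- data.frame(doc_id = "g", start = c(2L, 0L), end = c(6L, 4L),
                    label = "X", source = c("a", "b"))
  expect_identical(resolve_span(tie), c(0L, 4L))
})

test_that("label resolution: majority, then specificity, then tie-break", {
  mk_cl <- function(labels) data.frame(
    doc_id = "g", start = 0L, end = 4L, label = labels,
    source = paste0("a", seq_along(labels)), stringsAsFactors = FALSE)
  expect_identical(resolve_label(mk_cl(c("X", "X", "Y")))$label, "X")

  r <- resolve_label(mk_cl(c("First_Name", "Clinician_First_Name")))
  expect_identical(r$label, "Clinician_First_Name")
  expect_identical(r$decision, "specificity")

  pol <- resolution_policy(tie_break = c("Town", "Age"))
  r2 <- resolve_label(mk_cl(c("Age", "Town")), pol)
  expect_identical(r2$label, "Town")
  expect_identical(r2$decision, "tie_break")
})

test_that("consensus of identical annotators is idempotent and unions disjoint sets", {
  d <- grid_doc(12L)
  rows <- data.frame(start = c(0L, 8L), end = c(3L, 11L),
                     label = c("X", "Y"))
  same <- lapply(1:3, function(i) mk_set(rows, paste0("a", i)))
  st <- annotation_study(phi_corpus(list(d)), same)
  cons <- build_automatic_consensus(st)
  expect_identical(consensus_as_plain(cons),
                   consensus_as_plain(same[[1]]))

  # pairwise-disjoint annotator sets -> consensus is the exact union
  sets <- list(
    mk_set(data.frame(start = 0L, end = 1L, label = "X"), "a1"),
    mk_set(data.frame(start = 4L, end = 5L, label = "Y"), "a2"),
    mk_set(data.frame(start = 8L, end = 9L, label = "Z"), "a3"))
  st2 <- annotation_study(phi_corpus(list(d)), sets)
  cons2 <- build_automatic_consensus(st2)
  expect_identical(nrow(cons2), 3L)
  expect_identical(consensus_as_plain(cons2),
                   consensus_as_plain(bind_annotation_sets(sets)))
})

test_that("consensus counts follow cluster counts and singleton policy", {
  st <- tiny_study(10L, seed = 8L)
  clusters <- cluster_annotations(st)
  cons <- build_automatic_consensus(st)
  expect_identical(nrow(cons), length(clusters))

  multi <- sum(vapply(clusters, function(cl)
    length(unique(cl$source)) >= 2L, logical(1)))
  cons_ns <- build_automatic_consensus(
    st, resolution_policy(include_singletons = FALSE))
  expect_identical(nrow(cons_ns), multi)
})

test_that("coverage and unanimity hold on synthetic studies", {
  st <- tiny_study(10L, seed = 8L)
  cons <- as.data.frame(build_automatic_consensus(st))
  all_in <- as.data.frame(bind_annotation_sets(st$sets))
  # every input annotation overlaps some consensus annotation
  for (i in seq_len(nrow(all_in))) {
    expect_true(any(cons$doc_id == all_in$doc_id[i] &
                      cons$start < all_in$end[i] &
                      cons$end > all_in$start[i]))
  }
  # an annotation whose whole overlap cluster is unanimous (identical span
  # and label from >= 2 annotators, no other competitor) appears verbatim
  key <- paste(all_in$doc_id, all_in$start, all_in$end, all_in$label)
  dup <- names(table(key))[table(key) >= 2]
  ckey <- paste(cons$doc_id, cons$start, cons$end, cons$label)
  n_unanimous <- 0L
  for (k in dup) {
    parts <- strsplit(k, " ")[[1]]
    s <- as.integer(parts[2]); e <- as.integer(parts[3])
    competitors <- all_in[all_in$doc_id == parts[1] &
                            all_in$start < e & all_in$end > s, ]
    if (all(competitors$start == s & competitors$end == e &
              competitors$label == parts[4])) {
      expect_true(k %in% ckey)
      n_unanimous <- n_unanimous + 1L
    }
  }
  expect_gt(n_unanimous, 0L)   # the study actually exercises the property
  # consensus output is non-overlapping
  expect_silent(annotation_set(cons))
})

test_that("consensus equals the brute-force oracle on random studies", {
  d <- grid_doc(12L)
  corpus <- phi_corpus(list(d))
  spec <- default_catalog()$specificity
  tie <- default_catalog()$labels
  set.seed(99)
  for (rep in 1:200) {
    labels <- if (rep %% 2L)
      c("First_Name", "Clinician_First_Name", "Town")
    else c("X", "Y", "Z")
    sets <- lapply(1:3, function(i)
      mk_set(random_grid_rows(sample(0:3, 1), labels = labels),
             paste0("a", i)))
    if (all(vapply(sets, nrow, integer(1)) == 0L)) next
    st <- annotation_study(corpus, sets)
    pol <- resolution_policy(specificity = spec, tie_break = tie)
    got <- consensus_as_plain(build_automatic_consensus(st, pol))
    want <- oracle_consensus(sets, spec, tie)
    expect_identical(got, want)
  }
})
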