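# Synthetic corpus generator and annotator simulation

test_that("generator is seed-deterministic and gold surfaces are intact", {
  cfg <- synth_config(n_documents = 5L, seed = 123L)
  a <- generate_gold_corpus(cfg)
  b <- generate_gold_corpus(cfg)
  expect_identical(lapply(a$corpus, `[[`, "text"),
                   lapply(b$corpus, `[[`, "text"))
  expect_identical(as.data.frame(a$gold), as.data.frame(b$gold))

  lex <- cfg$lexicons
  g <- as.data.frame(a$gold)
  for (i in seq_len(nrow(g))) {
    surf <- substring(a$corpus[[g$doc_id[i]]]$text, g$start[i] + 1, g$end[i])
    expect_true(surf %in% lex[[g$label[i]]])
  }
})

test_that("a single-label config produces exactly the requested insertions", {
  cfg <- synth_config(n_documents = 1L, phi_per_doc = 1L,
                      class_frequencies = c(Age = 1),
                      distractor_rate = 0, seed = 4L)
  gc <- generate_gold_corpus(cfg)
  expect_identical(nrow(gc$gold), 1L)
  expect_identical(gc$gold$label, "Age")
  surf <- substring(gc$corpus[[gc$gold$doc_id]]$text,
                    gc$gold$start + 1, gc$gold$end)
  expect_true(surf %in% cfg$lexicons$Age)
})

test_that("zero-weight catalogs are rejected", {
  expect_error(synth_config(class_frequencies = c(Age = 0, Town = 0)),
               "positive weight")
  expect_error(synth_config(class_frequencies = c(Nonexistent_Class = 1)),
               "no lexicon")
})

test_that("Health_Care_Unit is the modal gold class under default skew", {
  gc <- generate_gold_corpus(synth_config(n_documents = 200L,
                                          tokens_per_doc = 60L, seed = 31L))
  tab <- sort(table(gc$gold$label), decreasing = TRUE)
  expect_identical(names(tab)[1], "Health_Care_Unit")
  expect_gt(tab[1], 1.5 * tab[2])   # dominant by a clear margin
})

test_that("empirical class frequencies track configured weights", {
  # ~10,000 insertions; expected absolute deviation per class is well
  # under 2% at this n
  cfg <- synth_config(n_documents = 200L, tokens_per_doc = 0L,
                      phi_per_doc = 50L, distractor_rate = 0, seed = 17L)
  gc <- generate_gold_corpus(cfg)
  emp <- table(gc$gold$label) / nrow(gc$gold)
  for (l in names(cfg$class_frequencies)) {
    e <- if (l %in% names(emp)) emp[[l]] else 0
    expect_lt(abs(e - cfg$class_frequencies[[l]]), 0.02)
  }
})

test_that("error-model identity and extremes behave exactly", {
  st <- tiny_study(5L, seed = 9L)
  gold <- st$gold; corpus <- st$corpus

  ident <- annotator_error_model(seed = 1L)
  sim <- simulate_annotator(gold, ident, "a", corpus)
  expect_identical(as.data.frame(sim)[c("doc_id", "start", "end", "label")],
                   as.data.frame(gold)[c("doc_id", "start", "end", "label")])

  all_miss <- annotator_error_model(miss_rate = 1, seed = 1L)
  expect_identical(nrow(simulate_annotator(gold, all_miss, "a", corpus)), 0L)
})

test_that("confusion rows must be distributions", {
  expect_error(annotator_error_model(confusion = list(Age = c(Age = 0.5))),
               "sum to 1")
})

test_that("kept counts follow the binomial model", {
  cfg <- synth_config(n_documents = 200L, tokens_per_doc = 0L,
                      phi_per_doc = 10L, distractor_rate = 0, seed = 29L)
  gc <- generate_gold_corpus(cfg)
  n <- nrow(gc$gold)
  expect_identical(n, 2000L)
  m <- annotator_error_model(miss_rate = 0.2, seed = 77L)
  kept <- nrow(simulate_annotator(gc$gold, m, "a", gc$corpus))
  sigma <- sqrt(n * 0.8 * 0.2)
  expect_lt(abs(kept - n * 0.8), 3 * sigma)
})

test_that("simulated sets are non-overlapping and spurious spans avoid gold", {
  st <- tiny_study(10L, seed = 13L)
  spur <- annotator_error_model(miss_rate = 0.1, boundary_jitter = 0.2,
                                spurious_rate = 1.5, seed = 19L)
  sim <- simulate_annotator(st$gold, spur, "a", st$corpus)
  # internal non-overlap survives annotation_set's validator
  expect_silent(annotation_set(as.data.frame(sim)))
  # spurious annotations (those matching no gold char-overlap) avoid gold
  g <- as.data.frame(st$gold)
  s <- as.data.frame(sim)
  for (i in seq_len(nrow(s))) {
    ov <- g$doc_id == s$doc_id[i] & g$start < s$end[i] & g$end > s$start[i]
    # every simulated annotation either overlaps gold (kept/jittered) or
    # sits entirely on unannotated tokens
    if (!any(ov)) {
      expect_false(any(g$doc_id == s$doc_id[i] &
                         pmax(g$start, s$start[i]) < pmin(g$end, s$end[i])))
    }
  }
})

test_that("asymmetric miss rates produce the expected total-count gap", {
  cfg <- synth_config(n_documents = 200L, tokens_per_doc = 0L,
                      phi_per_doc = 10L, distractor_rate = 0, seed = 41L)
  gc <- generate_gold_corpus(cfg)
  n <- nrow(gc$gold)
  low <- simulate_annotator(gc$gold,
                            annotator_error_model(miss_rate = 0.05, seed = 1L),
                            "a1", gc$corpus)
  high <- simulate_annotator(gc$gold,
                             annotator_error_model(miss_rate = 0.30, seed = 2L),
                             "a2", gc$corpus)
  gap <- nrow(low) - nrow(high)
  exp_gap <- n * 0.25
  sigma <- sqrt(n * (0.05 * 0.95 + 0.30 * 0.70))
  expect_lt(abs(gap - exp_gap), 3 * sigma)
})

test_that("a study needs at least two annotators", {
  cfg <- synth_config(n_documents = 2L, seed = 1L)
  expect_error(build_annotation_study(cfg, list(annotator_error_model())),
               "at least 2")
})

test_that("identical zero-error models give identical annotator sets", {
  cfg <- synth_config(n_documents = 3L, seed = 6L)
  models <- lapply(1:3, function(i) annotator_error_model(seed = 55L))
  st <- build_annotation_study(cfg, models)
  ref <- as.data.frame(st$sets[[1]])[c("doc_id", "start", "end", "label")]
  for (s in st$sets)
    expect_identical(as.data.frame(s)[c("doc_id", "start", "end", "label")],
                     ref)
})
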