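# Core data types: tokenizer, standoff I/O, BIO encoding

test_that("tokenizer keeps hyphenated words, numbers and abbreviations whole", {
  expect_identical(nrow(tokenize("")), 0L)

  txt <- "34-årig man"
  tk <- tokenize(txt)
  expect_identical(substring(txt, tk[, 1] + 1, tk[, 2]), c("34-årig", "man"))

  # hand-tokenized fixture (written before the tokenizer): abbreviation
  # period kept, comma split off
  txt <- "Karolinska Univ. Sjukh, Huddinge"
  tk <- tokenize(txt)
  expect_identical(substring(txt, tk[, 1] + 1, tk[, 2]),
                   c("Karolinska", "Univ.", "Sjukh", ",", "Huddinge"))

  txt <- "Opererad 2008-03-14 kl. 10:30. Tel 08-517 746 12."
  tk <- tokenize(txt)
  expect_identical(substring(txt, tk[, 1] + 1, tk[, 2]),
                   c("Opererad", "2008-03-14", "kl.", "10:30", ".",
                     "Tel", "08-517", "746", "12", "."))
})

test_that("tokenizer is offset-consistent and reconstructs the text", {
  set.seed(42)
  samples <- c(
    "Pat må bra. Återbesök 3/5 på Danderyds sjukhus, akutmott.",
    "   inledande   blanksteg\toch\ttabbar  ",
    "!!??  (parenteser) [och] {annat}",
    "enda"
  )
  for (txt in samples) {
    tk <- tokenize(txt)
    if (!nrow(tk)) next
    toks <- substring(txt, tk[, 1] + 1, tk[, 2])
    expect_false(any(grepl("\\s", toks)))
    expect_true(all(nchar(toks) > 0))
    expect_true(all(tk[, 1] < tk[, 2]))
    if (nrow(tk) > 1)
      expect_true(all(tk[-1, 1] >= tk[-nrow(tk), 2]))
    # concatenating tokens + separators reconstructs the text
    rebuilt <- ""
    prev <- 0L
    for (i in seq_len(nrow(tk))) {
      rebuilt <- paste0(rebuilt, substring(txt, prev + 1, tk[i, 1]), toks[i])
      prev <- tk[i, 2]
    }
    rebuilt <- paste0(rebuilt, substring(txt, prev + 1, nchar(txt)))
    expect_identical(rebuilt, txt)
  }
})

test_that("standoff reader checks offsets and surfaces", {
  dir <- withr::local_tempdir()
  writeLines("Anna kom in.", file.path(dir, "d1.txt"))
  writeLines("T1\tFirst_Name 0 4\tAnna", file.path(dir, "d1.ann"))
  r <- read_standoff(file.path(dir, "d1.ann"), file.path(dir, "d1.txt"))
  expect_identical(nrow(r$set), 1L)
  expect_identical(r$set$label, "First_Name")
  expect_identical(r$set$start, 0L)
  expect_identical(r$set$end, 4L)

  writeLines("T1\tFirst_Name 0 4\tBnna", file.path(dir, "d1.ann"))
  expect_error(read_standoff(file.path(dir, "d1.ann"),
                             file.path(dir, "d1.txt")),
               "surface mismatch")

  writeLines("T1\tFirst_Name 0 99\tAnna", file.path(dir, "d1.ann"))
  expect_error(read_standoff(file.path(dir, "d1.ann"),
                             file.path(dir, "d1.txt")),
               "out of range")
})

test_that("standoff write/read round-trips random sets", {
  dir <- withr::local_tempdir()
  doc <- grid_doc(12L, "g")
  writeLines(doc$text, file.path(dir, "g.txt"))
  set.seed(7)
  for (rep in 1:100) {
    rows <- random_grid_rows(sample(0:4, 1))
    s <- mk_set(rows, "a1")
    write_standoff(s, file.path(dir, "g.a1.ann"),
                   phi_corpus(list(doc)))
    r <- read_standoff(file.path(dir, "g.a1.ann"), file.path(dir, "g.txt"),
                       doc_id = "g", source = "a1")
    expect_identical(as.data.frame(r$set), as.data.frame(s))
  }
  # empty set -> empty file
  write_standoff(annotation_set(NULL), file.path(dir, "empty.ann"))
  expect_identical(length(readLines(file.path(dir, "empty.ann"))), 0L)
})

test_that("multi-document standoff files carry doc sections in order", {
  dir <- withr::local_tempdir()
  rows <- rbind(
    data.frame(doc_id = "b", start = 0L, end = 1L, label = "X"),
    data.frame(doc_id = "a", start = 2L, end = 3L, label = "Y"))
  s <- annotation_set(rows, source = "s")
  write_standoff(s, file.path(dir, "multi.ann"))
  lines <- readLines(file.path(dir, "multi.ann"))
  expect_identical(grep("^#doc", lines, value = TRUE),
                   c("#doc a", "#doc b"))
})

test_that("BIO encoding covers whole tokens and decoding inverts it", {
  d <- phi_document("d1", "Anna Svensson kom in.")
  s <- annotation_set(data.frame(doc_id = "d1", start = 5L, end = 13L,
                                 label = "Last_Name"), source = "g")
  enc <- encode_bio(d, s)
  expect_identical(enc$tag, c("O", "B-Last_Name", "O", "O", "O"))

  # no annotations -> all O
  expect_true(all(encode_bio(d, annotation_set(NULL))$tag == "O"))

  # annotation covering half a token is snapped to the whole token
  half <- annotation_set(data.frame(doc_id = "d1", start = 5L, end = 8L,
                                    label = "Last_Name"), source = "g")
  ench <- encode_bio(d, half)
  expect_identical(ench$tag[2], "B-Last_Name")
  expect_identical(attr(ench, "n_snapped"), 1L)
  dec <- decode_bio(ench, "d1")
  expect_identical(dec$start, 5L)   # token-extended span
  expect_identical(dec$end, 13L)

  expect_error(encode_bio(d, annotation_set(data.frame(
    doc_id = "d1", start = c(0L, 3L), end = c(6L, 9L),
    label = c("A", "B"), source = c("x", "y")), validate = FALSE)),
    "overlap")
})

test_that("orphan I tags are repaired IOB2-style", {
  tt <- data.frame(token = c("a", "b", "c"), tag = c("O", "I-Age", "O"),
                   start = c(0L, 2L, 4L), end = c(1L, 3L, 5L))
  dec <- decode_bio(tt, "d")
  expect_identical(nrow(dec), 1L)
  expect_identical(dec$label, "Age")
  expect_identical(c(dec$start, dec$end), c(2L, 3L))

  tt$tag <- c("B-Age", "I-Town", "I-Town")
  dec <- decode_bio(tt, "d")
  expect_identical(dec$label, c("Age", "Town"))

  tt$tag <- c("O", "Q-bad", "O")
  expect_error(decode_bio(tt, "d"), "unknown tag")
})

test_that("encode/decode round-trip holds for random token-aligned sets", {
  doc <- grid_doc(12L)
  set.seed(11)
  for (rep in 1:100) {
    rows <- random_grid_rows(sample(0:5, 1), labels = c("X", "Y", "Z"))
    s <- mk_set(rows, "gold")
    dec <- decode_bio(encode_bio(doc, s), "g", source = "gold")
    expect_identical(as.data.frame(dec)[c("doc_id", "start", "end", "label")],
                     as.data.frame(s)[c("doc_id", "start", "end", "label")])
  }
})

test_that("CoNLL round trip preserves tokens and tags", {
  st <- tiny_study(4L, seed = 2L)
  path <- withr::local_tempfile()
  write_conll(st$corpus, st$gold, path)
  back <- read_conll(path)
  expect_identical(names(back), names(st$corpus))
  for (d in names(back)) {
    enc <- encode_bio(st$corpus[[d]], st$gold)
    expect_identical(back[[d]]$token, enc$token)
    expect_identical(back[[d]]$tag, enc$tag)
  }
})
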