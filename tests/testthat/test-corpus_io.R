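test_that("abstracts files parse field-by-field and validate structure", {
  path <- withr::local_tempfile()
  writeLines(c("D1\tAspirin trial\tWe tested aspirin.",
               "D2\tSecond doc\tNothing here."), path)
  docs <- read_abstracts(path)
  expect_equal(docs$doc_id, c("D1", "D2"))
  expect_equal(docs$title[1], "Aspirin trial")
  expect_equal(docs$abstract[1], "We tested aspirin.")

  writeLines(character(), path)
  expect_equal(nrow(read_abstracts(path)), 0)

  writeLines("D1\tonly two fields", path)
  expect_error(read_abstracts(path), "line 1")

  writeLines(c("D1\ta\tb", "D1\tc\td"), path)
  expect_error(read_abstracts(path), "duplicate")
})

test_that("annotation records are validated against their section slice", {
  docs <- make_docs("D1", "Aspirin trial", "We tested aspirin.")
  path <- withr::local_tempfile()
  writeLines("D1\tA\t10\t17\taspirin\tTRIVIAL", path)
  anns <- read_annotations(path, docs)
  expect_equal(anns$text, "aspirin")
  expect_equal(anns$cls, "TRIVIAL")
  expect_equal(anns$confidence, 1)

  writeLines("D1\tA\t10\t99\taspirin\tTRIVIAL", path)
  expect_error(read_annotations(path, docs), "outside section")

  writeLines("D1\tA\t10\t17\tasprin\tTRIVIAL", path)
  expect_error(read_annotations(path, docs), "asprin")

  writeLines("D1\tA\t10\t17\taspirin\tBOGUS", path)
  expect_warning(anns <- read_annotations(path, docs), "UNCLASSIFIED")
  expect_equal(anns$cls, "UNCLASSIFIED")

  writeLines("D9\tA\t0\t2\tWe\tTRIVIAL", path)
  expect_error(read_annotations(path, docs), "unknown doc_id")
})

test_that("gold annotations round-trip through the TSV writer and reader", {
  corpus <- generate_corpus(generator_config(n_docs = 5, seed = 11))
  ap <- withr::local_tempfile(); gp <- withr::local_tempfile()
  write_abstracts(corpus$docs, ap)
  write_annotations(corpus$gold, gp)
  docs2 <- read_abstracts(ap)
  gold2 <- read_annotations(gp, docs2)
  expect_equal(docs2, corpus$docs)
  expect_equal(gold2$start, corpus$gold$start)
  expect_equal(gold2$end, corpus$gold$end)
  expect_equal(gold2$text, corpus$gold$text)
  expect_equal(gold2$cls, corpus$gold$cls)
})

test_that("BIO encoding marks span-initial tokens B and continuations I", {
  toks <- tokenize("We tested aspirin .")
  gold <- annotations("D1", "A", 10L, 17L, "aspirin")
  expect_equal(encode_bio(toks, gold), c("O", "O", "B", "O"))

  toks2 <- tokenize("acetylsalicylic acid works")
  gold2 <- annotations("D1", "A", 0L, 20L, "acetylsalicylic acid")
  expect_equal(encode_bio(toks2, gold2), c("B", "I", "O"))

  expect_equal(encode_bio(toks, annotations()), c("O", "O", "O", "O"))

  overlapping <- rbind(annotations("D1", "A", 0L, 9L, "We tested"),
                       annotations("D1", "A", 3L, 17L, "tested aspirin"))
  expect_error(encode_bio(toks, overlapping), "overlapping")
})

test_that("gold boundaries inside a token snap outward with a warning", {
  toks <- tokenize("We tested aspirin")
  gold <- annotations("D1", "A", 12L, 17L, "pirin")
  expect_warning(labels <- encode_bio(toks, gold), "snapped")
  expect_equal(labels, c("O", "O", "B"))
})

test_that("decode_bio inverts encode_bio on token-aligned spans", {
  text <- "We tested aspirin and acetylsalicylic acid today"
  toks <- tokenize(text)
  gold <- rbind(annotations("D1", "A", 10L, 17L, "aspirin"),
                annotations("D1", "A", 22L, 42L, "acetylsalicylic acid"))
  labels <- encode_bio(toks, gold)
  back <- decode_bio(toks, labels, "D1", "A", text)
  expect_equal(back$start, gold$start)
  expect_equal(back$end, gold$end)
  expect_equal(back$text, gold$text)

  expect_equal(nrow(decode_bio(toks, rep("O", nrow(toks)), "D1", "A", text)), 0)
  expect_warning(rep <- decode_bio(toks, c("O", "I", "O", "O", "O", "O", "O"),
                                   "D1", "A", text), "repaired")
  expect_equal(rep$text, "tested")
})

test_that("encode/decode round-trips exactly on generated corpora", {
  corpus <- generate_corpus(generator_config(n_docs = 8, seed = 3))
  seqs <- preprocess_corpus(corpus$docs, default_tagger())
  recovered <- list()
  for (toks in seqs) {
    did <- attr(toks, "doc_id"); sec <- attr(toks, "section")
    g <- corpus$gold[corpus$gold$doc_id == did & corpus$gold$section == sec &
                       corpus$gold$start < max(toks$end) &
                       corpus$gold$end > min(toks$start), ]
    labels <- encode_bio(toks, g)
    recovered[[length(recovered) + 1L]] <-
      decode_bio(toks, labels, did, sec, attr(toks, "sect_text"))
  }
  rec <- do.call(rbind, recovered)
  key <- function(a) sort(paste(a$doc_id, a$section, a$start, a$end))
  expect_equal(key(rec), key(corpus$gold))
})

test_that("CEM and CDI writers enforce the format and rank contract", {
  path <- withr::local_tempfile()
  a <- annotations("D1", "A", 10L, 17L, "aspirin", confidence = 0.912345)
  a$rank <- 1L
  write_cem(a, path)
  expect_equal(readLines(path), "D1\tA:10:17\t1\t0.912345")

  write_cem(a[0, ], path)
  expect_equal(length(readLines(path)), 0)

  two <- rbind(annotations("D1", "A", 0L, 2L, "We", confidence = 0.9),
               annotations("D1", "A", 3L, 9L, "tested", confidence = 0.7))
  two$rank <- c(1L, 3L)
  expect_error(write_cem(two, path), "contiguous")
  two$rank <- c(1L, 2L)
  write_cem(two, path)
  docs <- make_docs("D1", "t", "We tested aspirin.")
  back <- read_cem(path, docs)
  expect_equal(back$start, c(0L, 3L))
  expect_equal(back$confidence, c(0.9, 0.7))

  cdi <- data.frame(doc_id = "D1", text = "aspirin", rank = 1L,
                    confidence = 0.5, stringsAsFactors = FALSE)
  write_cdi(cdi, path)
  expect_equal(readLines(path), "D1\taspirin\t1\t0.500000")
  expect_equal(read_cdi(path)$text, "aspirin")
})
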