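test_that("parentheses filter removes odd bracket counts only", {
  a <- rbind(annotations("D1", "A", 0L, 18L, "1-(2-chlorophenyl)"),
             annotations("D1", "A", 20L, 29L, "2-(chloro"),
             annotations("D1", "A", 31L, 38L, "aspirin"),
             annotations("D1", "A", 40L, 47L, "a[b]{c}"))
  out <- parentheses_filter(a)
  expect_equal(out$text, c("1-(2-chlorophenyl)", "aspirin", "a[b]{c}"))
})

test_that("abbreviation detection finds worked short/long form pairs", {
  p <- detect_abbreviations(
    "Patients took non-steroidal anti-inflammatory drugs (NSAIDs) daily.")
  expect_equal(nrow(p), 1)
  expect_equal(p$short_text, "NSAIDs")
  expect_equal(p$long_text, "non-steroidal anti-inflammatory drugs")

  p2 <- detect_abbreviations("ethanol (EtOH) was administered overnight.")
  expect_equal(p2$short_text, "EtOH")
  expect_equal(p2$long_text, "ethanol")

  expect_equal(nrow(detect_abbreviations("The assay failed (see Figure 1).")), 0)
  expect_equal(nrow(detect_abbreviations("No parenthesis here.")), 0)
})

test_that("abbreviation spans carry correct offsets in the section frame", {
  txt <- "Patients received gamma aminobutyric acid (GABA) infusions."
  p <- detect_abbreviations(txt, offset = 100L, doc_id = "D1", section = "A")
  expect_equal(substr(txt, p$short_start - 100 + 1, p$short_end - 100), "GABA")
  expect_equal(substr(txt, p$long_start - 100 + 1, p$long_end - 100),
               "gamma aminobutyric acid")
})

test_that("abbreviation resolution adds, expands, and never removes", {
  abstract <- "Patients took non-steroidal anti-inflammatory drugs (NSAIDs) daily."
  docs <- make_docs("D1", "t", abstract)
  pairs <- detect_abbreviations_corpus(docs)
  expect_equal(nrow(pairs), 1)

  # short form annotated -> long form added
  short_ann <- annotations("D1", "A", pairs$short_start, pairs$short_end,
                           "NSAIDs", confidence = 0.8, source = "m1")
  out <- abbreviation_resolution(short_ann, pairs, docs)
  expect_equal(nrow(out), 2)
  added <- out[out$source == "abbrev", ]
  expect_equal(added$text, "non-steroidal anti-inflammatory drugs")
  expect_equal(added$confidence, 0.8)

  # partial coverage expanded to the form's full span
  part <- annotations("D1", "A", 28L, 51L, substr(abstract, 29, 51),
                      confidence = 0.6, source = "m1")
  out2 <- abbreviation_resolution(part, pairs, docs)
  long_row <- out2[out2$start == pairs$long_start, ]
  expect_equal(long_row$end, pairs$long_end)

  # neither form annotated -> unchanged
  other <- annotations("D1", "A", 0L, 8L, "Patients", confidence = 0.5,
                       source = "m1")
  expect_equal(nrow(abbreviation_resolution(other, pairs, docs)), 1)
})

test_that("exclusion list applies the log-odds and min-fp thresholds", {
  mk <- function(texts, starts, doc = "D1") {
    annotations(doc, "A", starts, starts + nchar(texts), texts,
                confidence = 0.5, source = "m")
  }
  # mention "was": 0 TP, 3 FP; mention "aspirin": 3 TP, 0 FP;
  # mention "salt": 10 TP (as gold), 1 FP
  gold <- mk(rep("aspirin", 3), c(0, 100, 200))
  gold <- rbind(gold, mk(rep("salt", 10), seq(300, 1200, by = 100)))
  pred <- rbind(mk(rep("aspirin", 3), c(0, 100, 200)),
                mk(rep("was", 3), c(50, 150, 250)),
                mk(rep("salt", 10), seq(300, 1200, by = 100)),
                mk("salt", 1300))
  xl <- build_exclusion_list(gold, pred, theta = 0.3, min_fp = 2)
  expect_equal(xl$entries, "was")  # ln(0.5/3.5) < 0.3 and 3 FP
  # "salt": ln(10.5/1.5) > 0.3, and FP count 1 < 2 -> excluded twice over
  xl2 <- build_exclusion_list(gold, pred, theta = 10, min_fp = 2)
  expect_false("salt" %in% xl2$entries)  # min_fp guard alone
  # monotonicity: theta = -Inf gives empty; huge theta and min_fp 0 gives all
  expect_equal(length(build_exclusion_list(gold, pred, -Inf, 0)$entries), 0)
  xl_all <- build_exclusion_list(gold, pred, Inf, 0)
  expect_setequal(xl_all$entries, c("aspirin", "was", "salt"))
  expect_equal(length(build_exclusion_list(gold, pred[0, ], 0.3, 2)$entries), 0)
})

test_that("applying an exclusion list is case-insensitive removal only", {
  a <- rbind(annotations("D1", "A", 0L, 3L, "WAS", confidence = 0.4),
             annotations("D1", "A", 10L, 17L, "aspirin", confidence = 0.9))
  xl <- structure(list(entries = "was", theta = 0.3, min_fp = 2L),
                  class = "exclusion_list")
  out <- apply_exclusion_list(a, xl)
  expect_equal(out$text, "aspirin")
  expect_equal(apply_exclusion_list(a, structure(list(entries = character(0)),
                                                 class = "exclusion_list")), a)
})

test_that("exclusion list files round-trip with their thresholds", {
  xl <- structure(list(entries = c("acid", "was"), theta = 0.25, min_fp = 3L),
                  class = "exclusion_list")
  path <- withr::local_tempfile()
  write_exclusion_list(xl, path, source_tag = "dev")
  back <- read_exclusion_list(path)
  expect_equal(back$entries, xl$entries)
  expect_equal(back$theta, 0.25)
  expect_equal(back$min_fp, 3L)
})

test_that("threshold tuning recovers a planted always-wrong mention", {
  corpus <- generate_corpus(generator_config(n_docs = 30, seed = 17))
  preds <- corrupt_predictions(corpus$gold, corpus$docs, seed = 5,
                               fp_rate = 1, fn_rate = 0,
                               trap_terms = corpus$trap_terms)
  tuned <- tune_exclusion_thresholds(corpus$gold, preds,
                                     theta_grid = c(0.3), min_fp_grid = c(2L),
                                     folds = 10, seed = 9)
  expect_equal(tuned$theta, 0.3)
  expect_equal(tuned$min_fp, 2L)
  expect_gt(tuned$mean_delta_f1, 0)
  xl <- build_exclusion_list(corpus$gold, preds, tuned$theta, tuned$min_fp)
  expect_true(any(corpus$trap_terms %in% xl$entries))

  # predictions identical to gold: no false positives, nothing to gain
  perfect <- corrupt_predictions(corpus$gold, corpus$docs, seed = 5)
  tuned2 <- tune_exclusion_thresholds(corpus$gold, perfect, c(0.3), c(2L),
                                      folds = 10, seed = 9)
  expect_lte(tuned2$mean_delta_f1, 0)

  expect_error(tune_exclusion_thresholds(corpus$gold[1:5, ], preds[1:5, ],
                                         folds = 10), "fewer documents")
})
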