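cfg_small <- feature_config(enabled_groups = c("token", "lemma", "pos",
                                               "suffix", "prefix", "word_shape",
                                               "context_conjunctions"),
                            context_windows = list(c(-1L, 0L), c(0L, 1L)))

fit_tiny <- function(order = 1, direction = "forward", n_rep = 2) {
  tc <- tiny_training_corpus(n_rep)
  seqs <- preprocess_corpus(tc$docs)
  td <- make_training_data(seqs, tc$gold, NULL, cfg_small)
  model <- train_crf(td, order = order, direction = direction, maxit = 200,
                     feature_config = cfg_small)
  list(model = model, td = td, tc = tc, seqs = seqs)
}

test_that("order-1 CRF overfits a toy corpus to near-perfect training F1", {
  fit <- fit_tiny(order = 1)
  preds <- decode_corpus(fit$model, fit$seqs)
  r <- evaluate(preds, fit$tc$gold, "exact")
  expect_gte(r$f1, 95)
  expect_true(all(preds$confidence >= 0 & preds$confidence <= 1))
})

test_that("order-2 label transform produces consecutive-pair states", {
  sts <- chemtagr:::crf_states(2)
  ids <- chemtagr:::labels_to_states(c("O", "B", "I"), 2)
  expect_equal(sts$states[ids + 1], c("BOS|O", "O|B", "B|I"))
  # transition structure: (a,b) -> (b,c) only, and I needs B/I before it
  expect_true(sts$trans_allowed["O|B", "B|I"])
  expect_false(sts$trans_allowed["O|B", "O|B"])
  expect_false(sts$trans_allowed["B|O", "B|I"])
})

test_that("training rejects degenerate inputs", {
  expect_error(train_crf(list()), "empty")
  bad <- list(list(features = list("W=a", "W=b"), labels = c("O", "I")))
  expect_error(train_crf(bad), "BIO")
})

test_that("backward parsing trains and decodes well-formed annotations", {
  fit <- fit_tiny(order = 1, direction = "backward")
  preds <- decode_corpus(fit$model, fit$seqs)
  r <- evaluate(preds, fit$tc$gold, "exact")
  expect_gte(r$f1, 95)
  for (i in seq_len(nrow(preds)))
    expect_gt(preds$end[i], preds$start[i])
})

test_that("span confidences equal brute-force enumeration on short sentences", {
  for (ord in c(1, 2)) {
    fit <- fit_tiny(order = ord)
    checked <- 0
    for (sq in fit$td) {
      if (length(sq$labels) > 8) next
      anns <- decode(fit$model, sq$tokens, sq$features)
      if (nrow(anns) == 0) next
      labels <- attr(anns, "labels")
      toks <- sq$tokens
      for (i in seq_len(nrow(anns))) {
        span_toks <- which(toks$start >= anns$start[i] & toks$end <= anns$end[i])
        p_oracle <- oracle_span_prob(fit$model, sq$features,
                                     min(span_toks), max(span_toks),
                                     labels[span_toks])
        expect_equal(anns$confidence[i], p_oracle, tolerance = 1e-9)
        checked <- checked + 1
      }
      if (checked >= 5) break
    }
    expect_gte(checked, 1)
  }
})

test_that("an order-2 model with tied weights decodes like its order-1 source", {
  fit <- fit_tiny(order = 1)
  m1 <- fit$model
  sp2 <- chemtagr:::crf_states(2)
  S1 <- 3; S2 <- length(sp2$states)
  nf <- length(m1$feat_names)
  theta2 <- numeric(nf * S2 + S2 * S2 + S2)
  lab_idx <- match(sp2$cur, c("O", "B", "I")) - 1L
  for (s2 in seq_len(S2) - 1L) {
    c1 <- lab_idx[s2 + 1L]
    theta2[(0:(nf - 1)) * S2 + s2 + 1L] <- m1$theta[(0:(nf - 1)) * S1 + c1 + 1L]
  }
  for (a in seq_len(S2)) for (b in seq_len(S2)) {
    if (!sp2$trans_allowed[a, b]) next
    t1 <- m1$theta[nf * S1 + lab_idx[a] * S1 + lab_idx[b] + 1L]
    theta2[nf * S2 + (a - 1L) * S2 + b] <- t1
  }
  for (s2 in which(sp2$init_allowed))
    theta2[nf * S2 + S2 * S2 + s2] <- m1$theta[nf * S1 + S1 * S1 + lab_idx[s2] + 1L]
  m2 <- m1
  m2$order <- 2; m2$states <- sp2$states; m2$cur_label <- sp2$cur
  m2$trans_allowed <- sp2$trans_allowed; m2$init_allowed <- sp2$init_allowed
  m2$theta <- theta2
  for (sq in fit$td[1:10]) {
    a1 <- decode(m1, sq$tokens, sq$features)
    a2 <- decode(m2, sq$tokens, sq$features)
    expect_equal(attr(a1, "labels"), attr(a2, "labels"))
  }
})

test_that("harmonization keeps the highest-confidence annotation on overlap", {
  s1 <- annotations("D1", "A", 5L, 10L, "xxxxx", confidence = 0.9, source = "m1")
  s2 <- annotations("D1", "A", 8L, 12L, "xxxx", confidence = 0.7, source = "m2")
  h <- harmonize(list(s1, s2))
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 5L)

  d1 <- annotations("D1", "A", 0L, 4L, "aaaa", confidence = 0.2, source = "m1")
  d2 <- annotations("D1", "A", 10L, 14L, "bbbb", confidence = 0.9, source = "m2")
  expect_equal(nrow(harmonize(list(d1, d2))), 2)

  chain <- list(
    annotations("D1", "A", 0L, 5L, "aaaaa", confidence = 0.6, source = "m1"),
    annotations("D1", "A", 4L, 9L, "bbbbb", confidence = 0.8, source = "m2"),
    annotations("D1", "A", 8L, 12L, "cccc", confidence = 0.7, source = "m3"))
  h3 <- harmonize(chain)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$start, 4L)
})

test_that("harmonization is idempotent and identity on single sets", {
  set.seed(99)
  for (rep in 1:50) {
    s1 <- random_annotation_set(n = sample(1:4, 1), source = "m1")
    s2 <- random_annotation_set(n = sample(1:4, 1), source = "m2")
    h <- harmonize(list(s1, s2))
    expect_equal(harmonize(list(h)), h)
    # non-overlapping output
    if (nrow(h) > 1)
      expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
  }
  single <- random_annotation_set(n = 3, source = "m1")
  expect_equal(nrow(harmonize(list(single))), nrow(single))
})

test_that("model serialization round-trips", {
  fit <- fit_tiny()
  path <- withr::local_tempfile(fileext = ".rds")
  save_crf(fit$model, path)
  m <- load_crf(path)
  expect_equal(m$theta, fit$model$theta)
  preds1 <- decode_corpus(fit$model, fit$seqs)
  preds2 <- decode_corpus(m, fit$seqs)
  expect_equal(preds1, preds2)
  saveRDS(1:3, path)
  expect_error(load_crf(path), "crf_model")
})
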