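# Shared fixtures and an independent brute-force oracle for CRF
# probabilities. The oracle enumerates whole label sequences and scores them
# directly from the model's weight vector, without touching the package's
# forward-backward code path.

make_docs <- function(ids, titles, abstracts) {
  data.frame(doc_id = ids, title = titles, abstract = abstracts,
             stringsAsFactors = FALSE)
}

# a tiny hand-written training corpus: chemical mentions in stereotyped
# contexts, enough for a CRF to overfit
tiny_training_corpus <- function(n_rep = 5) {
  chems <- c("aspirin", "ibuprofen", "caffeine", "morphine", "insulin",
             "heparin", "warfarin", "diazepam", "codeine", "nicotine")
  docs <- list(); golds <- list()
  k <- 0
  for (r in seq_len(n_rep)) {
    for (ch in chems) {
      k <- k + 1
      abstract <- paste0("We tested ", ch, " in mice. The dose was safe.")
      docs[[k]] <- make_docs(sprintf("D%03d", k), "A short study", abstract)
      golds[[k]] <- annotations(sprintf("D%03d", k), "A", 10L, 10L + nchar(ch),
                                ch, cls = "TRIVIAL")
    }
  }
  list(docs = do.call(rbind, docs), gold = do.call(rbind, golds))
}

# model parameter accessors mirroring the layout documented in src/crf.cpp
theta_emit <- function(model, f0, s0) {
  S <- length(model$states)
  model$theta[f0 * S + s0 + 1L]
}
theta_trans <- function(model, s0, s20) {
  S <- length(model$states)
  nf <- length(model$feat_names)
  model$theta[nf * S + s0 * S + s20 + 1L]
}
theta_init <- function(model, s0) {
  S <- length(model$states)
  nf <- length(model$feat_names)
  model$theta[nf * S + S * S + s0 + 1L]
}

# score one BIO label sequence under a model, or -Inf if structurally invalid
oracle_path_score <- function(model, feat_ids, labels) {
  S <- length(model$states)
  n <- length(labels)
  if (model$order == 1) {
    sts <- match(labels, c("O", "B", "I")) - 1L
  } else {
    prev <- c("BOS", labels[-n])
    sts <- match(paste(prev, labels, sep = "|"), model$states) - 1L
    if (any(is.na(sts))) return(-Inf)
  }
  if (!model$init_allowed[sts[1] + 1L]) return(-Inf)
  score <- theta_init(model, sts[1])
  for (t in seq_len(n)) {
    for (f in feat_ids[[t]]) score <- score + theta_emit(model, f, sts[t])
    if (t > 1) {
      if (!model$trans_allowed[sts[t - 1] + 1L, sts[t] + 1L]) return(-Inf)
      score <- score + theta_trans(model, sts[t - 1], sts[t])
    }
  }
  score
}

# enumerate all 3^n BIO label sequences; returns probability that positions
# from:to carry exactly `span_labels`
oracle_span_prob <- function(model, features, span_from, span_to, span_labels) {
  feat_ids <- lapply(features, function(f) {
    id <- match(f, model$feat_names) - 1L
    id[!is.na(id)]
  })
  n <- length(features)
  labs <- c("O", "B", "I")
  grid <- expand.grid(rep(list(labs), n), stringsAsFactors = FALSE)
  scores <- apply(grid, 1, function(row)
    oracle_path_score(model, feat_ids, unname(row)))
  m <- max(scores)
  w <- exp(scores - m)
  z <- sum(w)
  in_span <- apply(grid, 1, function(row)
    identical(unname(row[span_from:span_to]), span_labels))
  sum(w[in_span]) / z
}

# random internally non-overlapping annotation set on one document section
random_annotation_set <- function(doc_id = "D1", n = 3, source = "s1",
                                  sect_len = 60) {
  starts <- sort(sample(0:(sect_len - 6), n))
  rows <- list()
  last_end <- -1L
  for (s in starts) {
    if (s <= last_end) next
    e <- min(sect_len, s + sample(2:6, 1))
    rows[[length(rows) + 1L]] <- annotations(
      doc_id, "A", s, e, strrep("x", e - s),
      confidence = round(runif(1), 3), source = source)
    last_end <- e
  }
  do.call(rbind, rows)
}
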