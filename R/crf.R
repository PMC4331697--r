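BIO_LABELS <- c("O", "B", "I")

valid_bio <- function(labels) {
  if (length(labels) == 0) return(TRUE)
  if (any(!labels %in% BIO_LABELS)) return(FALSE)
  prev <- c("O", labels[-length(labels)])
  !any(labels == "I" & prev == "O")
}

# re-encode labels of a reversed sequence so every entity run is valid BIO
# (the first token of each run in the new direction gets B)
flip_bio <- function(labels) {
  n <- length(labels)
  if (n == 0) return(labels)
  out <- rep("O", n)
  inside <- labels != "O"
  prev <- c(FALSE, inside[-n])
  out[inside & !prev] <- "B"
  out[inside & prev] <- "I"
  out
}

# state space for a given label order; order 2 expands labels to
# (previous, current) pairs with an explicit BOS previous label
crf_states <- function(order) {
  if (order == 1) {
    states <- BIO_LABELS
    cur <- BIO_LABELS
    init <- c(TRUE, TRUE, FALSE)  # a sequence cannot start with I
    trans <- matrix(TRUE, 3, 3, dimnames = list(states, states))
    trans["O", "I"] <- FALSE
  } else if (order == 2) {
    pairs <- list(c("BOS", "O"), c("BOS", "B"),
                  c("O", "O"), c("O", "B"),
                  c("B", "B"), c("B", "I"), c("B", "O"),
                  c("I", "I"), c("I", "B"), c("I", "O"))
    states <- vapply(pairs, paste, "", collapse = "|")
    prev <- vapply(pairs, `[[`, "", 1L)
    cur <- vapply(pairs, `[[`, "", 2L)
    init <- prev == "BOS"
    S <- length(states)
    trans <- matrix(FALSE, S, S, dimnames = list(states, states))
    for (i in seq_len(S)) for (j in seq_len(S)) {
      ok <- prev[j] == cur[i] && prev[j] != "BOS" &&
        !(cur[j] == "I" && !cur[i] %in% c("B", "I"))
      trans[i, j] <- ok
    }
  } else stop("only CRF orders 1 and 2 are supported")
  list(states = states, cur = cur, init_allowed = init, trans_allowed = trans)
}

labels_to_states <- function(labels, order) {
  if (order == 1) return(match(labels, BIO_LABELS) - 1L)
  prev <- c("BOS", labels[-length(labels)])
  st <- paste(prev, labels, sep = "|")
  match(st, crf_states(2)$states) - 1L
}

#' Train a linear-chain CRF tagger
#'
#' Trains a BIO sequence labeler by penalized maximum likelihood (L-BFGS,
#' Gaussian prior). Order-2 models are realized by expanding labels to
#' consecutive-pair states and training a first-order chain over them.
#' Backward parsing reverses every token and label sequence before training
#' (labels are re-encoded so runs stay valid BIO) and re-reverses at decode
#' time. Training is deterministic for fixed data order.
#'
#' @param sequences list of `list(features = <list of character vectors>,
#'   labels = <B/I/O character vector>)`
#' @param order 1 or 2
#' @param direction "forward" or "backward"
#' @param sigma2 Gaussian prior variance (L2 regularization), default 1
#' @param maxit optimizer iteration cap, default 500
#' @param seed recorded in the training metadata (training itself is
#'   deterministic)
#' @param feature_config the [feature_config()] the features were built with
#' @return object of class `crf_model`
#' @export
train_crf <- function(sequences, order = 1, direction = c("forward", "backward"),
                      sigma2 = 1, maxit = 500L, seed = 42L,
                      feature_config = NULL) {
  direction <- match.arg(direction)
  if (length(sequences) == 0) stop("cannot train on an empty corpus")
  for (s in sequences) {
    if (length(s$features) != length(s$labels))
      stop("features and labels differ in length")
    if (!valid_bio(s$labels)) stop("invalid BIO label sequence in training data")
  }
  sequences <- sequences[vapply(sequences, function(s) length(s$labels) > 0, TRUE)]
  if (direction == "backward") {
    sequences <- lapply(sequences, function(s)
      list(features = rev(s$features), labels = flip_bio(rev(s$labels))))
  }
  sp <- crf_states(order)
  S <- length(sp$states)
  feat_names <- unique(unlist(lapply(sequences, function(s) unlist(s$features))))
  n_feat <- length(feat_names)
  data <- lapply(sequences, function(s) {
    list(feats = lapply(s$features, function(f) match(f, feat_names) - 1L),
         y = labels_to_states(s$labels, order))
  })
  npar <- n_feat * S + S * S + S
  cache <- new.env()
  cache$par <- NULL
  evalfn <- function(par) {
    r <- crf_nll_grad_cpp(par, data, n_feat, sp$trans_allowed, sp$init_allowed,
                          sigma2)
    cache$par <- par
    cache$grad <- r$grad
    r$nll
  }
  gradfn <- function(par) {
    if (!identical(par, cache$par)) evalfn(par)
    cache$grad
  }
  opt <- stats::optim(numeric(npar), evalfn, gradfn, method = "L-BFGS-B",
                      control = list(maxit = as.integer(maxit), factr = 1e8))
  structure(list(order = order, direction = direction,
                 states = sp$states, cur_label = sp$cur,
                 trans_allowed = sp$trans_allowed, init_allowed = sp$init_allowed,
                 feat_names = feat_names, theta = opt$par,
                 model_id = sprintf("crf-o%d-%s", order, substr(direction, 1, 1)),
                 training_meta = list(iterations = maxit, sigma2 = sigma2,
                                      seed = seed, nll = opt$value,
                                      convergence = opt$convergence,
                                      n_sequences = length(sequences),
                                      n_features = n_feat),
                 feature_config = feature_config,
                 version = as.character(utils::packageVersion("chemtagr"))),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model %s: order %d, %s parsing, %d features, %d sequences>\n",
              x$model_id, x$order, x$direction,
              x$training_meta$n_features, x$training_meta$n_sequences))
  invisible(x)
}

feats_to_ids <- function(features, feat_names, S_unused = NULL) {
  lapply(features, function(f) {
    id <- match(f, feat_names) - 1L
    id[!is.na(id)]
  })
}

# marginal posterior probability of the labels over positions span (internal
# frame), by constrained forward recursion
span_confidence <- function(model, ids, labels_int, from, to) {
  S <- length(model$states)
  T_ <- length(ids)
  allow <- matrix(TRUE, T_, S)
  for (t in from:to)
    allow[t, ] <- model$cur_label == BIO_LABELS[labels_int[t] + 1L]
  lz_c <- crf_logz_cpp(model$theta, ids, length(model$feat_names),
                       model$trans_allowed, model$init_allowed, allow)
  lz <- crf_logz_cpp(model$theta, ids, length(model$feat_names),
                     model$trans_allowed, model$init_allowed,
                     matrix(TRUE, T_, S))
  min(1, exp(lz_c - lz))
}

#' Decode a token sequence with a trained CRF
#'
#' Viterbi-best labeling, projected to BIO for order-2 models, then decoded
#' into span annotations. Each annotation's confidence is the marginal
#' posterior probability of its exact label subsequence over its span,
#' computed by constrained forward recursion, so it always lies in \[0, 1\].
#'
#' @param model a [train_crf()] model
#' @param tokens token data frame carrying attributes `doc_id`, `section`,
#'   `sect_text`
#' @param features feature list built with the model's configuration
#' @return `chem_annotations` with the model id as source; the predicted BIO
#'   labels are attached as attribute `"labels"`
#' @export
decode <- function(model, tokens, features) {
  n <- nrow(tokens)
  doc_id <- attr(tokens, "doc_id"); section <- attr(tokens, "section")
  sect_text <- attr(tokens, "sect_text")
  if (n == 0) return(empty_annotations())
  backward <- model$direction == "backward"
  feats <- if (backward) rev(features) else features
  ids <- feats_to_ids(feats, model$feat_names)
  path <- crf_viterbi_cpp(model$theta, ids, length(model$feat_names),
                          model$trans_allowed, model$init_allowed)
  labels_internal <- model$cur_label[path + 1L]
  labels_int <- match(labels_internal, BIO_LABELS) - 1L

  # entity runs in the internal frame
  inside <- labels_internal != "O"
  prev <- c(FALSE, inside[-n])
  run_start <- which(inside & !prev)
  anns <- empty_annotations()
  confs <- numeric(0)
  spans <- list()
  for (s in run_start) {
    e <- s
    while (e < n && inside[e + 1L]) e <- e + 1L
    confs <- c(confs, span_confidence(model, ids, labels_int, s, e))
    spans[[length(spans) + 1L]] <- c(s, e)
  }
  # map back to the original token order
  labels_orig <- if (backward) flip_bio(rev(labels_internal)) else labels_internal
  if (length(spans) > 0) {
    orig <- lapply(spans, function(se) {
      if (backward) c(n - se[2] + 1L, n - se[1] + 1L) else se
    })
    s_tok <- vapply(orig, `[[`, 0L, 1L)
    e_tok <- vapply(orig, `[[`, 0L, 2L)
    ord <- order(s_tok)
    s_off <- tokens$start[s_tok[ord]]
    e_off <- tokens$end[e_tok[ord]]
    anns <- annotations(rep(doc_id, length(ord)), rep(section, length(ord)),
                        s_off, e_off,
                        substr(rep(sect_text, length(ord)), s_off + 1L, e_off),
                        confidence = confs[ord], source = model$model_id)
  }
  attr(anns, "labels") <- labels_orig
  anns
}

#' Decode every sequence of a preprocessed corpus
#'
#' @param model a `crf_model`
#' @param seqs list of token sequences from [preprocess_corpus()]
#' @param lexicon optional lexicon for dictionary features
#' @return `chem_annotations` over the whole corpus
#' @export
decode_corpus <- function(model, seqs, lexicon = NULL) {
  config <- model$feature_config
  if (is.null(config)) config <- feature_config()
  out <- lapply(seqs, function(toks)
    decode(model, toks, build_features(toks, lexicon, config)))
  res <- do.call(rbind, c(list(empty_annotations()), out))
  class(res) <- c("chem_annotations", "data.frame")
  attr(res, "labels") <- NULL
  rownames(res) <- NULL
  res
}

#' Harmonize annotation sets from multiple models
#'
#' Annotations that overlap nothing from any other set are all kept. Where
#' annotations intersect (same document, same section, character-interval
#' intersection), resolution is greedy by priority — confidence descending,
#' then earlier start, longer span, and lexicographically smaller source —
#' accepting an annotation only if it overlaps no already-accepted one. The
#' output is therefore non-overlapping, and the operation is idempotent.
#'
#' @param sets list of `chem_annotations` (each internally non-overlapping)
#' @return harmonized `chem_annotations`
#' @export
harmonize <- function(sets) {
  if (inherits(sets, "data.frame")) sets <- list(sets)
  all <- do.call(rbind, c(list(empty_annotations()), sets))
  if (nrow(all) == 0) return(empty_annotations())
  ord <- order(-all$confidence, all$start, -(all$end - all$start), all$source)
  all <- all[ord, , drop = FALSE]
  keep <- logical(nrow(all))
  acc <- list()
  for (i in seq_len(nrow(all))) {
    key <- paste0(all$doc_id[i], "\r", all$section[i])
    iv <- acc[[key]]
    s <- all$start[i]; e <- all$end[i]
    clash <- !is.null(iv) && any(iv[, 1] < e & s < iv[, 2])
    if (!clash) {
      keep[i] <- TRUE
      acc[[key]] <- rbind(iv, c(s, e))
    }
  }
  out <- all[keep, , drop = FALSE]
  out <- out[order(out$doc_id, out$section, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chem_annotations", "data.frame")
  out
}

#' Save a CRF model to disk
#' @param model `crf_model`
#' @param path destination file
#' @export
save_crf <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a CRF model saved by [save_crf()]
#' @param path model file
#' @return `crf_model`
#' @export
load_crf <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "crf_model")) stop("not a crf_model file: ", path)
  m
}
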