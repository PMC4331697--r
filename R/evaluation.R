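MATCH_MODES <- c("exact", "left", "right", "shared", "overlap")

#' Test whether two spans match under a given strategy
#'
#' `exact` requires both indices to agree, `left` the starts, `right` the
#' ends, `shared` either index, and `overlap` any interval intersection.
#' Spans in different documents or sections never match.
#'
#' @param pred,gold single annotation rows (1-row data frames or lists with
#'   doc_id, section, start, end)
#' @param mode one of exact, left, right, shared, overlap
#' @return logical
#' @export
span_match <- function(pred, gold, mode = "exact") {
  mode <- match.arg(mode, MATCH_MODES)
  if (pred$doc_id != gold$doc_id || pred$section != gold$section) return(FALSE)
  switch(mode,
         exact = pred$start == gold$start && pred$end == gold$end,
         left = pred$start == gold$start,
         right = pred$end == gold$end,
         shared = pred$start == gold$start || pred$end == gold$end,
         overlap = pred$start < gold$end && gold$start < pred$end)
}

#' Harmonic-mean F-measure from precision and recall
#' @param precision,recall numeric (any common scale)
#' @return F1 on the same scale; 0 when both inputs are 0
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

new_eval_result <- function(tp, fp, fn, mode, per_class_recall = NULL) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = 100 * precision, recall = 100 * recall,
                 f1 = f_measure(100 * precision, 100 * recall),
                 mode = mode, per_class_recall = per_class_recall),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s matching: TP=%d FP=%d FN=%d  P=%.2f%% R=%.2f%% F1=%.2f%%\n",
              x$mode, x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  if (!is.null(x$per_class_recall)) {
    cat("per-class recall (%):\n")
    for (cl in names(x$per_class_recall))
      cat(sprintf("  %-14s %.2f\n", cl, x$per_class_recall[[cl]]))
  }
  invisible(x)
}

dedup_spans <- function(anns) {
  if (nrow(anns) == 0) return(anns)
  key <- paste(anns$doc_id, anns$section, anns$start, anns$end)
  ord <- order(key, -anns$confidence)
  anns <- anns[ord, , drop = FALSE]
  anns <- anns[!duplicated(key[ord]), , drop = FALSE]
  rownames(anns) <- NULL
  anns
}

mode_candidates <- function(p, g, mode) {
  # candidate (pred, gold) index pairs under `mode` within one doc+section
  res <- list()
  for (i in seq_len(nrow(p))) {
    hit <- switch(mode,
      exact = which(g$start == p$start[i] & g$end == p$end[i]),
      left = which(g$start == p$start[i]),
      right = which(g$end == p$end[i]),
      shared = which(g$start == p$start[i] | g$end == p$end[i]),
      overlap = which(g$start < p$end[i] & p$start[i] < g$end))
    if (length(hit) > 0)
      res[[length(res) + 1L]] <- cbind(pred = i, gold = hit)
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

#' Evaluate span predictions against gold annotations
#'
#' One-to-one greedy matching per document and section: exact matches are
#' resolved first, then remaining candidates under the requested mode,
#' ordered by earliest start and longest overlap. TP is the number of
#' matched pairs, FP the unmatched predictions (identical predicted spans
#' are merged first), FN the unmatched gold annotations. Precision, recall
#' and F1 are reported as percentages.
#'
#' @param preds predicted `chem_annotations`
#' @param golds gold `chem_annotations`
#' @param mode matching strategy, see [span_match()]
#' @return `eval_result`
#' @export
evaluate <- function(preds, golds, mode = "exact") {
  mode <- match.arg(mode, MATCH_MODES)
  preds <- dedup_spans(preds)
  tp <- 0L
  groups <- unique(rbind(data.frame(doc_id = preds$doc_id, section = preds$section),
                         data.frame(doc_id = golds$doc_id, section = golds$section)))
  for (gi in seq_len(nrow(groups))) {
    p <- preds[preds$doc_id == groups$doc_id[gi] &
                 preds$section == groups$section[gi], , drop = FALSE]
    g <- golds[golds$doc_id == groups$doc_id[gi] &
                 golds$section == groups$section[gi], , drop = FALSE]
    if (nrow(p) == 0 || nrow(g) == 0) next
    used_p <- logical(nrow(p)); used_g <- logical(nrow(g))
    for (stage_mode in unique(c("exact", mode))) {
      cand <- mode_candidates(p, g, stage_mode)
      if (is.null(cand)) next
      ov <- pmin(p$end[cand[, 1]], g$end[cand[, 2]]) -
        pmax(p$start[cand[, 1]], g$start[cand[, 2]])
      cand <- cand[order(p$start[cand[, 1]], -ov), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_p[i] && !used_g[j]) {
          used_p[i] <- TRUE; used_g[j] <- TRUE; tp <- tp + 1L
        }
      }
    }
  }
  new_eval_result(tp, nrow(preds) - tp, nrow(golds) - tp, mode)
}

#' Evaluate document-indexing predictions
#'
#' Per-document set comparison of mention strings: TP is the size of the
#' intersection of predicted and gold string sets, aggregated over documents.
#'
#' @param preds data frame doc_id, text (predicted distinct mentions)
#' @param golds data frame doc_id, text (gold distinct mentions)
#' @return `eval_result` with mode "cdi"
#' @export
evaluate_cdi <- function(preds, golds) {
  pk <- unique(paste(preds$doc_id, preds$text, sep = "\r"))
  gk <- unique(paste(golds$doc_id, golds$text, sep = "\r"))
  tp <- length(intersect(pk, gk))
  new_eval_result(tp, length(pk) - tp, length(gk) - tp, "cdi")
}

#' Per-class recall of unclassed predictions
#'
#' The tagger predicts a single merged chemical class, so class-based
#' precision is undefined; recall per gold class is the fraction of gold
#' annotations of that class matched by any prediction under `mode`.
#'
#' @param preds predicted `chem_annotations`
#' @param golds gold `chem_annotations` carrying classes
#' @param mode matching strategy
#' @return named numeric vector, recall in % per class present in the gold
#' @export
class_recall <- function(preds, golds, mode = "exact") {
  mode <- match.arg(mode, MATCH_MODES)
  if (nrow(golds) == 0) return(setNames(numeric(0), character(0)))
  matched <- logical(nrow(golds))
  for (i in seq_len(nrow(golds))) {
    p <- preds[preds$doc_id == golds$doc_id[i] &
                 preds$section == golds$section[i], , drop = FALSE]
    if (nrow(p) == 0) next
    g <- golds[i, ]
    matched[i] <- switch(mode,
      exact = any(p$start == g$start & p$end == g$end),
      left = any(p$start == g$start),
      right = any(p$end == g$end),
      shared = any(p$start == g$start | p$end == g$end),
      overlap = any(p$start < g$end & g$start < p$end))
  }
  cls <- ifelse(is.na(golds$cls), "UNCLASSIFIED", golds$cls)
  out <- tapply(matched, cls, function(x) 100 * mean(x))
  setNames(as.numeric(out), names(out))
}

#' Iterative feature-group elimination
#'
#' Starting from `config`, each round trains one model per candidate
#' single-group removal and evaluates exact F1 on the development corpus.
#' The group whose removal yields the largest F1 improvement over the
#' current configuration is eliminated; the protocol stops when no removal
#' improves F1. The token group is protected from removal by default.
#'
#' @param train_docs,train_gold training corpus
#' @param dev_docs,dev_gold development corpus
#' @param lexicon `chem_lexicon` for dictionary features
#' @param config starting [feature_config()]
#' @param protected groups never removed
#' @param order CRF order used throughout
#' @param tagger linguistic tagger
#' @param ... passed to [train_crf()]
#' @return list with `final_config` and a per-round report of candidate
#'   P/R/F1 tables
#' @export
iterative_feature_elimination <- function(train_docs, train_gold,
                                          dev_docs, dev_gold, lexicon = NULL,
                                          config = feature_config(),
                                          protected = "token", order = 1,
                                          tagger = default_tagger(), ...) {
  if (nrow(train_docs) == 0 || nrow(dev_docs) == 0)
    stop("degenerate corpus: no documents")
  train_seqs <- preprocess_corpus(train_docs, tagger)
  dev_seqs <- preprocess_corpus(dev_docs, tagger)
  score_config <- function(cfg) {
    td <- make_training_data(train_seqs, train_gold, lexicon, cfg)
    model <- train_crf(td, order = order, feature_config = cfg, ...)
    preds <- decode_corpus(model, dev_seqs, lexicon)
    evaluate(preds, dev_gold, "exact")
  }
  rounds <- list()
  current <- config
  base <- score_config(current)
  repeat {
    candidates <- setdiff(current$enabled_groups, protected)
    report <- data.frame(group = character(), precision = numeric(),
                         recall = numeric(), f1 = numeric(),
                         stringsAsFactors = FALSE)
    for (grp in candidates) {
      r <- score_config(disable_groups(current, grp))
      report <- rbind(report, data.frame(group = grp, precision = r$precision,
                                         recall = r$recall, f1 = r$f1,
                                         stringsAsFactors = FALSE))
    }
    rounds[[length(rounds) + 1L]] <- list(
      baseline = c(precision = base$precision, recall = base$recall, f1 = base$f1),
      candidates = report)
    if (nrow(report) == 0 || max(report$f1) <= base$f1) break
    winner <- report$group[which.max(report$f1)]
    current <- disable_groups(current, winner)
    base <- score_config(current)
  }
  list(final_config = current, rounds = rounds,
       final = c(precision = base$precision, recall = base$recall, f1 = base$f1))
}
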