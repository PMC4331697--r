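#' Remove annotations with unbalanced parentheses
#'
#' Counts all round, square and curly brackets in each annotation's text and
#' removes the annotation when the total is odd — a clear model boundary
#' mistake. Surviving annotations are untouched.
#'
#' @param anns `chem_annotations`
#' @return filtered `chem_annotations`
#' @export
parentheses_filter <- function(anns) {
  if (nrow(anns) == 0) return(anns)
  counts <- nchar(gsub("[^][(){}]", "", anns$text))
  out <- anns[counts %% 2L == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Schwartz-Hearst style long-form search: match short-form characters
# right-to-left against the text before the parenthesis; the first character
# must match at a word start. Returns the 1-based start of the long form
# within `lf`, or NA.
find_long_form_start <- function(sf, lf) {
  s_chars <- strsplit(tolower(sf), "")[[1]]
  l_chars <- strsplit(tolower(lf), "")[[1]]
  si <- length(s_chars); li <- length(l_chars)
  while (si >= 1) {
    ch <- s_chars[si]
    if (!grepl("[[:alnum:]]", ch)) { si <- si - 1; next }
    repeat {
      if (li < 1) return(NA_integer_)
      ok <- l_chars[li] == ch &&
        !(si == 1 && li > 1 && grepl("[[:alnum:]]", l_chars[li - 1]))
      if (ok) break
      li <- li - 1
    }
    si <- si - 1; li <- li - 1
  }
  li + 1L
}

#' Detect abbreviation definitions in a sentence
#'
#' Candidate short forms are parenthesized strings of 2-10 characters, at
#' most two words, containing at least one letter, with an alphanumeric
#' first character. The long form is searched right-to-left before the
#' parenthesis, matching each short-form character case-insensitively, with
#' the first character anchored at a word start. Chemistry short forms often
#' reorder letters ("EtOH" for ethanol), so when the strict character match
#' fails, the token immediately preceding the parenthesis is accepted as the
#' long form if it shares the short form's initial letter.
#'
#' @param text sentence text
#' @param offset 0-based offset of the sentence within its section
#' @param doc_id,section coordinates recorded on the output
#' @return data frame with short/long form spans (0-based, section frame)
#' @export
detect_abbreviations <- function(text, offset = 0L, doc_id = NA_character_,
                                 section = NA_character_) {
  empty <- data.frame(doc_id = character(), section = character(),
                      short_start = integer(), short_end = integer(),
                      short_text = character(), long_start = integer(),
                      long_end = integer(), long_text = character(),
                      stringsAsFactors = FALSE)
  m <- gregexpr("\\(([^()]*)\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  out <- empty
  for (k in seq_along(m)) {
    open <- as.integer(m[k])                      # 1-based "(" position
    len <- attr(m, "match.length")[k]
    sf <- substr(text, open + 1L, open + len - 2L)
    if (nchar(sf) < 2 || nchar(sf) > 10) next
    if (length(strsplit(trimws(sf), "\\s+")[[1]]) > 2) next
    if (!grepl("[[:alpha:]]", sf)) next
    if (!grepl("^[[:alnum:]]", sf)) next

    before <- substr(text, 1L, open - 1L)
    before <- sub("\\s+$", "", before)
    if (!nzchar(before)) next
    start <- find_long_form_start(sf, before)
    long <- NA_character_
    if (!is.na(start)) {
      long <- substr(before, start, nchar(before))
      n_words <- length(strsplit(long, "\\s+")[[1]])
      if (n_words > min(nchar(sf) + 5L, 2L * nchar(sf)) ||
          nchar(long) <= nchar(sf)) { long <- NA_character_; start <- NA_integer_ }
    }
    if (is.na(start)) {
      # adapted fallback: single preceding token sharing the initial letter
      tok <- sub("^.*\\s", "", before)
      if (nzchar(tok) && nchar(tok) > nchar(sf) &&
          tolower(substr(tok, 1, 1)) == tolower(substr(sf, 1, 1))) {
        start <- nchar(before) - nchar(tok) + 1L
        long <- tok
      } else next
    }
    out <- rbind(out, data.frame(
      doc_id = doc_id, section = section,
      short_start = offset + open, short_end = offset + open + nchar(sf),
      short_text = sf,
      long_start = offset + start - 1L,
      long_end = offset + start - 1L + nchar(long),
      long_text = long, stringsAsFactors = FALSE))
  }
  out
}

#' Detect abbreviation pairs over a whole corpus
#' @param docs abstracts data frame
#' @return row-bound [detect_abbreviations()] results over all sentences
#' @export
detect_abbreviations_corpus <- function(docs) {
  res <- list()
  for (i in seq_len(nrow(docs))) {
    for (section in c("T", "A")) {
      txt <- if (section == "T") docs$title[i] else docs$abstract[i]
      sents <- split_sentences(txt, docs$doc_id[i], section)
      for (k in seq_len(nrow(sents)))
        res[[length(res) + 1L]] <- detect_abbreviations(
          sents$text[k], sents$start[k], docs$doc_id[i], section)
    }
  }
  if (length(res) == 0)
    return(detect_abbreviations(""))
  do.call(rbind, res)
}

span_overlaps <- function(anns, doc_id, section, start, end) {
  which(anns$doc_id == doc_id & anns$section == section &
          anns$start < end & start < anns$end)
}

#' Propagate annotations between abbreviation short and long forms
#'
#' For every detected pair: if exactly one form overlaps an annotation, the
#' other form's full span is added as a new annotation with the existing
#' confidence and source `"abbrev"`. If an annotation only partially covers a
#' form, its boundaries are expanded to include the form's full span.
#' Duplicate spans are merged keeping the maximum confidence. Annotations are
#' never removed.
#'
#' @param anns `chem_annotations`
#' @param pairs pairs from [detect_abbreviations_corpus()]
#' @param docs abstracts data frame, used to re-slice expanded spans
#' @return augmented `chem_annotations`
#' @export
abbreviation_resolution <- function(anns, pairs, docs) {
  if (nrow(pairs) == 0 || nrow(anns) == 0) return(anns)
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    forms <- list(short = c(p$short_start, p$short_end),
                  long = c(p$long_start, p$long_end))
    ov <- lapply(forms, function(f)
      span_overlaps(anns, p$doc_id, p$section, f[1], f[2]))
    # expand partial coverage to the form's full span
    for (f in names(forms)) {
      for (i in ov[[f]]) {
        s <- min(anns$start[i], forms[[f]][1])
        e <- max(anns$end[i], forms[[f]][2])
        if (s != anns$start[i] || e != anns$end[i]) {
          anns$start[i] <- s; anns$end[i] <- e
          sect <- section_text(docs, anns$doc_id[i], anns$section[i])
          anns$text[i] <- substr(sect, s + 1L, e)
        }
      }
    }
    annotated <- vapply(ov, function(x) length(x) > 0, TRUE)
    if (sum(annotated) == 1) {
      have <- names(forms)[annotated]
      miss <- names(forms)[!annotated]
      conf <- max(anns$confidence[ov[[have]]])
      sect <- section_text(docs, p$doc_id, p$section)
      f <- forms[[miss]]
      anns <- rbind(anns, annotations(p$doc_id, p$section, f[1], f[2],
                                      substr(sect, f[1] + 1L, f[2]),
                                      confidence = conf, source = "abbrev"))
    }
  }
  # merge duplicate spans, keeping max confidence
  key <- paste(anns$doc_id, anns$section, anns$start, anns$end)
  ord <- order(key, -anns$confidence)
  anns <- anns[ord, , drop = FALSE]
  anns <- anns[!duplicated(key[ord]), , drop = FALSE]
  anns <- anns[order(anns$doc_id, anns$section, anns$start), , drop = FALSE]
  rownames(anns) <- NULL
  class(anns) <- c("chem_annotations", "data.frame")
  anns
}

#' Build a log-odds exclusion list from gold and predicted annotations
#'
#' For each distinct lowercased predicted mention, counts exact-span true
#' positives (TPc) and false positives (FPc) and scores it as
#' `ln((TPc + 0.5) / (FPc + 0.5))` (Haldane-smoothed log odds). The mention
#' enters the list iff its score is below `theta` and it appeared at least
#' `min_fp` times as a false positive.
#'
#' @param gold gold `chem_annotations`
#' @param predicted predicted `chem_annotations` over the same documents
#' @param theta log-odds threshold (default 0.3)
#' @param min_fp minimum false-positive count (default 2)
#' @return object of class `exclusion_list`
#' @export
build_exclusion_list <- function(gold, predicted, theta = 0.3, min_fp = 2L) {
  if (nrow(predicted) == 0)
    return(structure(list(entries = character(0), theta = theta,
                          min_fp = min_fp), class = "exclusion_list"))
  gold_key <- paste(gold$doc_id, gold$section, gold$start, gold$end)
  pred_key <- paste(predicted$doc_id, predicted$section, predicted$start,
                    predicted$end)
  is_tp <- pred_key %in% gold_key
  mention <- tolower(predicted$text)
  tpc <- tapply(is_tp, mention, sum)
  fpc <- tapply(!is_tp, mention, sum)
  score <- log((tpc + 0.5) / (fpc + 0.5))
  entries <- names(score)[score < theta & fpc >= min_fp]
  structure(list(entries = sort(unname(entries)), theta = theta,
                 min_fp = as.integer(min_fp)), class = "exclusion_list")
}

#' @export
print.exclusion_list <- function(x, ...) {
  cat(sprintf("<exclusion_list: %d entries, theta=%g, min_fp=%d>\n",
              length(x$entries), x$theta, x$min_fp))
  invisible(x)
}

#' Remove annotations whose mention is on an exclusion list
#'
#' Matching is case-insensitive; all other annotations are untouched.
#'
#' @param anns `chem_annotations`
#' @param list an `exclusion_list`
#' @return filtered `chem_annotations`
#' @export
apply_exclusion_list <- function(anns, list) {
  if (nrow(anns) == 0 || length(list$entries) == 0) return(anns)
  out <- anns[!(tolower(anns$text) %in% list$entries), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tune exclusion-list thresholds by 10-fold cross-validation
#'
#' Documents are partitioned into folds by a seeded shuffle. For every grid
#' point, the list is built on 9/10 of the documents and the change in exact
#' F1 from applying it is measured on the held-out 1/10; the grid point with
#' the largest mean improvement wins. Ties prefer the smaller resulting list
#' (then lower theta, then higher min_fp).
#'
#' @param gold gold annotations of the development corpus
#' @param predicted model predictions on the same corpus
#' @param theta_grid,min_fp_grid candidate thresholds
#' @param folds number of folds (default 10)
#' @param seed shuffle seed
#' @return list with `theta`, `min_fp`, `mean_delta_f1` and the full grid
#' @export
tune_exclusion_thresholds <- function(gold, predicted, theta_grid = 0.3,
                                      min_fp_grid = 2L, folds = 10L,
                                      seed = 42L) {
  doc_ids <- unique(c(gold$doc_id, predicted$doc_id))
  if (length(doc_ids) < folds)
    stop("fewer documents (", length(doc_ids), ") than folds (", folds, ")")
  set.seed(seed)
  shuffled <- sample(doc_ids)
  fold_of <- setNames(rep_len(seq_len(folds), length(shuffled)), shuffled)
  grid <- expand.grid(theta = theta_grid, min_fp = min_fp_grid)
  grid$mean_delta_f1 <- NA_real_
  grid$n_entries <- NA_integer_
  for (gi in seq_len(nrow(grid))) {
    deltas <- numeric(folds)
    for (f in seq_len(folds)) {
      test_docs <- names(fold_of)[fold_of == f]
      g_tr <- gold[!gold$doc_id %in% test_docs, , drop = FALSE]
      p_tr <- predicted[!predicted$doc_id %in% test_docs, , drop = FALSE]
      g_te <- gold[gold$doc_id %in% test_docs, , drop = FALSE]
      p_te <- predicted[predicted$doc_id %in% test_docs, , drop = FALSE]
      xl <- build_exclusion_list(g_tr, p_tr, grid$theta[gi], grid$min_fp[gi])
      base <- evaluate(p_te, g_te, "exact")$f1
      filt <- evaluate(apply_exclusion_list(p_te, xl), g_te, "exact")$f1
      deltas[f] <- filt - base
    }
    grid$mean_delta_f1[gi] <- mean(deltas)
    grid$n_entries[gi] <- length(
      build_exclusion_list(gold, predicted, grid$theta[gi], grid$min_fp[gi])$entries)
  }
  best <- order(-grid$mean_delta_f1, grid$n_entries, grid$theta, -grid$min_fp)[1]
  list(theta = grid$theta[best], min_fp = as.integer(grid$min_fp[best]),
       mean_delta_f1 = grid$mean_delta_f1[best], grid = grid)
}

#' Write an exclusion list to a text file
#'
#' One lowercased mention per line; a header comment records the thresholds.
#'
#' @param list an `exclusion_list`
#' @param path output path
#' @param source_tag free-text provenance recorded in the header
#' @export
write_exclusion_list <- function(list, path, source_tag = "unknown") {
  header <- sprintf("# exclusion list: theta=%g min_fp=%d source=%s",
                    list$theta, list$min_fp, source_tag)
  writeLines(c(header, list$entries), path, useBytes = FALSE)
  invisible(path)
}

#' Read an exclusion list written by [write_exclusion_list()]
#' @param path list file
#' @return `exclusion_list`
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  theta <- 0.3; min_fp <- 2L
  if (length(header) > 0) {
    th <- regmatches(header[1], regexpr("theta=[-0-9.eE]+", header[1]))
    mf <- regmatches(header[1], regexpr("min_fp=[0-9]+", header[1]))
    if (length(th)) theta <- as.numeric(sub("theta=", "", th))
    if (length(mf)) min_fp <- as.integer(sub("min_fp=", "", mf))
  }
  entries <- lines[!startsWith(lines, "#") & nzchar(lines)]
  structure(list(entries = entries, theta = theta, min_fp = min_fp),
            class = "exclusion_list")
}

#' Full post-processing chain
#'
#' Parentheses filter, then abbreviation resolution, then (optionally) the
#' exclusion list — in that order.
#'
#' @param anns predicted `chem_annotations`
#' @param docs abstracts data frame
#' @param exclusion optional `exclusion_list` (NULL to skip)
#' @return post-processed `chem_annotations`
#' @export
postprocess <- function(anns, docs, exclusion = NULL) {
  anns <- parentheses_filter(anns)
  pairs <- detect_abbreviations_corpus(docs)
  anns <- abbreviation_resolution(anns, pairs, docs)
  if (!is.null(exclusion)) anns <- apply_exclusion_list(anns, exclusion)
  anns
}
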