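#' Rank mention-level predictions per document
#'
#' Sorts annotations within each document by confidence descending, breaking
#' ties by section (title before abstract), then start and end ascending, and
#' assigns ranks 1..n.
#'
#' @param anns `chem_annotations` with confidences
#' @return annotations with a `rank` column, ordered by doc then rank
#' @export
rank_cem <- function(anns) {
  if (nrow(anns) == 0) {
    anns$rank <- integer(0)
    return(anns)
  }
  sec <- match(anns$section, c("T", "A"))
  ord <- order(anns$doc_id, -anns$confidence, sec, anns$start, anns$end)
  out <- anns[ord, , drop = FALSE]
  out$rank <- as.integer(stats::ave(seq_len(nrow(out)), out$doc_id,
                                    FUN = seq_along))
  rownames(out) <- NULL
  class(out) <- c("chem_annotations", "data.frame")
  out
}

#' Rank document-indexing predictions per document
#'
#' Groups annotations by exact surface string within each document, keeps one
#' entry per string with the maximum confidence over the group, and ranks as
#' in [rank_cem()]. String comparison is case-sensitive.
#'
#' @param anns `chem_annotations` with confidences
#' @return data frame doc_id, text, rank, confidence (plus section/start of
#'   the best-scoring occurrence, used for tie-breaking)
#' @export
rank_cdi <- function(anns) {
  if (nrow(anns) == 0)
    return(data.frame(doc_id = character(), text = character(),
                      section = character(), start = integer(),
                      confidence = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  sec <- match(anns$section, c("T", "A"))
  ord <- order(anns$doc_id, anns$text, -anns$confidence, sec, anns$start)
  a <- anns[ord, , drop = FALSE]
  key <- paste(a$doc_id, a$text, sep = "\r")
  a <- a[!duplicated(key), , drop = FALSE]
  sec <- match(a$section, c("T", "A"))
  ord2 <- order(a$doc_id, -a$confidence, sec, a$start, a$end)
  a <- a[ord2, , drop = FALSE]
  out <- data.frame(doc_id = a$doc_id, text = a$text, section = a$section,
                    start = a$start, confidence = a$confidence,
                    stringsAsFactors = FALSE)
  out$rank <- as.integer(stats::ave(seq_len(nrow(out)), out$doc_id,
                                    FUN = seq_along))
  rownames(out) <- NULL
  out
}
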