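#' @useDynLib chemtagr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rbinom rmultinom runif rnbinom setNames
#' @importFrom utils head tail
NULL

#' Annotation classes recognized in CHEMDNER-style corpora
#' @export
ANNOTATION_CLASSES <- c("SYSTEMATIC", "TRIVIAL", "ABBREVIATION", "FAMILY",
                        "IDENTIFIER", "FORMULA", "MULTIPLE", "UNCLASSIFIED")

#' Construct an annotation table
#'
#' Annotations are plain data frames with one row per entity mention. Offsets
#' are 0-based, end-exclusive Unicode code-point positions, counted
#' independently within the title (`section = "T"`) and abstract
#' (`section = "A"`).
#'
#' @param doc_id character document identifiers
#' @param section "T" (title) or "A" (abstract)
#' @param start,end integer offsets, 0-based, end-exclusive
#' @param text surface strings
#' @param cls entity class, one of [ANNOTATION_CLASSES] or NA
#' @param confidence numeric in \[0, 1\]
#' @param source provenance tag (model id, "abbrev", "gold")
#' @return data frame of class `chem_annotations`
#' @export
annotations <- function(doc_id = character(), section = character(),
                        start = integer(), end = integer(),
                        text = character(), cls = NA_character_,
                        confidence = 1, source = "gold") {
  n <- length(doc_id)
  df <- data.frame(doc_id = as.character(doc_id),
                   section = as.character(section),
                   start = as.integer(start), end = as.integer(end),
                   text = as.character(text),
                   cls = rep_len(as.character(cls), n),
                   confidence = rep_len(as.numeric(confidence), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(!df$section %in% c("T", "A")))
      stop("section must be 'T' or 'A'")
    if (any(df$start < 0L) || any(df$end <= df$start))
      stop("annotation offsets must satisfy 0 <= start < end")
    if (any(df$confidence < 0 | df$confidence > 1))
      stop("confidence must lie in [0, 1]")
  }
  class(df) <- c("chem_annotations", "data.frame")
  df
}

empty_annotations <- function() annotations()

#' Read a CHEMDNER-style abstracts file
#'
#' One record per line: `doc_id TAB title TAB abstract`. Tabs beyond the third
#' field are treated as literal characters of the abstract.
#'
#' @param path path to a UTF-8 tab-separated file
#' @return data frame with columns doc_id, title, abstract, in input order
#' @export
read_abstracts <- function(path) {
  if (!file.exists(path)) stop("abstracts file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(doc_id = character(), title = character(),
                      abstract = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad) > 0)
    stop("malformed abstracts line ", bad[1], ": expected >= 3 tab-separated fields")
  docs <- data.frame(
    doc_id = vapply(parts, `[[`, "", 1L),
    title = vapply(parts, `[[`, "", 2L),
    abstract = vapply(parts, function(p) paste(p[-(1:2)], collapse = "\t"), ""),
    stringsAsFactors = FALSE)
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup) > 0) stop("duplicate doc_id in abstracts file: ", dup[1])
  docs
}

#' Write an abstracts table to the tab-separated dialect
#' @param docs data frame with doc_id, title, abstract
#' @param path output path
#' @export
write_abstracts <- function(docs, path) {
  lines <- paste(docs$doc_id, docs$title, docs$abstract, sep = "\t")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

section_text <- function(docs, doc_id, section) {
  i <- match(doc_id, docs$doc_id)
  ifelse(section == "T", docs$title[i], docs$abstract[i])
}

#' Read a CHEMDNER-style annotations file
#'
#' Records are `doc_id TAB section TAB start TAB end TAB text [TAB class]`.
#' Every record is validated against the referenced document: the stored text
#' must equal the section slice `[start, end)`.
#'
#' @param path annotations file
#' @param corpus abstracts data frame (see [read_abstracts()])
#' @return `chem_annotations` data frame; gold records carry confidence 1
#' @export
read_annotations <- function(path, corpus) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_annotations())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 5L)
  if (length(bad) > 0)
    stop("malformed annotations line ", bad[1], ": expected >= 5 fields")
  doc_id <- vapply(parts, `[[`, "", 1L)
  section <- vapply(parts, `[[`, "", 2L)
  start <- as.integer(vapply(parts, `[[`, "", 3L))
  end <- as.integer(vapply(parts, `[[`, "", 4L))
  text <- vapply(parts, `[[`, "", 5L)
  cls <- vapply(parts, function(p) if (length(p) >= 6) p[[6]] else NA_character_, "")

  missing <- setdiff(doc_id, corpus$doc_id)
  if (length(missing) > 0)
    stop("annotation references unknown doc_id: ", missing[1])
  sect <- section_text(corpus, doc_id, section)
  out_of_range <- which(start < 0L | end <= start | end > nchar(sect))
  if (length(out_of_range) > 0) {
    i <- out_of_range[1]
    stop(sprintf("annotation offsets [%d,%d) outside section %s of %s",
                 start[i], end[i], section[i], doc_id[i]))
  }
  slice <- substr(sect, start + 1L, end)
  mism <- which(slice != text)
  if (length(mism) > 0) {
    i <- mism[1]
    stop(sprintf("annotation text mismatch in %s %s [%d,%d): file has \"%s\" but slice is \"%s\"",
                 doc_id[i], section[i], start[i], end[i], text[i], slice[i]))
  }
  unknown <- !is.na(cls) & !(cls %in% ANNOTATION_CLASSES)
  if (any(unknown)) {
    warning("unknown annotation class(es) mapped to UNCLASSIFIED: ",
            paste(unique(cls[unknown]), collapse = ", "))
    cls[unknown] <- "UNCLASSIFIED"
  }
  annotations(doc_id, section, start, end, text, cls,
              confidence = 1, source = "gold")
}

#' Write annotations in the tab-separated gold dialect
#' @param anns `chem_annotations`
#' @param path output path
#' @export
write_annotations <- function(anns, path) {
  if (nrow(anns) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cls <- ifelse(is.na(anns$cls), "UNCLASSIFIED", anns$cls)
  lines <- paste(anns$doc_id, anns$section, anns$start, anns$end,
                 anns$text, cls, sep = "\t")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Encode gold spans over a token sequence as BIO labels
#'
#' A token fully inside a gold span is labeled B if it starts the span, I
#' otherwise; all remaining tokens are O. Gold boundaries falling strictly
#' inside a token are snapped outward to the covering token boundaries (with a
#' warning), so no training signal is lost.
#'
#' @param tokens token data frame (section-level `start`, `end`, `surface`)
#' @param gold annotations restricted to the same document section
#' @return character vector of labels, one per token
#' @export
encode_bio <- function(tokens, gold) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  if (is.null(gold) || nrow(gold) == 0 || n == 0) return(labels)
  g <- gold[order(gold$start), , drop = FALSE]
  if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
    stop("overlapping gold spans cannot be BIO-encoded")
  for (i in seq_len(nrow(g))) {
    s <- g$start[i]; e <- g$end[i]
    # tokens intersecting the span
    idx <- which(tokens$end > s & tokens$start < e)
    if (length(idx) == 0) next
    if (tokens$start[idx[1]] < s || tokens$end[idx[length(idx)]] > e)
      warning(sprintf("gold span [%d,%d) snapped outward to token boundaries [%d,%d)",
                      s, e, tokens$start[idx[1]], tokens$end[idx[length(idx)]]))
    labels[idx[1]] <- "B"
    if (length(idx) > 1) labels[idx[-1]] <- "I"
  }
  labels
}

#' Decode BIO labels over tokens into span annotations
#'
#' Each maximal B(I)* run becomes one annotation. An I directly following O is
#' repaired as B, with a warning.
#'
#' @param tokens token data frame with section-level offsets
#' @param labels character vector of B/I/O labels
#' @param doc_id,section coordinates of the sequence
#' @param sect_text full section text used to slice surface strings
#' @param confidence,source annotation metadata
#' @return `chem_annotations`
#' @export
decode_bio <- function(tokens, labels, doc_id, section, sect_text,
                       confidence = 1, source = "model") {
  stopifnot(nrow(tokens) == length(labels))
  n <- length(labels)
  if (n == 0) return(empty_annotations())
  prev <- c("O", labels[-n])
  orphan <- labels == "I" & prev == "O"
  if (any(orphan)) {
    warning("I label without preceding B repaired as B")
    labels[orphan] <- "B"
  }
  starts <- which(labels == "B")
  if (length(starts) == 0) return(empty_annotations())
  ends <- vapply(starts, function(i) {
    j <- i
    while (j < n && labels[j + 1L] == "I") j <- j + 1L
    j
  }, 0L)
  s <- tokens$start[starts]
  e <- tokens$end[ends]
  annotations(rep(doc_id, length(starts)), rep(section, length(starts)),
              s, e, substr(rep(sect_text, length(s)), s + 1L, e),
              cls = NA_character_, confidence = confidence, source = source)
}

check_ranks <- function(doc_id, rank) {
  for (d in unique(doc_id)) {
    r <- sort(rank[doc_id == d])
    if (!identical(as.integer(r), seq_len(length(r))))
      stop("ranks not contiguous from 1 within document ", d)
  }
  invisible(TRUE)
}

#' Write mention-level (CEM) predictions
#'
#' Lines are `doc_id TAB section:start:end TAB rank TAB confidence`, with the
#' confidence printed to six decimals. Ranks must be contiguous from 1 within
#' each document.
#'
#' @param ranked annotations with `rank` column (see [rank_cem()])
#' @param path output path
#' @export
write_cem <- function(ranked, path) {
  if (nrow(ranked) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  check_ranks(ranked$doc_id, ranked$rank)
  lines <- sprintf("%s\t%s:%d:%d\t%d\t%.6f", ranked$doc_id, ranked$section,
                   ranked$start, ranked$end, ranked$rank, ranked$confidence)
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Write document-indexing (CDI) predictions
#'
#' Lines are `doc_id TAB mention TAB rank TAB confidence`.
#'
#' @param ranked data frame with doc_id, text, rank, confidence
#' @param path output path
#' @export
write_cdi <- function(ranked, path) {
  if (nrow(ranked) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  check_ranks(ranked$doc_id, ranked$rank)
  lines <- sprintf("%s\t%s\t%d\t%.6f", ranked$doc_id, ranked$text,
                   ranked$rank, ranked$confidence)
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a CEM prediction file back into annotations
#' @param path CEM file written by [write_cem()]
#' @param corpus abstracts data frame for slice validation
#' @return `chem_annotations` with confidences from the file
#' @export
read_cem <- function(path, corpus) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_annotations())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 4L)) stop("malformed CEM line")
  doc_id <- vapply(parts, `[[`, "", 1L)
  loc <- strsplit(vapply(parts, `[[`, "", 2L), ":", fixed = TRUE)
  section <- vapply(loc, `[[`, "", 1L)
  start <- as.integer(vapply(loc, `[[`, "", 2L))
  end <- as.integer(vapply(loc, `[[`, "", 3L))
  conf <- as.numeric(vapply(parts, `[[`, "", 4L))
  sect <- section_text(corpus, doc_id, section)
  if (any(is.na(sect))) stop("CEM prediction references unknown doc_id")
  if (any(end > nchar(sect))) stop("CEM prediction offsets outside section")
  annotations(doc_id, section, start, end, substr(sect, start + 1L, end),
              confidence = conf, source = "file")
}

#' Read a CDI prediction file
#' @param path CDI file written by [write_cdi()]
#' @return data frame doc_id, text, rank, confidence
#' @export
read_cdi <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(doc_id = character(), text = character(),
                      rank = integer(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(doc_id = vapply(parts, `[[`, "", 1L),
             text = vapply(parts, `[[`, "", 2L),
             rank = as.integer(vapply(parts, `[[`, "", 3L)),
             confidence = as.numeric(vapply(parts, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}
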