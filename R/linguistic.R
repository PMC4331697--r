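#' Sentence-final abbreviation exceptions
#'
#' Words (including their trailing period) after which a period never ends a
#' sentence. Loaded from the packaged resource, which can be replaced by the
#' `path` argument.
#'
#' @param path optional path to a custom exception list (one entry per line,
#'   `#` comments)
#' @return character vector of exceptions, lowercased
#' @export
sentence_abbreviations <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sentence_abbrev.txt", package = "chemtagr")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  tolower(lines[nzchar(lines)])
}

#' Split a section text into sentences
#'
#' Splits after sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and an uppercase letter or digit, unless the word ending in the
#' period is a known abbreviation (e.g. "et al.", "Fig."). Offsets are 0-based
#' within the section; concatenating sentence slices and the whitespace gaps
#' between them reconstructs the section text.
#'
#' @param text section text
#' @param doc_id,section coordinates recorded on the output
#' @param abbrev exception list, see [sentence_abbreviations()]
#' @return data frame doc_id, section, start, end, text
#' @export
split_sentences <- function(text, doc_id = NA_character_, section = NA_character_,
                            abbrev = sentence_abbreviations()) {
  empty <- data.frame(doc_id = character(), section = character(),
                      start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  m <- gregexpr("[.!?](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1L) {
    for (p in as.integer(m)) {
      before <- substr(text, 1L, p)
      word <- sub("^.*[\\s(]", "", before, perl = TRUE)
      if (tolower(word) %in% abbrev) next
      cuts <- c(cuts, p)  # 1-based position of the punctuation = 0-based end
    }
  }
  bounds <- c(0L, cuts, nchar(text))
  out <- empty
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k]; e <- bounds[k + 1L]
    chunk <- substr(text, s + 1L, e)
    lead <- nchar(chunk) - nchar(sub("^\\s+", "", chunk))
    trail <- nchar(chunk) - nchar(sub("\\s+$", "", chunk))
    s <- s + lead; e <- e - trail
    if (e <= s) next
    out <- rbind(out, data.frame(doc_id = doc_id, section = section,
                                 start = s, end = e,
                                 text = substr(text, s + 1L, e),
                                 stringsAsFactors = FALSE))
  }
  out
}

new_tokens <- function(start = integer(), end = integer(), surface = character()) {
  data.frame(start = as.integer(start), end = as.integer(end),
             surface = as.character(surface),
             lemma = NA_character_, pos = NA_character_, chunk = NA_character_,
             dep_head = NA_integer_, dep_label = NA_character_,
             stringsAsFactors = FALSE)
}

#' Tokenize a sentence with chemistry-aware splitting
#'
#' Base segmentation keeps letters, digits and the symbols `' + . / -`
#' together and isolates every other non-space character. A second pass then
#' splits any token containing `/`, `-` or `.` so that each such symbol
#' becomes its own single-character token. Decimal numbers (`digit.digit`)
#' are exempt from the period split so that doses and quantities survive as
#' one token. Offsets are 0-based within the section.
#'
#' @param text sentence text
#' @param offset 0-based offset of the sentence within its section
#' @return token data frame (start, end, surface, plus empty linguistic slots)
#' @export
tokenize <- function(text, offset = 0L) {
  if (is.na(text) || !nzchar(text)) return(new_tokens())
  m <- gregexpr("[\\p{L}\\p{N}_'+./-]+|\\S", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(new_tokens())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surfaces <- substring(text, starts, starts + lens - 1L)
  out_start <- integer(0); out_surf <- character(0)
  for (i in seq_along(surfaces)) {
    tok <- surfaces[i]
    if (grepl("[-/.]", tok) && !grepl("^[0-9]+\\.[0-9]+$", tok)) {
      parts <- regmatches(tok, gregexpr("[0-9]+\\.[0-9]+|[^-/.]+|[-/.]", tok))[[1]]
      pos <- starts[i]
      for (p in parts) {
        out_start <- c(out_start, pos)
        out_surf <- c(out_surf, p)
        pos <- pos + nchar(p)
      }
    } else {
      out_start <- c(out_start, starts[i])
      out_surf <- c(out_surf, tok)
    }
  }
  s0 <- out_start - 1L + as.integer(offset)
  new_tokens(s0, s0 + nchar(out_surf), out_surf)
}

#' Construct a linguistic tagger
#'
#' A tagger is a named contract: given a token data frame it returns one
#' attribute row per token, never altering token boundaries. `capabilities`
#' declares which of lemma, pos, chunk, dependency it provides; missing
#' capabilities simply leave the corresponding attributes unset.
#'
#' @param name identifier
#' @param capabilities subset of c("lemma", "pos", "chunk", "dependency")
#' @param fun function(tokens) returning a data frame with the capability
#'   columns and nrow equal to the input
#' @return object of class `linguistic_tagger`
#' @export
linguistic_tagger <- function(name, capabilities, fun) {
  stopifnot(is.function(fun),
            all(capabilities %in% c("lemma", "pos", "chunk", "dependency")))
  structure(list(name = name, capabilities = capabilities, fun = fun),
            class = "linguistic_tagger")
}

closed_class_pos <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", these = "DT", that = "DT",
  those = "DT", each = "DT", all = "DT", no = "DT",
  of = "IN", "in" = "IN", on = "IN", with = "IN", by = "IN", "for" = "IN",
  at = "IN", from = "IN", to = "IN", after = "IN", before = "IN",
  during = "IN", into = "IN", under = "IN", between = "IN", via = "IN",
  and = "CC", or = "CC", but = "CC", plus = "CC",
  we = "PRP", it = "PRP", they = "PRP", he = "PRP", she = "PRP", i = "PRP",
  you = "PRP", its = "PRP$", their = "PRP$", our = "PRP$",
  was = "VBD", were = "VBD", did = "VBD", showed = "VBD",
  is = "VBZ", has = "VBZ", does = "VBZ",
  are = "VBP", have = "VBP", be = "VB", been = "VBN",
  not = "RB", also = "RB", however = "RB", significantly = "RB")

fallback_pos <- function(surface, first = FALSE) {
  low <- tolower(surface)
  if (!is.na(closed_class_pos[low])) return(unname(closed_class_pos[low]))
  if (grepl("^[0-9]+(\\.[0-9]+)?$", surface)) return("CD")
  if (nchar(surface) == 1 && grepl("[^\\p{L}\\p{N}]", surface, perl = TRUE))
    return(surface)
  if (grepl("ed$", low) && nchar(low) > 3) return("VBD")
  if (grepl("ing$", low) && nchar(low) > 4) return("VBG")
  if (grepl("ly$", low) && nchar(low) > 3) return("RB")
  if (grepl("(ous|ive|ical|able|ic|al)$", low) && nchar(low) > 4) return("JJ")
  if (grepl("[b-df-hj-np-tv-xz]s$", low) && nchar(low) > 3) return("NNS")
  if (!first && grepl("^[A-Z]", surface)) return("NNP")
  "NN"
}

fallback_chunk <- function(pos) {
  np <- grepl("^(DT|JJ|NN|CD|PRP)", pos)
  vp <- grepl("^(VB|MD)", pos)
  chunk <- rep("O", length(pos))
  chunk[vp] <- "B-VP"
  if (any(np)) {
    prev <- c(FALSE, np[-length(np)])
    chunk[np & !prev] <- "B-NP"
    chunk[np & prev] <- "I-NP"
  }
  chunk
}

#' Deterministic rule-based fallback tagger
#'
#' Suffix- and lexicon-driven POS tags, a noun-phrase/verb-phrase chunker on
#' top of them, and identity-lowercase lemmas. Shipped so that the whole
#' pipeline runs with no external NLP tool; an external GENIA/GDep-style
#' tagger can be plugged in through the [linguistic_tagger()] contract for
#' higher fidelity.
#'
#' @return a `linguistic_tagger` with capabilities lemma, pos, chunk
#' @export
default_tagger <- function() {
  linguistic_tagger("fallback", c("lemma", "pos", "chunk"), function(tokens) {
    n <- nrow(tokens)
    pos <- character(n)
    for (i in seq_len(n)) pos[i] <- fallback_pos(tokens$surface[i], first = (i == 1))
    data.frame(lemma = tolower(tokens$surface), pos = pos,
               chunk = fallback_chunk(pos), stringsAsFactors = FALSE)
  })
}

#' Tagger reading a tab-separated token-attribute exchange file
#'
#' Adapter for external-process taggers: each line carries
#' `token TAB lemma TAB pos TAB chunk TAB head TAB deplabel` for the tokens of
#' the corpus, in tokenization order.
#'
#' @param path exchange file
#' @return `linguistic_tagger` consuming rows sequentially
#' @export
file_tagger <- function(path) {
  rows <- strsplit(readLines(path, encoding = "UTF-8", warn = FALSE), "\t", fixed = TRUE)
  cursor <- new.env()
  cursor$i <- 0L
  linguistic_tagger("file", c("lemma", "pos", "chunk", "dependency"), function(tokens) {
    n <- nrow(tokens)
    idx <- cursor$i + seq_len(n)
    if (max(idx) > length(rows)) stop("tagger exchange file exhausted")
    cursor$i <- cursor$i + n
    sel <- rows[idx]
    data.frame(lemma = vapply(sel, `[[`, "", 2L),
               pos = vapply(sel, `[[`, "", 3L),
               chunk = vapply(sel, `[[`, "", 4L),
               dep_head = as.integer(vapply(sel, `[[`, "", 5L)),
               dep_label = vapply(sel, `[[`, "", 6L),
               stringsAsFactors = FALSE)
  })
}

#' Enrich tokens with a tagger's linguistic attributes
#'
#' @param tokens token data frame
#' @param tagger a [linguistic_tagger()]; attributes outside its capabilities
#'   are left unset
#' @return tokens with lemma/pos/chunk/dependency columns filled in
#' @export
annotate_linguistics <- function(tokens, tagger) {
  stopifnot(inherits(tagger, "linguistic_tagger"))
  if (length(tagger$capabilities) == 0 || nrow(tokens) == 0) return(tokens)
  attrs <- tagger$fun(tokens)
  if (nrow(attrs) != nrow(tokens))
    stop("tagger returned ", nrow(attrs), " rows for ", nrow(tokens), " tokens")
  if ("lemma" %in% tagger$capabilities) tokens$lemma <- attrs$lemma
  if ("pos" %in% tagger$capabilities) tokens$pos <- attrs$pos
  if ("chunk" %in% tagger$capabilities) tokens$chunk <- attrs$chunk
  if ("dependency" %in% tagger$capabilities) {
    tokens$dep_head <- attrs$dep_head
    tokens$dep_label <- attrs$dep_label
  }
  tokens
}

#' Preprocess a corpus into tagged sentence token sequences
#'
#' Runs sentence splitting, tokenization and linguistic annotation over the
#' title and abstract of every document. Title and abstract are processed
#' fully independently.
#'
#' @param docs abstracts data frame
#' @param tagger a [linguistic_tagger()]
#' @return list of token data frames; each carries attributes `doc_id`,
#'   `section` and `sect_text`
#' @export
preprocess_corpus <- function(docs, tagger = default_tagger()) {
  seqs <- list()
  for (i in seq_len(nrow(docs))) {
    for (section in c("T", "A")) {
      txt <- if (section == "T") docs$title[i] else docs$abstract[i]
      sents <- split_sentences(txt, docs$doc_id[i], section)
      for (k in seq_len(nrow(sents))) {
        toks <- tokenize(sents$text[k], sents$start[k])
        if (nrow(toks) == 0) next
        toks <- annotate_linguistics(toks, tagger)
        attr(toks, "doc_id") <- docs$doc_id[i]
        attr(toks, "section") <- section
        attr(toks, "sect_text") <- txt
        seqs[[length(seqs) + 1L]] <- toks
      }
    }
  }
  seqs
}
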