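#' All feature group names
#' @export
ALL_FEATURE_GROUPS <- c(
  "token", "lemma", "pos", "chunk", "dependency",
  "capitalization", "counting", "symbols", "greek",
  "char_ngrams", "suffix", "prefix", "word_shape", "dictionary",
  "context_windows", "context_conjunctions")

#' Feature configuration
#'
#' The default enables every group except dependency parsing and
#' capitalization — the configuration that evaluated best — and uses
#' conjunctions rather than windows for local context. Enabling both
#' `context_windows` and `context_conjunctions` is an error: they are two
#' encodings of the same information.
#'
#' @param enabled_groups character subset of [ALL_FEATURE_GROUPS]
#' @param ngram_lengths character n-gram lengths (default 2, 3, 4)
#' @param affix_lengths prefix/suffix lengths (default 2, 3, 4)
#' @param context_windows list of `c(from, to)` relative-offset windows
#' @return object of class `feature_config`
#' @export
feature_config <- function(enabled_groups = setdiff(ALL_FEATURE_GROUPS,
                             c("dependency", "capitalization", "context_windows")),
                           ngram_lengths = 2:4,
                           affix_lengths = 2:4,
                           context_windows = list(c(-1L, 0L), c(-2L, -1L),
                                                  c(0L, 1L), c(-1L, 1L),
                                                  c(-3L, -1L))) {
  bad <- setdiff(enabled_groups, ALL_FEATURE_GROUPS)
  if (length(bad) > 0) stop("unknown feature group(s): ", paste(bad, collapse = ", "))
  if (all(c("context_windows", "context_conjunctions") %in% enabled_groups))
    stop("context_windows and context_conjunctions are mutually exclusive")
  for (w in context_windows)
    if (length(w) != 2 || w[1] > w[2]) stop("each context window must be c(from, to) with from <= to")
  structure(list(enabled_groups = enabled_groups,
                 ngram_lengths = as.integer(ngram_lengths),
                 affix_lengths = as.integer(affix_lengths),
                 context_windows = lapply(context_windows, as.integer)),
            class = "feature_config")
}

#' Disable feature groups in a configuration
#' @param config a [feature_config()]
#' @param groups groups to remove
#' @return modified configuration
#' @export
disable_groups <- function(config, groups) {
  config$enabled_groups <- setdiff(config$enabled_groups, groups)
  config
}

#' Word shape abstraction
#'
#' Maps uppercase letters to `A`, lowercase to `a`, digits to `1` and any
#' other character to `#`, e.g. `"Abc:1234"` becomes `"Aaa#1111"`.
#'
#' @param surface non-empty token string
#' @return shape string
#' @export
word_shape <- function(surface) {
  if (any(!nzchar(surface))) stop("word_shape of empty string")
  s <- gsub("\\p{Lu}", "A", surface, perl = TRUE)
  s <- gsub("\\p{Ll}", "a", s, perl = TRUE)
  s <- gsub("\\p{Nd}", "1", s, perl = TRUE)
  gsub("[^Aa1]", "#", s, perl = TRUE)
}

GREEK_NAMES <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
                 "theta", "iota", "kappa", "lambda", "mu", "nu", "xi",
                 "omicron", "pi", "rho", "sigma", "tau", "upsilon", "phi",
                 "chi", "psi", "omega")

SYMBOL_CLASSES <- list(Dash = "-", Dot = ".", Comma = ",", Slash = "/",
                       Parenthesis = "()", Bracket = "[]{}", Plus = "+",
                       Percent = "%", Apostrophe = "'", Colon = ":",
                       Semicolon = ";", Equals = "=")

count_bin <- function(n, what) {
  lab <- c("No", "One", "Two", "ThreeOrMore")[pmin(n, 3L) + 1L]
  paste0(lab, what)
}

cap_class <- function(surface) {
  n_up <- nchar(gsub("[^\\p{Lu}]", "", surface, perl = TRUE))
  n_lo <- nchar(gsub("[^\\p{Ll}]", "", surface, perl = TRUE))
  if (n_up + n_lo == 0) return(character(0))
  if (n_up == 1 && n_lo == 0 && nchar(surface) == 1) return("CAP=SingleCap")
  if (n_lo == 0 && n_up >= 2) return("CAP=AllCaps")
  if (n_up == 0) return("CAP=LowerCase")
  if (grepl("^\\p{Lu}", surface, perl = TRUE) &&
      n_up == 1) return("CAP=StartCap")
  "CAP=MixedCase"
}

#' Orthographic features of one token surface
#'
#' Emits the capitalization class, digit and capital counting bins, one flag
#' per symbol class present, and Greek-letter flags for spelled-out names and
#' glyphs.
#'
#' @param surface token string
#' @return character vector of feature strings
#' @export
orthographic_features <- function(surface) {
  feats <- cap_class(surface)
  n_dig <- nchar(gsub("[^0-9]", "", surface))
  n_up <- nchar(gsub("[^\\p{Lu}]", "", surface, perl = TRUE))
  feats <- c(feats, paste0("DIGITS=", count_bin(n_dig, "Digit")),
             paste0("CAPS=", count_bin(n_up, "Cap")))
  for (nm in names(SYMBOL_CLASSES)) {
    chars <- strsplit(SYMBOL_CLASSES[[nm]], "")[[1]]
    if (any(vapply(chars, function(ch) grepl(ch, surface, fixed = TRUE), TRUE)))
      feats <- c(feats, paste0("SYM=", nm))
  }
  low <- tolower(surface)
  hit <- GREEK_NAMES[vapply(GREEK_NAMES, function(g) grepl(g, low, fixed = TRUE), TRUE)]
  glyphs <- utf8ToInt("α") : utf8ToInt("ω")
  cp <- utf8ToInt(tolower(surface))
  hit <- unique(c(hit, GREEK_NAMES[match(cp[cp %in% glyphs], glyphs)]))
  hit <- hit[!is.na(hit)]
  c(feats, if (length(hit)) paste0("GREEK=", hit))
}

#' Morphological features of one token surface
#'
#' Prefixes and suffixes of the configured lengths (skipped when the token is
#' shorter), all contiguous character n-grams of the configured lengths, and
#' the [word_shape()] feature.
#'
#' @param surface token string
#' @param config a [feature_config()]; only the length settings are used
#' @return character vector of feature strings
#' @export
morphological_features <- function(surface, config = feature_config()) {
  nc <- nchar(surface)
  feats <- character(0)
  for (l in config$affix_lengths) {
    if (nc < l) next
    feats <- c(feats, sprintf("P%d=%s", l, substr(surface, 1, l)),
               sprintf("S%d=%s", l, substr(surface, nc - l + 1, nc)))
  }
  for (l in config$ngram_lengths) {
    if (nc < l) next
    grams <- unique(substring(surface, 1:(nc - l + 1), l:nc))
    feats <- c(feats, sprintf("NG%d=%s", l, grams))
  }
  c(feats, paste0("SHAPE=", word_shape(surface)))
}

norm_term <- function(x) tolower(stringi::stri_trans_nfkc(x))

#' Load a lexicon file
#'
#' UTF-8 plain text, one term per line, `#` comments allowed; multi-word
#' terms are space-separated. Terms are tokenized with the package tokenizer
#' and normalized (Unicode NFKC, lowercase) for case-insensitive matching.
#'
#' @param path lexicon file
#' @return object of class `chem_lexicon`
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  as_lexicon(lines[nzchar(lines)])
}

#' Build a lexicon from a character vector of terms
#' @param terms character vector; multi-word terms space-separated
#' @return `chem_lexicon`
#' @export
as_lexicon <- function(terms) {
  terms <- unique(terms[nzchar(terms)])
  toks <- lapply(terms, function(t) norm_term(tokenize(t)$surface))
  toks <- toks[vapply(toks, length, 0L) > 0]
  index <- split(toks, vapply(toks, `[[`, "", 1L))
  structure(list(terms = terms, token_seqs = toks, index = index),
            class = "chem_lexicon")
}

#' Dictionary-match features over a token sequence
#'
#' Case-insensitive leftmost-longest matching of lexicon terms against the
#' token sequence; matches must align with token boundaries. Matched tokens
#' receive `LEXICON=B` / `LEXICON=I` positional features.
#'
#' @param tokens token data frame
#' @param lexicon a `chem_lexicon` (or NULL for no features)
#' @return list of character vectors, one per token
#' @export
dictionary_features <- function(tokens, lexicon) {
  n <- nrow(tokens)
  out <- replicate(n, character(0), simplify = FALSE)
  if (is.null(lexicon) || n == 0) return(out)
  norm <- norm_term(tokens$surface)
  i <- 1L
  while (i <= n) {
    cands <- lexicon$index[[norm[i]]]
    best <- 0L
    if (!is.null(cands)) {
      for (term in cands) {
        L <- length(term)
        if (L > best && i + L - 1L <= n &&
            identical(norm[i:(i + L - 1L)], term)) best <- L
      }
    }
    if (best > 0L) {
      out[[i]] <- "LEXICON=B"
      if (best > 1L) for (j in (i + 1L):(i + best - 1L)) out[[j]] <- "LEXICON=I"
      i <- i + best
    } else i <- i + 1L
  }
  out
}

ctx_attr <- function(tokens, idx, attr) {
  n <- nrow(tokens)
  vapply(idx, function(j) {
    if (j < 1L) return("BOS")
    if (j > n) return("EOS")
    v <- tokens[[attr]][j]
    if (is.na(v)) return("NA")
    if (attr == "lemma") tolower(v) else v
  }, "")
}

#' Local-context features for one token position
#'
#' In `windows` mode the lemma, POS and chunk of every token inside each
#' configured window are copied onto the current token, tagged with the
#' window and relative offset. In `conjunctions` mode one new feature per
#' window and attribute (lemma, POS) concatenates the attribute across the
#' window positions with `|`. Positions outside the sentence contribute
#' BOS/EOS placeholders.
#'
#' @param i token position (1-based)
#' @param tokens token data frame with linguistic attributes
#' @param mode "windows" or "conjunctions"
#' @param config a [feature_config()]
#' @return character vector of feature strings
#' @export
context_features <- function(i, tokens, mode = c("conjunctions", "windows"),
                             config = feature_config()) {
  mode <- match.arg(mode)
  feats <- character(0)
  for (w in config$context_windows) {
    idx <- i + (w[1]:w[2])
    if (mode == "windows") {
      for (attr in c("lemma", "pos", "chunk")) {
        vals <- ctx_attr(tokens, idx, attr)
        feats <- c(feats, sprintf("WIN[%d,%d]%s@%d=%s", w[1], w[2], attr,
                                  w[1]:w[2], vals))
      }
    } else {
      for (attr in c("lemma", "pos")) {
        vals <- ctx_attr(tokens, idx, attr)
        feats <- c(feats, sprintf("CONJ[%d,%d]%s=%s", w[1], w[2], attr,
                                  paste(vals, collapse = "|")))
      }
    }
  }
  feats
}

#' Build the full feature set for a token sequence
#'
#' Union of all enabled feature groups per token. Linguistic groups whose
#' attributes are missing from the tokens are skipped with one warning per
#' sequence. The result is deterministic for fixed inputs.
#'
#' @param tokens token data frame (see [tokenize()] / [annotate_linguistics()])
#' @param lexicon optional `chem_lexicon` for dictionary features
#' @param config a [feature_config()]
#' @return list of character feature vectors, one per token
#' @export
build_features <- function(tokens, lexicon = NULL, config = feature_config()) {
  n <- nrow(tokens)
  if (n == 0) return(list())
  g <- config$enabled_groups
  has <- function(col) !all(is.na(tokens[[col]]))
  missing_groups <- character(0)

  per <- replicate(n, character(0), simplify = FALSE)
  add <- function(per, vecs) mapply(c, per, vecs, SIMPLIFY = FALSE)

  if ("token" %in% g) per <- add(per, paste0("W=", tokens$surface))
  for (grp in c("lemma", "pos", "chunk")) {
    if (!grp %in% g) next
    if (!has(grp)) { missing_groups <- c(missing_groups, grp); next }
    v <- tokens[[grp]]
    if (grp == "lemma") v <- tolower(v)
    per <- add(per, paste0(toupper(grp), "=", v))
  }
  if ("dependency" %in% g) {
    if (!has("dep_label")) missing_groups <- c(missing_groups, "dependency")
    else {
      dep <- lapply(seq_len(n), function(i) {
        f <- character(0)
        if (!is.na(tokens$dep_label[i]))
          f <- c(f, paste0("DEPLBL=", tokens$dep_label[i]))
        h <- tokens$dep_head[i]
        if (!is.na(h) && h >= 1 && h <= n && !is.na(tokens$lemma[h]))
          f <- c(f, paste0("DEPHEAD=", tolower(tokens$lemma[h])))
        f
      })
      per <- add(per, dep)
    }
  }

  ortho_groups <- intersect(g, c("capitalization", "counting", "symbols", "greek"))
  if (length(ortho_groups) > 0) {
    keep_prefix <- c(capitalization = "CAP=", counting = "DIGITS=|CAPS=",
                     symbols = "SYM=", greek = "GREEK=")[ortho_groups]
    pat <- paste0("^(", paste(keep_prefix, collapse = "|"), ")")
    ortho <- lapply(tokens$surface, function(s) {
      f <- orthographic_features(s)
      f[grepl(pat, f)]
    })
    per <- add(per, ortho)
  }

  morph_groups <- intersect(g, c("char_ngrams", "suffix", "prefix", "word_shape"))
  if (length(morph_groups) > 0) {
    keep_prefix <- c(char_ngrams = "NG", suffix = "S[0-9]+=", prefix = "P[0-9]+=",
                     word_shape = "SHAPE=")[morph_groups]
    pat <- paste0("^(", paste(keep_prefix, collapse = "|"), ")")
    morph <- lapply(tokens$surface, function(s) {
      f <- morphological_features(s, config)
      f[grepl(pat, f)]
    })
    per <- add(per, morph)
  }

  if ("dictionary" %in% g && !is.null(lexicon))
    per <- add(per, dictionary_features(tokens, lexicon))

  ctx_mode <- if ("context_windows" %in% g) "windows"
              else if ("context_conjunctions" %in% g) "conjunctions"
              else NULL
  if (!is.null(ctx_mode)) {
    need <- if (ctx_mode == "windows") c("lemma", "pos", "chunk") else c("lemma", "pos")
    if (!any(vapply(need, has, TRUE))) {
      missing_groups <- c(missing_groups, paste0("context_", ctx_mode))
    } else {
      ctx <- lapply(seq_len(n), context_features, tokens = tokens,
                    mode = ctx_mode, config = config)
      per <- add(per, ctx)
    }
  }

  if (length(missing_groups) > 0)
    warning("linguistic attributes missing; skipped feature group(s): ",
            paste(missing_groups, collapse = ", "))
  per
}
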