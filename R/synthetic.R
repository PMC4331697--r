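read_packaged_list <- function(name) {
  path <- system.file("extdata", name, package = "chemtagr")
  lines <- trimws(sub("#.*$", "", readLines(path, encoding = "UTF-8", warn = FALSE)))
  lines[nzchar(lines)]
}

#' Configuration for the synthetic corpus generator
#'
#' The defaults describe the corpus the package's own experiments run on:
#' abstracts built from templated sentences with planted chemical mentions of
#' all seven annotation classes, homograph "trap" terms planted both as
#' chemicals and as ordinary words, and a mention-count distribution with
#' mild overdispersion.
#'
#' @param n_docs number of documents
#' @param seed RNG seed; generation is fully deterministic given the seed
#' @param class_mix named proportions over the seven mention classes (must
#'   sum to 1)
#' @param mentions_per_doc c(mean, dispersion) of a negative binomial
#' @param abbrev_rate probability that a document contains an abbreviation
#'   definition sentence
#' @param fp_trap_terms homograph strings planted as non-chemical decoys
#' @param lexicon_fraction fraction of non-trivial mention strings included
#'   in the emitted lexicon
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_docs = 100L, seed = 42L,
                             class_mix = c(SYSTEMATIC = 0.22, TRIVIAL = 0.30,
                                           ABBREVIATION = 0.15, FAMILY = 0.14,
                                           FORMULA = 0.10, IDENTIFIER = 0.05,
                                           MULTIPLE = 0.04),
                             mentions_per_doc = c(mean = 6, dispersion = 8),
                             abbrev_rate = 0.6,
                             fp_trap_terms = c("lead", "iron", "gold", "zinc"),
                             lexicon_fraction = 0.5) {
  if (n_docs < 1) stop("n_docs must be >= 1")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (abbrev_rate < 0 || abbrev_rate > 1) stop("abbrev_rate must be in [0, 1]")
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 class_mix = class_mix, mentions_per_doc = mentions_per_doc,
                 abbrev_rate = abbrev_rate, fp_trap_terms = fp_trap_terms,
                 lexicon_fraction = lexicon_fraction),
            class = "generator_config")
}

SYS_LOCANTS <- as.character(1:9)
SYS_STEMS <- c("chloro", "bromo", "fluoro", "iodo", "methyl", "ethyl",
               "propyl", "butyl", "hydroxy", "amino", "nitro", "acetoxy",
               "oxo", "cyano", "methoxy", "phenyl")
SYS_BASES <- c("benzoic acid", "phenol", "aniline", "toluene", "butanol",
               "hexane", "pyridine", "indole", "acetic acid", "benzaldehyde",
               "naphthalene", "propanol", "pyrimidine", "imidazole",
               "quinoline", "cyclohexanone")
SYS_SUBS <- c("dimethylamino", "aminomethyl", "chloromethyl", "hydroxymethyl",
              "trifluoromethyl", "methylsulfonyl")
FAMILY_NAMES <- c("benzodiazepines", "sulfonamides", "phenothiazines",
                  "statins", "opioids", "flavonoids", "alkaloids",
                  "terpenoids", "catecholamines", "barbiturates",
                  "salicylates", "corticosteroids", "prostaglandins",
                  "nitrosamines", "polyphenols", "anthracyclines",
                  "quinolones", "macrolides", "tetracyclines", "xanthines")
ABBREV_PAIRS <- list(
  c("ethylene glycol", "EG"), c("acetylsalicylic acid", "ASA"),
  c("gamma aminobutyric acid", "GABA"), c("polyethylene glycol", "PEG"),
  c("nitric oxide", "NO"), c("carbon monoxide", "CO"),
  c("hydrogen peroxide", "HP"),
  c("dimethyl sulfoxide", "DMSO"), c("epigallocatechin gallate", "EGCG"),
  c("docosahexaenoic acid", "DHA"), c("bovine serum albumin", "BSA"))
MULTIPLE_PHRASES <- c("methyl and ethyl esters", "sodium and potassium salts",
                      "cis and trans isomers", "mono and di esters",
                      "alpha and beta anomers")

gen_systematic <- function() {
  form <- sample.int(3, 1)
  if (form == 1)
    paste0(sample(SYS_LOCANTS, 1), "-", sample(SYS_STEMS, 1),
           sample(SYS_BASES, 1))
  else if (form == 2) {
    loc <- sort(sample(1:6, 2))
    paste0(loc[1], ",", loc[2], "-di", sample(SYS_STEMS, 1),
           sample(SYS_BASES, 1))
  } else
    paste0(sample(SYS_LOCANTS, 1), "-(", sample(SYS_SUBS, 1), ")",
           sample(SYS_BASES, 1))
}

gen_formula <- function(elements) {
  k <- sample(2:4, 1)
  els <- sample(elements, k)
  counts <- sample(1:12, k, replace = TRUE)
  paste0(vapply(seq_len(k), function(i)
    paste0(els[i], if (counts[i] > 1) counts[i] else ""), ""), collapse = "")
}

gen_identifier <- function() {
  switch(sample.int(3, 1),
         sprintf("CHEBI:%d", sample(1000:99999, 1)),
         sprintf("DB%05d", sample(1:99999, 1)),
         sprintf("CID%d", sample(10000:999999, 1)))
}

gen_mention <- function(cls, trivial_pool, elements) {
  switch(cls,
         SYSTEMATIC = gen_systematic(),
         TRIVIAL = sample(trivial_pool, 1),
         FAMILY = sample(FAMILY_NAMES, 1),
         FORMULA = gen_formula(elements),
         IDENTIFIER = gen_identifier(),
         MULTIPLE = sample(MULTIPLE_PHRASES, 1),
         stop("unhandled class ", cls))
}

# sentence templates; NA marks a mention slot
MENTION_TEMPLATES <- list(
  c("The patients were treated with ", NA, " for two weeks."),
  c("Levels of ", NA, " increased after administration of ", NA, "."),
  c("We measured the concentration of ", NA, " in plasma samples."),
  c("Treatment with ", NA, " reduced the expression of the target gene."),
  c("The compound ", NA, " inhibited the enzyme in vitro."),
  c("Exposure to ", NA, " was associated with increased toxicity."),
  c("No significant effect of ", NA, " was observed in the control group."),
  c("Synthesis of ", NA, " was achieved in three steps."),
  c("Oral administration of ", NA, " improved the clinical outcome."),
  c("Binding of ", NA, " to the receptor was dose dependent."),
  c("Serum concentrations of ", NA, " and ", NA, " were quantified."),
  c("Pretreatment with ", NA, " attenuated the response to ", NA, "."))
FILLER_SENTENCES <- c(
  "The study included forty two participants from two centers.",
  "Results were analyzed with standard statistical methods.",
  "Samples were collected at baseline and after treatment.",
  "The findings support further clinical investigation.",
  "All procedures were approved by the local ethics committee.",
  "Follow up examinations were scheduled every month.")
TRAP_TEMPLATES <- c("The %s author designed and supervised the study.",
                    "A %s standard assay was used for validation.",
                    "Researchers will %s future trials on this topic.")
TITLE_TEMPLATES <- list(
  c("Effects of ", NA, " on renal function in rats"),
  c("A randomized trial of ", NA, " in chronic disease"),
  c("Pharmacokinetics of ", NA, " in healthy volunteers"),
  c("Clinical outcomes after treatment including biomarkers"),
  c("Quantification of ", NA, " in human plasma"))

# fill a template, returning the text and the 0-based local slot spans
fill_template <- function(parts, values) {
  text <- ""
  spans <- list()
  vi <- 1L
  for (p in parts) {
    if (is.na(p)) {
      v <- values[vi]; vi <- vi + 1L
      spans[[length(spans) + 1L]] <- c(nchar(text), nchar(text) + nchar(v))
      text <- paste0(text, v)
    } else text <- paste0(text, p)
  }
  list(text = text, spans = spans)
}

#' Generate a synthetic CHEMDNER-style corpus
#'
#' Deterministically (given the seed) builds abstracts from sentence
#' templates with planted chemical mentions: systematic names from a
#' locant-stem-suffix grammar with optional parenthesized substituents,
#' formulas from an element-symbol/count grammar, trivial names from the
#' packaged list, abbreviation definitions as "long form (SHORT)" pairs,
#' registry-style identifiers, pluralized family names and coordinated
#' multiple mentions. All gold offsets are exact. The emitted lexicon
#' contains every trivial name, a configurable fraction of the other planted
#' mentions, and distractor terms.
#'
#' @param config a [generator_config()]
#' @return list with `docs` (abstracts data frame), `gold`
#'   (`chem_annotations` with classes), `lexicon` (`chem_lexicon`) and
#'   `trap_terms`
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  trivial_pool <- unique(c(read_packaged_list("trivial_names.txt"),
                           config$fp_trap_terms))
  elements <- read_packaged_list("elements.txt")
  classes <- names(config$class_mix)

  docs <- data.frame(doc_id = character(), title = character(),
                     abstract = character(), stringsAsFactors = FALSE)
  gold_rows <- list()
  planted <- character(0)

  add_gold <- function(doc_id, section, spans, texts, clses) {
    for (i in seq_along(spans))
      gold_rows[[length(gold_rows) + 1L]] <<- data.frame(
        doc_id = doc_id, section = section,
        start = spans[[i]][1], end = spans[[i]][2],
        text = texts[i], cls = clses[i], stringsAsFactors = FALSE)
  }

  # returns list(text, spans, texts, clses) for one mention-bearing sentence
  make_mention_sentence <- function(n_slots_wanted) {
    tmpl <- MENTION_TEMPLATES[[sample.int(length(MENTION_TEMPLATES), 1)]]
    n_slots <- sum(is.na(tmpl))
    clses <- sample(classes, n_slots, replace = TRUE,
                    prob = config$class_mix)
    clses[clses == "ABBREVIATION"] <- "TRIVIAL"  # definitions are separate
    vals <- vapply(clses, gen_mention, "", trivial_pool = trivial_pool,
                   elements = elements)
    ft <- fill_template(tmpl, vals)
    list(text = ft$text, spans = ft$spans, texts = vals, clses = clses)
  }

  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("SYN%05d", d)
    # title
    tmpl <- TITLE_TEMPLATES[[sample.int(length(TITLE_TEMPLATES), 1)]]
    n_slots <- sum(is.na(tmpl))
    t_cls <- if (n_slots > 0) sample(classes, n_slots, replace = TRUE,
                                     prob = config$class_mix) else character(0)
    t_cls[t_cls == "ABBREVIATION"] <- "TRIVIAL"
    t_vals <- vapply(t_cls, gen_mention, "", trivial_pool = trivial_pool,
                     elements = elements)
    ft <- fill_template(tmpl, t_vals)
    title <- ft$text
    add_gold(doc_id, "T", ft$spans, t_vals, t_cls)
    planted <- c(planted, t_vals)

    # abstract sentences
    m <- max(1L, rnbinom(1, size = config$mentions_per_doc["dispersion"],
                         mu = config$mentions_per_doc["mean"]))
    sents <- list()
    placed <- 0L
    while (placed < m) {
      s <- make_mention_sentence()
      sents[[length(sents) + 1L]] <- s
      placed <- placed + length(s$spans)
    }
    if (runif(1) < config$abbrev_rate) {
      ab <- ABBREV_PAIRS[[sample.int(length(ABBREV_PAIRS), 1)]]
      ft2 <- fill_template(c("Patients received ", NA, " (", NA, ") daily."),
                           c(ab[1], ab[2]))
      sents[[length(sents) + 1L]] <- list(text = ft2$text, spans = ft2$spans,
                                          texts = ab,
                                          clses = c("TRIVIAL", "ABBREVIATION"))
    }
    n_fill <- sample(1:2, 1)
    for (k in seq_len(n_fill))
      sents[[length(sents) + 1L]] <- list(text = sample(FILLER_SENTENCES, 1),
                                          spans = list(), texts = character(0),
                                          clses = character(0))
    if (runif(1) < 0.4)
      sents[[length(sents) + 1L]] <- list(
        text = sprintf(sample(TRAP_TEMPLATES, 1),
                       sample(config$fp_trap_terms, 1)),
        spans = list(), texts = character(0), clses = character(0))
    sents <- sents[sample.int(length(sents))]

    abstract <- ""
    for (s in sents) {
      off <- nchar(abstract) + if (nzchar(abstract)) 1L else 0L
      abstract <- if (nzchar(abstract)) paste(abstract, s$text) else s$text
      if (length(s$spans) > 0) {
        spans <- lapply(s$spans, function(sp) sp + off)
        add_gold(doc_id, "A", spans, s$texts, s$clses)
        planted <- c(planted, s$texts)
      }
    }
    docs <- rbind(docs, data.frame(doc_id = doc_id, title = title,
                                   abstract = abstract,
                                   stringsAsFactors = FALSE))
  }

  gold_df <- do.call(rbind, gold_rows)
  gold <- annotations(gold_df$doc_id, gold_df$section, gold_df$start,
                      gold_df$end, gold_df$text, gold_df$cls,
                      confidence = 1, source = "gold")
  # validate the slice invariant defensively
  sect <- section_text(docs, gold$doc_id, gold$section)
  stopifnot(identical(substr(sect, gold$start + 1L, gold$end), gold$text))

  others <- setdiff(unique(planted), trivial_pool)
  extra <- others[runif(length(others)) < config$lexicon_fraction]
  distractors <- c("placebo", "patient", "receptor", "protein", "baseline",
                   "outcome measure", "standard deviation")
  long_forms <- vapply(ABBREV_PAIRS, `[[`, "", 1L)
  lexicon <- as_lexicon(c(trivial_pool, long_forms, extra, distractors))
  list(docs = docs, gold = gold, lexicon = lexicon,
       trap_terms = config$fp_trap_terms)
}

#' Corrupt gold annotations into a simulated prediction set
#'
#' Seeded removal of gold spans (false negatives), injection of trap-term
#' spans (false positives) and token-boundary jitter, producing predictions
#' with synthetic confidences (kept spans high, injected ones low). Useful
#' as an oracle for evaluation and exclusion-list machinery.
#'
#' @param gold gold `chem_annotations`
#' @param docs abstracts data frame the gold refers to
#' @param seed RNG seed
#' @param fp_rate probability of injecting a prediction at each trap-term
#'   occurrence not covered by gold
#' @param fn_rate probability of dropping each gold span
#' @param boundary_jitter maximum character shift; each surviving span is
#'   extended to an adjacent token boundary with probability 1/2 when the
#'   shift fits the budget
#' @param trap_terms strings whose free-text occurrences become injected
#'   false positives
#' @return simulated `chem_annotations`
#' @export
corrupt_predictions <- function(gold, docs, seed = 42L, fp_rate = 0,
                                fn_rate = 0, boundary_jitter = 0L,
                                trap_terms = c("lead", "iron", "gold", "zinc")) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  set.seed(seed)
  keep <- runif(nrow(gold)) >= fn_rate
  preds <- gold[keep, , drop = FALSE]
  n <- nrow(preds)
  if (n > 0) {
    preds$confidence <- runif(n, 0.7, 0.99)
    preds$source <- "sim"
    preds$cls <- NA_character_
  }
  if (boundary_jitter > 0 && n > 0) {
    for (i in seq_len(n)) {
      if (runif(1) >= 0.5) next
      sect <- section_text(docs, preds$doc_id[i], preds$section[i])
      toks <- tokenize(sect)
      nxt <- which(toks$start >= preds$end[i])
      if (length(nxt) == 0) next
      j <- nxt[1]
      if (toks$end[j] - preds$end[i] > boundary_jitter) next
      preds$end[i] <- toks$end[j]
      preds$text[i] <- substr(sect, preds$start[i] + 1L, preds$end[i])
    }
  }
  if (fp_rate > 0) {
    inj <- list()
    for (d in seq_len(nrow(docs))) {
      for (section in c("T", "A")) {
        sect <- section_text(docs, docs$doc_id[d], section)
        for (term in trap_terms) {
          m <- gregexpr(paste0("\\b", term, "\\b"), sect, perl = TRUE)[[1]]
          if (m[1] == -1L) next
          for (k in seq_along(m)) {
            s <- as.integer(m[k]) - 1L
            e <- s + attr(m, "match.length")[k]
            covered <- any(gold$doc_id == docs$doc_id[d] &
                             gold$section == section &
                             gold$start < e & s < gold$end)
            if (!covered && runif(1) < fp_rate)
              inj[[length(inj) + 1L]] <- annotations(
                docs$doc_id[d], section, s, e, term,
                confidence = runif(1, 0.1, 0.5), source = "sim-fp")
          }
        }
      }
    }
    if (length(inj) > 0) preds <- rbind(preds, do.call(rbind, inj))
  }
  preds <- preds[order(preds$doc_id, preds$section, preds$start), , drop = FALSE]
  rownames(preds) <- NULL
  class(preds) <- c("chem_annotations", "data.frame")
  preds
}

#' Write a generated corpus to a directory
#'
#' Emits `abstracts.tsv`, `annotations.tsv` and `lexicon.txt`.
#'
#' @param corpus result of [generate_corpus()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abstracts(corpus$docs, file.path(dir, "abstracts.tsv"))
  write_annotations(corpus$gold, file.path(dir, "annotations.tsv"))
  writeLines(corpus$lexicon$terms, file.path(dir, "lexicon.txt"),
             useBytes = FALSE)
  invisible(dir)
}
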