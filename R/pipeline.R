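#' Build labeled training data from preprocessed sequences
#'
#' Pairs every sentence token sequence with its BIO labels (from the gold
#' annotations intersecting it) and its feature set.
#'
#' @param seqs token sequences from [preprocess_corpus()]
#' @param gold gold `chem_annotations`
#' @param lexicon optional `chem_lexicon`
#' @param config a [feature_config()]
#' @return list of `list(features, labels, tokens)` ready for [train_crf()]
#' @export
make_training_data <- function(seqs, gold, lexicon = NULL,
                               config = feature_config()) {
  lapply(seqs, function(toks) {
    lo <- min(toks$start); hi <- max(toks$end)
    g <- gold[gold$doc_id == attr(toks, "doc_id") &
                gold$section == attr(toks, "section") &
                gold$start < hi & gold$end > lo, , drop = FALSE]
    list(features = build_features(toks, lexicon, config),
         labels = encode_bio(toks, g),
         tokens = toks)
  })
}

#' Train the full tagging pipeline on a corpus
#'
#' Convenience wrapper: preprocess, featurize, and train one CRF per
#' requested order.
#'
#' @param docs abstracts data frame
#' @param gold gold `chem_annotations`
#' @param lexicon optional `chem_lexicon`
#' @param orders CRF orders to train (default c(1, 2))
#' @param config a [feature_config()]
#' @param tagger linguistic tagger
#' @param ... passed to [train_crf()]
#' @return named list of `crf_model`s ("order1", "order2", ...)
#' @export
train_pipeline <- function(docs, gold, lexicon = NULL, orders = c(1, 2),
                           config = feature_config(),
                           tagger = default_tagger(), ...) {
  seqs <- preprocess_corpus(docs, tagger)
  td <- make_training_data(seqs, gold, lexicon, config)
  models <- lapply(orders, function(o)
    train_crf(td, order = o, feature_config = config, ...))
  names(models) <- paste0("order", orders)
  models
}

#' Annotate a corpus with one or more CRF models
#'
#' Decodes every model, harmonizes the annotation sets, applies the
#' post-processing chain (parentheses filter, abbreviation resolution,
#' optional exclusion list), and returns the final annotations.
#'
#' @param docs abstracts data frame
#' @param models list of `crf_model`s sharing a feature configuration
#' @param lexicon optional `chem_lexicon`
#' @param exclusion optional `exclusion_list`
#' @param tagger linguistic tagger
#' @return post-processed `chem_annotations`
#' @export
annotate_corpus <- function(docs, models, lexicon = NULL, exclusion = NULL,
                            tagger = default_tagger()) {
  if (inherits(models, "crf_model")) models <- list(models)
  cfgs <- lapply(models, function(m) m$feature_config)
  for (cfg in cfgs[-1])
    if (!identical(cfg$enabled_groups, cfgs[[1]]$enabled_groups))
      stop("models do not share a feature configuration")
  seqs <- preprocess_corpus(docs, tagger)
  sets <- lapply(models, decode_corpus, seqs = seqs, lexicon = lexicon)
  anns <- harmonize(sets)
  postprocess(anns, docs, exclusion)
}
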