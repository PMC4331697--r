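test_that("word shape maps character classes as documented", {
  expect_equal(word_shape("Abc:1234"), "Aaa#1111")
  expect_equal(word_shape("aspirin"), "aaaaaaa")
  expect_equal(word_shape("CaCl2"), "AaAa1")
  expect_error(word_shape(""), "empty")
})

test_that("orthographic features cover capitalization, counts, symbols, greek", {
  f <- orthographic_features("NSAIDs")
  expect_true("CAP=MixedCase" %in% f)
  expect_true("DIGITS=NoDigit" %in% f)
  expect_true("CAPS=ThreeOrMoreCap" %in% f)

  f2 <- orthographic_features("alpha-2")
  expect_true("GREEK=alpha" %in% f2)
  expect_true("SYM=Dash" %in% f2)
  expect_true("DIGITS=OneDigit" %in% f2)

  f3 <- orthographic_features("aspirin")
  expect_true(all(c("CAP=LowerCase", "DIGITS=NoDigit", "CAPS=NoCap") %in% f3))

  expect_true("GREEK=beta" %in% orthographic_features("β"))
  expect_true("SYM=Parenthesis" %in% orthographic_features("(R)"))
  expect_true("CAP=SingleCap" %in% orthographic_features("K"))
  expect_true("CAP=AllCaps" %in% orthographic_features("DNA"))
  expect_true("CAP=StartCap" %in% orthographic_features("Aspirin"))
})

test_that("morphological features enumerate affixes and n-grams with length guards", {
  cfg <- feature_config(ngram_lengths = 2:3, affix_lengths = 2:3)
  f <- morphological_features("acid", cfg)
  expect_true(all(c("P2=ac", "P3=aci", "S2=id", "S3=cid") %in% f))
  expect_true(all(c("NG2=ac", "NG2=ci", "NG2=id", "NG3=aci", "NG3=cid") %in% f))

  f2 <- morphological_features("Na", feature_config())
  expect_equal(sort(f2[grepl("^(P[0-9]|S[0-9]|NG)", f2)]),
               sort(c("P2=Na", "S2=Na", "NG2=Na")))

  f3 <- morphological_features("K", feature_config())
  expect_equal(f3, "SHAPE=A")
})

test_that("dictionary matching is leftmost-longest on token boundaries", {
  toks <- tokenize("We tested acetylsalicylic acid today")
  lex <- as_lexicon(c("acetylsalicylic acid"))
  f <- dictionary_features(toks, lex)
  expect_equal(f[[3]], "LEXICON=B")
  expect_equal(f[[4]], "LEXICON=I")
  expect_equal(lengths(f[c(1, 2, 5)]), c(0L, 0L, 0L), ignore_attr = TRUE)

  # longest match wins over a shorter overlapping term
  lex2 <- as_lexicon(c("acid", "acetylsalicylic acid"))
  expect_equal(dictionary_features(toks, lex2), f)

  # case-insensitive
  lex3 <- as_lexicon("ASPIRIN")
  toks3 <- tokenize("We tested aspirin")
  expect_equal(dictionary_features(toks3, lex3)[[3]], "LEXICON=B")

  expect_equal(lengths(dictionary_features(toks, NULL)), rep(0L, 5))
})

test_that("context conjunctions concatenate attributes across windows", {
  toks <- annotate_linguistics(tokenize("We tested aspirin"), default_tagger())
  cfg <- feature_config(context_windows = list(c(-1L, 0L)))
  f <- context_features(3, toks, "conjunctions", cfg)
  expect_true("CONJ[-1,0]lemma=tested|aspirin" %in% f)
  expect_true("CONJ[-1,0]pos=VBD|NN" %in% f)

  # boundary placeholders
  f0 <- context_features(1, toks, "conjunctions",
                         feature_config(context_windows = list(c(-3L, -1L))))
  expect_equal(f0[1], "CONJ[-3,-1]lemma=BOS|BOS|BOS")

  fw <- context_features(3, toks, "windows",
                         feature_config(enabled_groups = c("token", "context_windows"),
                                        context_windows = list(c(0L, 1L))))
  expect_true("WIN[0,1]lemma@1=EOS" %in% fw)
  expect_true("WIN[0,1]pos@0=NN" %in% fw)
})

test_that("build_features honors group configuration exactly", {
  toks <- annotate_linguistics(tokenize("We tested aspirin"), default_tagger())
  only_token <- feature_config(enabled_groups = "token")
  f <- build_features(toks, NULL, only_token)
  expect_equal(lengths(f), rep(1L, 3))
  expect_equal(f[[3]], "W=aspirin")

  # disabling a group removes all and only its features
  cfg_all <- feature_config(enabled_groups = setdiff(ALL_FEATURE_GROUPS,
                                                     c("context_windows", "dictionary",
                                                       "dependency")))
  cfg_nosuf <- disable_groups(cfg_all, "suffix")
  fa <- build_features(toks, NULL, cfg_all)
  fb <- build_features(toks, NULL, cfg_nosuf)
  for (i in 1:3) {
    removed <- setdiff(fa[[i]], fb[[i]])
    expect_true(all(grepl("^S[0-9]+=", removed)))
    expect_equal(setdiff(fb[[i]], fa[[i]]), character(0))
  }

  # default best config carries no dependency or capitalization features
  fd <- build_features(toks, NULL, feature_config())
  expect_false(any(grepl("^(DEP|CAP=)", unlist(fd))))

  # extraction is pure
  expect_identical(build_features(toks, NULL, cfg_all),
                   build_features(toks, NULL, cfg_all))
})

test_that("every enabled group can produce at least one feature", {
  txt <- "Domain alpha-Fe2O3 compounds like 2-acetoxybenzoic acid react"
  toks <- annotate_linguistics(tokenize(txt), default_tagger())
  toks$dep_label <- "mod"; toks$dep_head <- 1L
  lex <- as_lexicon("acid")
  cfg <- feature_config(enabled_groups = setdiff(ALL_FEATURE_GROUPS,
                                                 "context_windows"))
  feats <- unlist(build_features(toks, lex, cfg))
  prefixes <- c(token = "W=", lemma = "LEMMA=", pos = "POS=", chunk = "CHUNK=",
                dependency = "DEPLBL=", capitalization = "CAP=",
                counting = "DIGITS=", symbols = "SYM=", greek = "GREEK=",
                char_ngrams = "NG", suffix = "S2=", prefix = "P2=",
                word_shape = "SHAPE=", dictionary = "LEXICON=",
                context_conjunctions = "CONJ")
  for (g in names(prefixes))
    expect_true(any(startsWith(feats, prefixes[[g]])), info = g)
})

test_that("windows and conjunctions are mutually exclusive", {
  expect_error(feature_config(enabled_groups = c("token", "context_windows",
                                                 "context_conjunctions")),
               "mutually exclusive")
})

test_that("missing linguistic attributes skip their groups with a warning", {
  toks <- tokenize("We tested aspirin")  # no tagger: lemma/pos/chunk NA
  cfg <- feature_config(enabled_groups = c("token", "pos"))
  expect_warning(f <- build_features(toks, NULL, cfg), "pos")
  expect_equal(lengths(f), rep(1L, 3))
})
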