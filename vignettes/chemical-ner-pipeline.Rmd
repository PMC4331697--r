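---
title: "A CRF pipeline for chemical named-entity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A CRF pipeline for chemical named-entity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`chemtagr` recognizes chemical and drug name mentions in scientific
abstracts: it labels tokens with the BIO scheme using linear-chain
conditional random fields (CRFs), combines models of different label order,
repairs characteristic model errors, and emits confidence-ranked
mention-level (CEM) and document-level (CDI) outputs. This vignette explains
the model, its parameters and the design choices behind them.

## The model and its assumptions

A document is two independent text sections (title, abstract); offsets are
0-based, end-exclusive Unicode code-point positions counted per section —
the convention of the CHEMDNER corpus distribution. Sections are split into
sentences, each sentence into tokens, and a CRF labels each token B, I or O.

The CRF is a standard linear-chain model: per-token feature vectors interact
with the label, plus label-transition weights, trained by penalized maximum
likelihood. Its core assumptions are (i) mentions respect token boundaries
(gold spans whose ends fall inside a token are snapped outward to the
covering tokens, with a warning, rather than dropped — this preserves
training signal at the cost of slightly longer spans); (ii) sentences are
independent given their features; and (iii) all chemical classes can be
merged into a single mention class for tagging, which is why evaluation can
only report per-class *recall*, never per-class precision.

**Order-2 models** condition on the two previous labels. Rather than a native
higher-order implementation, labels are expanded to consecutive-pair states
(`BOS|O`, `O|B`, `B|I`, ...) and a first-order chain is trained over them —
the same model family, much simpler machinery. Structural masks keep every
decode a valid BIO sequence (no `O → I`, no sequence-initial `I`).
**Backward parsing** reverses each token sequence before training and
re-reverses at decode; BIO runs are re-encoded so the first token of a run in
the parsing direction carries B.

**Confidence.** Each annotation's confidence is the marginal posterior
probability of its exact label subsequence over its span: the ratio of the
constrained to the unconstrained partition function, computed by a masked
forward recursion. This is a true probability in [0, 1] and is verified in
the tests against brute-force enumeration of all `3^n` label sequences on
short sentences (agreement to 1e-9). A cheaper product-of-token-marginals
score would not be a coherent probability of the span labeling, which is why
the constrained-marginal definition is the default and only implementation.

**Harmonization.** When several models annotate the same text, annotations
that overlap nothing from another model are all kept; where spans conflict,
resolution is greedy in priority order (confidence descending, then earlier
start, longer span, lexicographically smaller model id), accepting an
annotation only if it overlaps no already-accepted one. For three or more
chain-overlapping annotations a "keep the best of each mutually-intersecting
group" rule can produce overlapping output depending on how groups are
drawn; the greedy formulation avoids that, reproduces the natural forced
cases (highest confidence wins pairwise; disjoint spans all survive), is
idempotent, and always yields a non-overlapping set. Fully specified
tie-breaks matter because equal confidences do occur.

## Sentence splitting and tokenization

Sentences end at `.`, `!` or `?` followed by whitespace and an uppercase
letter or digit, unless the word ending in the period is on a packaged,
user-replaceable abbreviation exception list (`e.g.`, `et al.`, `Fig.`, ...).

Tokenization is chemistry-aware: a base pass keeps letters, digits and
`' + . / -` together and isolates every other non-space character, then any
token containing `/`, `-` or `.` is re-split so each such symbol becomes its
own single-character token (`Ca2+/calmodulin → Ca2+, /, calmodulin`;
`2-acetoxybenzoic → 2, -, acetoxybenzoic`). Two decisions here were
genuinely open:

- **Decimal numbers are exempt** from the period split when the pattern is
  `digit.digit` (`0.5 mg/kg`): splitting them would destroy dose and
  quantity tokens, and the split rule targets chemical names, not numerals.
- **The symbol becomes its own token** (rather than merely breaking at it),
  which keeps offsets exact and matches the behaviour of biomedical NER
  tokenizers that motivated the rule.

Linguistic attributes (lemma, POS, chunk, dependency) come from a pluggable
tagger contract. The package ships a deterministic rule-based fallback
(lexicon- and suffix-driven POS, a small NP/VP chunker, lowercase lemmas) so
everything runs with no external tool; a GENIA/GDep-style tagger can be
plugged in through the same contract, including via a tab-separated
token-attribute exchange file for external processes. The fallback's tags
are crude but consistent, which is what conjunction features mostly need;
fidelity-sensitive users should plug in a real tagger.

## Feature groups and defaults

| group | example | default |
|---|---|---|
| token | `W=aspirin` | on |
| lemma / pos / chunk | `LEMMA=aspirin`, `POS=NN`, `CHUNK=B-NP` | on |
| dependency | `DEPLBL=nsubj`, `DEPHEAD=inhibit` | **off** |
| capitalization | `CAP=StartCap` | **off** |
| counting | `DIGITS=TwoDigit`, `CAPS=NoCap` | on |
| symbols | `SYM=Dash`, `SYM=Parenthesis` | on |
| greek | `GREEK=alpha` (names and glyphs) | on |
| prefix / suffix | `P3=asp`, `S3=rin` (lengths 2–4) | on |
| char n-grams | `NG3=spi` (lengths 2–4) | on |
| word shape | `SHAPE=Aaa#1111` | on |
| dictionary | `LEXICON=B/I` | on |
| context | `CONJ[-1,0]lemma=of|aspirin` | conjunctions |

The default configuration disables dependency and capitalization features
and uses conjunctions (not windows) — the configuration that evaluated best
in the feature-elimination study this pipeline reimplements. Counting
features are binned (0, 1, 2, ≥3) rather than raw counts. Affix lengths
default to the n-gram lengths {2, 3, 4}. Dictionary matching is
case-insensitive after Unicode NFKC normalization, aligned to token
boundaries, resolved leftmost-longest. Conjunctions concatenate lemma and
POS (not chunk) across each window with a reserved `|` separator and carry
the window identity in the feature name; window features copy lemma, POS
and chunk tagged with their relative offset; both use BOS/EOS placeholders
at sentence edges, and enabling both encodings at once is an error. The
iterative elimination protocol (`iterative_feature_elimination()`) retrains
one model per candidate single-group removal each round, removes the group
whose removal most improves exact F1 on the development split, stops when
nothing improves, and protects the token group from removal.

## Training parameters

| parameter | default | meaning |
|---|---|---|
| `sigma2` | 1.0 | Gaussian prior variance; the L2 penalty is `||w||²/2σ²` |
| `maxit` | 500 | L-BFGS iteration cap (`factr = 1e8`, i.e. ~1e-8 relative tolerance) |
| `order` | 1 | label history; 2 via pair-state expansion |
| `direction` | forward | backward available behind a flag |
| `seed` | 42 | recorded in metadata; training itself is deterministic given data order |

Weights initialize at zero; the objective is convex, so the optimum does not
depend on initialization. Orders above 2 are deliberately unsupported:
training cost grows exponentially with order and higher orders added nothing
in the study this package follows.

## Post-processing

Order of operations: parentheses filter → abbreviation resolution →
optional exclusion list.

1. **Parentheses filter**: an annotation whose text contains an odd total of
   `( ) [ ] { }` is removed — an unbalanced bracket is always a boundary
   error.
2. **Abbreviation resolution**: candidate short forms are parenthesized
   strings of 2–10 characters, at most two words, at least one letter,
   alphanumeric first character. The long form is found by matching
   short-form characters right-to-left in the text before the parenthesis,
   first character anchored at a word start. Chemistry short forms often
   reorder letters (*EtOH* for *ethanol* — the 'O' has nothing to match left
   of the matched 'h'), so when the strict scan fails, the single token
   immediately preceding the parenthesis is accepted if it shares the short
   form's initial letter. If exactly one form of a pair is annotated, the
   other is added with the same confidence (source `"abbrev"`); partial
   coverage of a form is expanded to the form's full span; duplicate spans
   merge keeping the maximum confidence. Resolution never removes
   annotations.
3. **Exclusion list**: every distinct lowercased predicted mention is scored
   `ln((TP + 0.5)/(FP + 0.5))` against exact-span gold matches. The +0.5
   Haldane correction makes zero-TP mentions scorable with natural log;
   a mention joins the list iff its score is below `theta` (default 0.3) and
   it appeared at least `min_fp` (default 2) times as a false positive.
   `tune_exclusion_thresholds()` re-tunes both on a grid by 10-fold
   document-level cross-validation, maximizing mean ΔF1; ties prefer the
   smaller resulting list. Pure length-based filtering is deliberately not
   offered — short-mention filters trade far more recall than the precision
   they buy.

## Evaluation

Span matching comes in five modes — exact (both indices), left (start),
right (end), shared (either), overlap (any intersection) — with one-to-one
greedy matching per document and section: exact pairs are matched first,
remaining candidates by earliest start and longest overlap. Identical
predicted spans are merged before counting, so a duplicated prediction
cannot count twice (the official scorer's behaviour here is unspecified;
merging is the conservative choice). Precision, recall and F1 follow the
standard definitions and are reported as percentages, printed to two
decimals, half-up. CDI evaluation compares per-document string sets; CDI
deduplication is exact-string and case-sensitive, since document-indexing
gold is string-based.

## The synthetic corpus generator

`generate_corpus()` is the package's study environment: fully deterministic
given its seed, it builds abstracts from sentence templates with planted
mentions of all seven classes — systematic names from a
locant–stem–suffix grammar with optional parenthesized substituents,
formulas from an element/count grammar, trivial names from a ~200-entry
packaged list, abbreviation definitions as "long form (SHORT)" sentences,
registry-style identifiers, pluralized family names, and coordinated
multiple mentions. Defaults (chosen once, as the study conditions): class
mix SYSTEMATIC .22 / TRIVIAL .30 / ABBREVIATION .15 / FAMILY .14 /
FORMULA .10 / IDENTIFIER .05 / MULTIPLE .04, roughly CHEMDNER-like;
mentions per document negative-binomial with mean 6 and dispersion 8;
`abbrev_rate` 0.6. ABBREVIATION mass drawn inside ordinary templates is
remapped to TRIVIAL and realized instead through dedicated definition
sentences, so every short form co-occurs with its definition and is
detectable by the recognizer; the pair "sodium chloride (NaCl)" is not in
the generator's list because no character-matching recognizer can align
NaCl with its long form, which would break the construction guarantee that
`abbrev_rate = 1` makes every document contain a detectable pair.

Homograph **trap terms** (*lead*, *iron*, *gold*, *zinc*) are planted both
as chemical mentions and inside non-chemical decoy sentences ("The lead
author..."), exercising context features and the exclusion-list machinery;
`corrupt_predictions()` turns gold into simulated predictions with seeded
false-negative deletion, trap-term false-positive injection (low
confidence) and token-boundary jitter, giving closed-form expectations for
evaluation tests.

What the generator does *not* emulate: real lexical diversity (template
variety is deliberately small), true CHEMDNER class frequencies and journal
style, annotation-guideline ambiguity, nested or overlapping gold spans,
and noisy linguistic attributes. Templated context makes mentions highly
learnable, so held-out scores on synthetic corpora (the test suite trains
on 200 documents and evaluates on 50 held-out documents; smaller corpora
elsewhere are sized to what each property needs) are an upper bound on, not
an estimate of, real-corpus performance. Passing tests demonstrate that the
machinery is correct — offsets exact, probabilities calibrated against
enumeration, protocols faithful — not that the model would reach any
particular F1 on real abstracts.

## Numerical choices and degenerate inputs

- All chain computations run in log space with log-sum-exp; structural
  impossibilities use a −1e30 sentinel rather than `-Inf` to avoid NaN in
  differences.
- Confidences are clamped at 1 (constrained/unconstrained log-partition
  differences can land a rounding error above 0).
- Unknown features at decode time are dropped; an `I` decoded after `O`
  (possible only on hand-built models) is repaired as `B` with a warning.
- Empty sections, empty sentences and empty prediction sets flow through
  every operation as empty results; training on an empty corpus, invalid
  BIO labels, overlapping gold spans, and rank sequences not contiguous
  from 1 are errors.
- Ranking ties break by section (title before abstract), then start, then
  end; CDI keeps the best-scoring occurrence of each string.

## Known limitations

- The fallback tagger is intentionally simple; POS/chunk-dependent features
  are only as good as the plugged-in tagger.
- Dependency features are implemented but off by default and unexercised by
  the fallback tagger (it provides no dependency capability).
- No entity normalization, no class prediction (single merged class), no
  statistical significance machinery, and no PubMed XML/full-text readers —
  the corpus dialect is the tab-separated CHEMDNER format.
- Exact replication of numbers reported on the licensed CHEMDNER corpus is
  out of reach without that corpus; the package's own reproducible numbers
  come from `scripts/acceptance.R` on synthetic data.
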