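---
title: "Feature engineering for drug name recognition: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature engineering for drug name recognition: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnr)
```

This vignette documents the scientific model behind `dnr`, the parameters
that matter, the design decisions taken where several reasonable options
existed, and what the synthetic benchmark does and does not establish.

## The labeling model

Drug name recognition is formulated as token-level sequence labeling.
Mentions of four entity types — `drug` (generic substances for human
use), `brand` (trade names), `group` (drug classes) and `no-human`
(substances not approved for human use) — are encoded over tokens with
the BILOU scheme: a single-token mention is `U-<type>`, a multi-token
mention is `B-<type>`, optional `I-<type>` tokens and a final `L-<type>`,
and everything else is `O`. With four types this yields a 17-tag label
alphabet. BILOU is preferred over the smaller BIO scheme because the
explicit last/unit distinctions give the model sharper boundary evidence,
which matters for the multi-token class names common in this domain.

The tagger is a linear-chain conditional random field: emission weights
tie each instantiated feature string to each label, plus a full
label-transition matrix and start/end weights. Two assumptions follow
from this formulation and are enforced rather than worked around:
mentions must align with token boundaries (misaligned annotations are an
error, with an opt-in boundary-snapping repair that is logged), and
mentions must not overlap or nest — one tag per token cannot represent
them, so they are rejected with a clear error instead of being silently
dropped.

### Estimation and decoding

The CRF's convex negative log-likelihood, with an L2 penalty
`0.5 * c2 * ||w||²`, is minimized by L-BFGS-B on analytic gradients
computed by forward–backward in the compiled core. Numerical choices:
forward variables are rescaled per position (with per-position max
shifting of the node potentials before exponentiation), so no sentence
length or weight magnitude can overflow; weights start at zero, making
training deterministic for a fixed instance set; the optimizer stops at a
relative objective change of about 1e-8 (`factr = 1e8`) or 200
iterations by default. Decoding is exact Viterbi. Features never seen in
training are ignored at prediction time. A predicted tag sequence can be
structurally invalid (e.g. `I` without `B`); decoding to mentions
therefore uses the lenient repair by default: a stray `I`/`L` opens (or
closes) an entity, an interrupted entity is closed at the last consistent
token, and every repair is counted and reported.

The only exposed training knob is the regularization coefficient `c2`,
tuned by default over the grid `{0.5, 0.6, ..., 1.5}` with 10-fold
cross-validation at the sentence level, selecting on strict-matching F1
(the primal criterion of DDI-style evaluations). Folds are assigned at
the sentence level because the sentence is the labeling unit here;
document-level blocking would matter for corpora with strong
within-document repetition and can be layered on top by the caller.
Whether tuning should be repeated per feature configuration is left to
the user; the tools support both.

## The feature system

### Singleton templates

Sixteen templates (`f1`–`f16`) each produce at most one feature string
per token: word identity; POS and chunk labels from a pluggable tagger;
an orthographic class plus a hyphen flag; three dictionary-membership
flags; an embedding-cluster id; prefixes and suffixes of lengths 3, 4
and 5; and two word shapes. Every enabled template is instantiated at all
five offsets of the `[-2, 2]` context window, with `__BOS__`/`__EOS__`
sentinels beyond sentence edges so that boundary positions remain
informative rather than silently absent.

Decisions where the definitions were genuinely open:

* **Orthographic classes** are assigned in the fixed precedence order
  All-capitalized → Is-capitalized → All-digits → Alphanumeric → Other,
  so each token gets exactly one class. "Alphanumeric" is interpreted as
  containing at least one letter and one digit, internal symbols allowed
  — this is an interpretation, chosen so that names like `interleukin-2`
  fall in the class their mixed surface suggests. The hyphen flag is a
  separate feature (emitted only at in-window, in-sentence positions).
* **Short-word affixes are omitted, not padded.** A padded affix of a
  2-character word would duplicate the word feature under several
  template ids and inflate the feature space with synonyms.
* **Dictionary membership is per word**, case-insensitive: a token
  matches if it equals a single-word term or any whitespace-delimited
  word of a multiword term. Dictionaries are plain word sets behind a
  small class, so real resources drop in without code changes.
* **The POS/chunk provider is a contract**, not a dependency: any
  function mapping a token vector to equal-length `pos` and `chunk`
  vectors qualifies, and the bundled `simple_tagger()` is a deterministic
  rule-based provider (closed-class lists, suffix rules, noun-phrase
  runs) so the package is self-contained. Its labels are coarse; a real
  biomedical tagger should be attached for real corpora.
* **Embedding clusters**: words are clustered by k-means (k-means++-style
  seeding under a caller-supplied seed, Lloyd iterations via
  `stats::kmeans`, at most 300). The default `k = 400` reflects a grid
  search over `{100, ..., 1000}` semantic classes at full corpus scale;
  on small vocabularies `k` must be chosen proportionally (the synthetic
  pipeline uses one cluster per entity category by default). Out-of-vocabulary
  words map to the dedicated id `OOV`, keeping the feature total.

### Conjunction templates

Conjunctions pair two singleton features into one feature whose value is
the joined pair of member values. Only 2-tuples are shipped: the template
machinery represents general k-tuples, but higher orders multiply the
feature space beyond what selection can usefully prune. Two canonical
sets are provided: `S1`, the 12 adjacent-position bigrams of the word,
POS and chunk templates; `S2`, the 23 target-word pairs (all pairs among
`f2`–`f8`, plus word×POS and word×chunk — the word feature pairs only
with the syntactic features because word×surface pairs mostly reproduce
the word feature itself). Custom sets load from a one-template-per-line
text spec, so deliberately noisy sets (e.g. shape bigrams) can be built
for ablation without code changes. Two details guard correctness: member
values are escaped before joining (so a `_` inside a value cannot forge a
different pair), and a conjunction whose member is omitted (short-word
affix) is suppressed entirely — a half-empty pair carries nothing its
surviving member does not.

### Feature selection

Selection scores each distinct feature string against the coarse tag
variable `T ∈ {B, I, L, O, U}` — the positional letter, with types
dropped. Collapsing is the documented protocol choice (the CRF still
predicts all 17 typed tags); scoring against typed tags is available
behind a flag. Events are token occurrences; counts come from training
data only, never from test data.

Three statistics are implemented on the 2×2 contingency counts of
(feature present/absent) × (tag = t / tag ≠ t): Chi-square with expected
counts from the marginals (degenerate marginals score 0 by convention,
and note a feature *anti*-correlated with a tag scores high too — the
statistic measures dependence, not direction); plug-in mutual information
in bits with `0·log 0 := 0`; and information gain
`H(T) − H(T|e_f)` over the 5-valued tag variable. Chi-square and MI
aggregate over tags by the maximum; IG is already global.

Retention keeps the top `round(p·N)` features, rounding half away from
zero (at `p = 0.4` this maps 294 782 features to exactly 117 913, the
reference behavior the implementation pins down). Ties are broken by the
fixed order (score descending, feature string ascending), which makes
the retained subset reproducible and monotone in `p`.

## Evaluation

Entity-level scoring implements the four DDI-style criteria: strict
(boundary and type), exact (boundary only), type (character overlap ≥ 1
and same type) and partial (overlap only). Matching is one-to-one; the
pairing rule — gold mentions in document order, each taking the first
unconsumed qualifying prediction — is a design decision, since the
challenge's exact rule is not published. For non-overlapping mention
sets (the only kind this package produces, and the common case in gold
data) the greedy rule attains the maximum matching; an exhaustive
optimal matcher is included and used as an oracle in the tests rather
than trusted by construction. Zero denominators score 0. Scores are
micro-averaged over documents and reported as percentages.

## The synthetic benchmark: what it shows and what it cannot

`generate_corpus()` emulates the structure that makes DNR learnable:
entity names built from morpheme inventories with type-characteristic
suffixes (`-mab`, `-vir`, `-cillin`, ... for drugs; capitalized coinages
for brands; plural class heads, optionally with modifiers, for groups;
`-thion`, `-fos`, ... for non-human substances), mentions of 1–3 tokens
embedded in templated pharmacological sentence frames, a type mixture
skewed like real corpora (defaults: drug 64%, group 23%, brand 9%,
no-human 4%, derived from published corpus statistics), noise tokens at
rate 0.05, and an ambiguous-use rate of 0.1 at which a drug name appears
unannotated in an endogenous-substance frame (the classic "insulin"
ambiguity), which is precisely the case where context conjunctions earn
their keep. Dictionaries cover an exact, seeded fraction (default 0.8)
of the distinct name vocabulary per word stratum, so the realized
token-level hit rate concentrates around the nominal coverage; the three
dictionaries are independent draws and therefore overlap without
coinciding. Embeddings place each word near a Gaussian center shared by
its category, with 5% of the vocabulary withheld to exercise the OOV
path. One global seed fans out to per-component streams through a fixed
derivation, so corpus, dictionaries and embeddings are independently
reproducible.

What the generator does **not** emulate: real biomedical prose (frames
are templated and short), nested or discontinuous mentions, genuinely
ambiguous type boundaries between drugs and groups, tagger errors
correlated with entity content, Zipfian vocabulary growth, or
dictionary noise (misspellings, partial terms). Consequently, passing
the end-to-end bar here demonstrates that the pipeline is wired
correctly — features carry the planted signal through selection and
training to decoding — not that any particular F-score would transfer to
a real corpus. On real data, performance is dominated by resource
quality (tagger, dictionaries, embedding corpus), which this package
deliberately treats as replaceable inputs.

Problem sizes were chosen to keep the full check suite at desk scale:
the end-to-end benchmark trains on 300 sentences and tests on 100 (one
generator run, split — dictionaries and embeddings are external-style
resources shared by both sides), property tests run hundreds to a
thousand randomized cases under fixed seeds, and cross-validation tests
use reduced grids and fold counts while the defaults remain the
full protocol.

## Known limitations

* The CRF backend is the package's own implementation; it supports L2
  regularization only. The published protocol's "regularization
  coefficient" is mapped onto the L2 penalty weight — L1/elastic-net
  sparsity is not available.
* Feature strings are interned as plain character vectors; corpora far
  beyond desk scale would want hashed feature indices.
* The lenient BILOU repair is one of several defensible conventions;
  strict mode exists precisely so disagreements surface as errors.
* `simple_tagger()` is intentionally minimal. Its chunk labels make the
  chunk-based features coarse; conclusions about the relative value of
  syntactic features should not be drawn from the bundled tagger.
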