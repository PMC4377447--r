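# dnr — drug name recognition with conjunction features and feature selection

`dnr` is an R package for recognizing mentions of pharmacological
substances in biomedical text and typing them as **drug**, **brand**,
**group** or **no-human**. It is aimed at text-mining practitioners who
want a transparent, fully inspectable feature-engineering pipeline for
drug-name recognition (DNR) rather than an opaque end-to-end model.

## The method

DNR is cast as sequence labeling: every token of a sentence receives a tag
from the BILOU scheme (Begin / Inside / Last / Outside / Unit-length),
crossed with the four entity types — 17 tags in all. A linear-chain
conditional random field models

```
p(y | x) ∝ exp Σ_t [ Σ_k w_k f_k(x, t, y_t) + T(y_{t-1}, y_t) ]
```

and is estimated by L2-penalized maximum likelihood; the regularization
coefficient is tuned over {0.5, 0.6, …, 1.5} by 10-fold cross-validation
on strict entity F1.

The features `f_k` come from three stages:

1. **Singleton templates** (`f1`–`f16`): word identity, POS, chunk,
   orthographic class + hyphen flag, membership in three drug
   dictionaries, a k-means cluster id of the word's embedding vector,
   prefixes/suffixes of length 3–5, and generalized/brief word shapes
   (`"Aspirin1+"` → `"Xxxxxxx0O"` / `"Xx0O"`). Each template is
   instantiated at every offset of the 5-token context window.
2. **Conjunction templates**: 2-tuples of singleton features. Set **S1**
   (12 templates) pairs adjacent window positions of the word/POS/chunk
   features, `f_i[m]_f_i[m+1]`; set **S2** (23 templates) pairs different
   feature types at the target word.
3. **Feature selection**: every instantiated feature is scored against the
   coarse tag variable T ∈ {B, I, L, O, U} by Chi-square, mutual
   information (both aggregated as `I(f) = max_t score(f, t)`) or
   information gain `IG(f) = H(T) − H(T | e_f)`, and the top fraction `p`
   is retained (at `p = 0.4`, 294 782 features reduce to exactly 117 913).

Predictions are scored at the entity level under four matching criteria —
strict (boundary + type), exact (boundary only), type (typed overlap) and
partial (any overlap) — with one-to-one matching, micro-averaged P/R/F1,
and per-type breakdowns.

Because the real challenge corpora, taggers and dictionaries are external
licensed resources, the package ships a seeded generator of DDI-style
corpora, dictionaries (partial coverage) and embedding tables with planted
type-correlated signal, so every stage is testable offline.

## Worked example

```r
library(dnr)

cfg  <- simulate_config(seed = 1, n_sentences = 400)
res  <- generate_resources(cfg)     # corpus + dictionaries + embeddings
res$corpus[[2]]
#> <dnr_sentence [s2] >
#>   coadministration of b.i.d praduvir and proton pump corticosteroids increased plasma exposure .
#>   tokens: 12, mentions: 2
#>     [26,34) drug: praduvir
#>     [39,66) group: proton pump corticosteroids

fconf <- feature_config(dictionaries = res$dictionaries,
                        clusters     = res$clusters,
                        conjunctions = rbind(build_S1(), build_S2()))
inst  <- assemble_instances(res$corpus[1:300], fconf)
model <- crf_train(inst, c2 = 1.0)
model
#> <dnr_crf: 10629 features, 17 labels, c2 = 1>

cf   <- corpus_features(res$corpus[1:300], fconf)
imp  <- feature_importance(cf$features, cf$tags, statistic = "ig")
head(imp, 3)
#>               feature     score
#> 1             f8[0]=1 0.3027852
#> 2 f3[-1]_f3[0]=O_B-NP 0.2708898
#> 3 f4[0]_f8[0]=Other_1 0.2593237
keep <- select_top_fraction(imp, p = 0.4)
length(keep)
#> [1] 4252

gold <- lapply(res$corpus[301:400], `[[`, "mentions")
pred <- crf_predict_mentions(model, res$corpus[301:400], fconf)
round(score_mentions(gold, pred, "strict"), 2)
#>  TP  FP  FN   P   R  F1
#> 117   0   0 100 100 100
```

The importance table reads naturally: the most informative features here
are the target word's embedding cluster (`f8[0]`), a chunk bigram from S1
and a cross-type conjunction from S2 — the planted corpus makes entity
tokens separable by semantics, syntax and morphology, and the selector
finds exactly those features. `score_mentions` reports entity-level counts
and percentages: all 117 test mentions are recovered with correct
boundaries and types.

A command-line wrapper with `simulate`, `train`, `label` and `evaluate`
subcommands lives in `inst/cli/dnr.R`.

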