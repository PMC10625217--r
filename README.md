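# guidescreen

Automatic literature screening for clinical practice guideline (CPG)
development.

CPGs are built on evidence drawn from published articles, and keeping them
current means repeatedly screening tens of thousands of candidate records —
a task usually done by hand by senior domain experts. `guidescreen` treats
screening as a binary classification problem: articles cited by the extant
guidelines and systematic reviews are positives, everything else retrieved
by the topic query is negative, and a trained classifier ranks new articles
by their probability of being guideline-worthy so reviewers can read down a
short ranked list instead of the whole retrieval.

The package covers the full pipeline:

* **Corpus construction** — fuzzy key-phrase screening of titles and
  abstracts (phrase words must appear in order with at most 3 intervening
  words; e.g. *"cervical spine joint pain"* matches the phrase
  `cervical pain` with a gap of 2), deduplication, removal of records
  without resolvable journal metadata, labelling against a cited-id list,
  and uniform downsampling of the negative class to a 3:7 ratio.
* **Feature encoding** — titles and abstracts are embedded per article; a
  journal's bibliometrics (impact factor 2015–2021, CiteScore, SJR, SNIP,
  ranking zone, H-index) are z-scored with training-split statistics,
  median-imputed with missingness flags, and passed through a feed-forward
  ReLU encoder.
* **Batch-level inter-sample attention** — with batch embeddings
  `r = [r_1, …, r_s]ᵀ`, the model forms `Q = rW^Q`, `K = rW^K`, `V = rW^V`
  and re-represents each article as `R_i = α_i V` with
  `α_i = softmax(q_i Kᵀ)`, so every article's text representation is a
  convex mixture over its batch-mates — the model learns from the subtle
  contrasts between articles, not just from each article in isolation.
* **Focal-loss classification** — the fused feature
  `X_i = (R_i, N_i, J_i)` feeds a two-class softmax head trained under the
  focal loss `FL(i) = −α̃ (1 − p̃_i)^γ log p̃_i` (defaults γ = 2, α = 0.8),
  which down-weights easy samples so the scarce positives are not drowned
  out.
* **Evaluation and screening** — confusion-matrix metrics (precision,
  recall, specificity, accuracy, F1), trapezoidal ROC AUC and average
  precision; model comparison in percentage points; and ranked screening
  at a configurable probability threshold.
* **Synthetic data** — a seeded generator producing corpora with planted
  keyword and journal-quality signal, so the whole pipeline runs and is
  tested entirely offline.

## Worked example

```r
library(guidescreen)

# synthetic screening corpus: 180 guideline-cited positives, 420 negatives,
# planted keyword + journal-quality signal
synth <- generate_corpus(synth_config(seed = 42))

built <- build_corpus(synth$records, synth$journals, synth$positive_ids,
                      target_pos_frac = 0.3, seed = 42)
built$counts
#>         screened     deduplicated journal_filtered         positive
#>              600              600              600              180
#>         negative      downsampled
#>              420              600

split <- split_dataset(built$corpus, train_frac = 0.8, seed = 42)
model <- train_screener(split$train, synth$journals,
                        screener_config(epochs = 20, seed = 42))
model
#> <screener_model> features: title+abstract+journal | d = 64 | 20 epoch(s) trained
#>   loss: 0.0399 -> 0.0006

preds  <- predict_screener(model, split$test)
evaluate_predictions(preds$prob, split$test$label, threshold = 0.5)
#> <metrics_report> n = 120 at threshold 0.50
#>   TP 30  TN 82  FP 2  FN 6
#>   precision     93.75%
#>   recall        83.33%
#>   specificity   97.62%
#>   accuracy      93.33%
#>   f1            88.24%
#>   auc           97.09%

head(rank_screen(model, split$test, threshold = 0.3), 5)
#>       id probability rank retained
#> 1 A00152   0.9999987    1     TRUE
#> 2 A00005   0.9999957    2     TRUE
#> 3 A00017   0.9999734    3     TRUE
#> 4 A00112   0.9999343    4     TRUE
#> 5 A00124   0.9998950    5     TRUE
```

The counts show every generated record passing the key-phrase screen (600
of 600), the 180/420 labelling, and the corpus already at the 3:7 target
ratio. After 20 epochs the training focal loss has fallen two orders of
magnitude, and on the 120 held-out articles the model reaches 97.1% ROC
AUC; at a lowered screening threshold of 0.3 the ranked list puts the
most guideline-worthy candidates first.

A thin command-line wrapper with subcommands `synth`, `build-corpus`,
`train`, `evaluate` and `screen` lives at `inst/cli/guidescreen.R`.

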