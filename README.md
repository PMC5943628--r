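# clinrelex

Clinical relation extraction for medication and adverse drug event (ADE)
surveillance. Given clinical notes whose entity mentions are already
annotated (nine types: Medication, Indication, ADE, Severity, Dosage,
Route, Frequency, Duration, and relation-free OtherSS), clinrelex decides
which of seven relation types holds for a mention pair — the drug-attribute
relations `Dosage`, `Route`, `Frequency`, `Duration`, the causal relations
`Indication` and `Adverse`, and `Severity` — or `None`. Relations are
classified both within and across sentence boundaries, which matters
because medication–ADE and medication–indication pairs are often sentences
apart while drug attributes hug the drug name.

Three extractor families share one candidate-generation and evaluation
protocol:

* **Rule induction baseline** — classify a pair by which per-type
  average-distance bin its token distance falls in: bins `(m_{i-1}, m_i]`
  over the type means `m_i` fitted on training positives.
* **Linear SVM** — one-vs-rest linear machines over sparse features:
  document-level entity frequencies; token distance and mentions-between;
  TF-IDF-weighted word 1/2/3-grams between and around the pair
  (`idf = ln(N/df)`, fitted on training documents only); one-hot entity
  types and character 2/3-grams; dictionary-based semantic types;
  Brown-cluster prefixes, k-means word-vector classes and mean mention
  embeddings. Regularization grid-searched on the dev split, refit on
  train+dev.
* **Neural extractors** — per-entity LSTM encoders over the `L`-token
  window ending at the mention head, with gates
  `c_t = f ⊙ c_{t-1} + i ⊙ i'`, `h_t = o ⊙ tanh(c_t)`; optional
  bidirectionality (concatenated outputs, widths `2k`); optional global
  attention `a = softmax(wᵀ tanh(W₁S + W₂h_L 1ᵀ))`, `z = S aᵀ`,
  `h' = tanh(W₃z + W₄h_L)`; MLP composition plus softmax layer; and an
  augmented variant that embeds bucketed token/mention distances and
  mention types. Trained with ADAM, input/output dropout, decoupled l2
  weight decay, dev-based epoch selection — all backpropagation derived and
  implemented in the package and verified against numerical gradients.

Scoring is macro-averaged precision/recall/F1 over the seven positive
types (`p = TP/(TP+FP)`, `r = TP/(TP+FN)`, `F1 = 2pr/(p+r)`, 0/0 := 0);
`None` never enters the macro.

The annotated clinical corpus this framework targets is not distributable,
so the package ships a synthetic corpus generator that emulates its
statistical structure — per-type relation frequencies, a right-skewed
token-distance distribution with mean ≈ 7 and a long intersentential tail,
long-distance Indication/Adverse relations — and every stage is tested
end to end against generated data. I/O follows the field's standard
formats: BRAT-style standoff annotation (`.txt` + `.ann`), word2vec text
embeddings, and Brown-cluster paths files.

## Worked example

```r
library(clinrelex)

corpus <- generate_corpus(gen_config(n_docs = 60, relations_per_doc = 8, seed = 11))
corpus_stats(corpus)
#> <corpus: 60 docs, 425 relations, mean distance 6.56, max 69>
#>     Dosage      Route  Frequency   Duration Indication    Adverse   Severity
#>         86         74         95         13         86         19         52

data <- prepare_experiment(corpus, corruptions_per_side = 2, keep_rate = 0.5, seed = 1)

rule <- train_system("rule", data)
svm  <- train_system("svm", data, svm_grid = c(0.1, 1, 10), seed = 1)
score(data$test$label, predict_system(rule, data$test, data$docs))$macro_f1
#> [1] 14.22
score(data$test$label, predict_system(svm, data$test, data$docs))$macro_f1
#> [1] 64.09
```

The rule baseline reaches a macro-F1 near 14 on the synthetic test split —
its distance bins cannot separate types with overlapping distance supports
— while the feature-engineered SVM, using the same candidates, scores 50
points higher; the gap mirrors the ordering reported for the original
clinical benchmark. Neural variants sit between the two at this reduced
scale and order as expected at 3-seed medians (LSTM ≤ BiLSTM ≤
BiLSTM+attention ≤ feature-augmented):

```r
nn <- train_system("bilstm-att-feat", data,
                   neural_opts = list(hidden = 32, window = 30, emb_dim = 32,
                                      epochs = 10, batch_size = 16, lr = 3e-3),
                   seed = 1)
score(data$test$label, predict_system(nn, data$test, data$docs))$macro_f1
#> [1] 63.63
```

A command-line front end wraps the same workflow
(`inst/cli/clinrelex.R generate|train|evaluate|sweep`), writing a
reproducibility manifest beside every output.

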