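# circlass

Sequence-feature classification of plant circular RNAs.

Plant circRNAs — covalently closed transcripts formed by back-splicing —
are easily confused with long noncoding RNAs: both are long and neither
codes for protein. `circlass` separates the two classes from sequence
alone, for bioinformaticians who already have candidate transcripts
(e.g. back-splice candidates from RNA-seq plus curated lncRNAs) and
want a tested, reproducible classifier rather than a pipeline of
one-off scripts.

The method maps each candidate to 543 features in three blocks and
feeds them to a 100-tree random forest:

* **k-mer composition (341)** — for every k-mer *i* of length
  *k* ∈ {1..4}, the length-scaled frequency *f*<sub>i</sub> =
  *x*<sub>i</sub>·*k*/*L* over overlapping windows, plus GC content;
* **ORF (2)** — length of the optimal six-frame ORF and its coverage
  ×10, X<sub>ORF</sub> = {10·L<sub>ORF</sub>/L, L<sub>ORF</sub>};
* **splice-junction sequence coding (200)** — the ±50 bp genomic
  windows around the two splice sites, encoded positionwise with
  {A:1, T:−1, C:2, G:−2} (N:0); lncRNA negatives use their transcript's
  genomic ends as the two sites.

Evaluation follows the stratified repeated ten-fold cross-validation
protocol (10 folds × 10 repeats, per-fold metrics averaged), reporting
recall, precision, accuracy, F1, MCC and ROC/PR curves. Dataset
preparation (redundancy removal at >95 % global-alignment identity,
keeping the longest representative, plus Tukey box-whisker length
filtering) and a seeded synthetic fixture generator with signal planted
in exactly the three feature families are included, so the whole
pipeline runs and is testable without any external download.

## Worked example

```r
library(circlass)

fx <- generate_dataset(fixture_config(n_pos = 60, n_neg = 60, seed = 42))
fx
#> <circ_fixture> 120 sequences ( 60 positive / 60 negative ), toy genome 103660 nt, seed 42

feats <- circ_features(fx$sequences, fx$genome, fx$junctions)
dim(feats)
#> [1] 120 545    # id + label + 341 k-mer + 2 ORF + 200 SJSC columns

cv <- repeated_kfold_cv(feats, algorithm = "rf", k = 5, repeats = 2, seed = 42)
cv
#> <circ_cv> 2 x 5 -fold stratified CV, rf on 120 records (seed 42)
#>   accuracy 0.9958 | precision 0.9923 | recall 1.0000 | F1 0.9960 | MCC 0.9920 | AUC 0.9999

model <- train_classifier(feats, "rf", seed = 42)
head(tidy(model), 5)
#> # A tibble: 5 × 2
#>   term             importance
#>   <chr>                 <dbl>
#> 1 ORF_coverage_x10       4.97
#> 2 ORF_length             4.91
#> 3 GC_content             2.96
#> 4 sjsc_150               2.84
#> 5 sjsc_49                2.19

predict(model, feats[1:3, ])
#> # A tibble: 3 × 3
#>   id        score label
#>   <chr>     <dbl> <chr>
#> 1 circ_0001  1    circRNA
#> 2 circ_0002  0.93 circRNA
#> 3 circ_0003  0.97 circRNA
```

The cross-validated accuracy of 0.996 says the forest recovers the
planted class signal almost perfectly at this sample size; MCC near 1
confirms both classes are classified symmetrically. The importance
ranking is the sanity check that it recovers it from the *right*
features: the two ORF features lead (the fixture's strongest planted
difference), followed by GC content and the SJSC positions 49/150 —
exactly where the generator plants the `AG`/`GT` splice dinucleotides.
`predict()` returns the circRNA-class probability and the 0.5-threshold
label per record.

`autoplot(cv)` draws the ROC curve, `plot_pr_curve(cv)` the
precision–recall curve, and `feature_combination_grid(feats)` scores
all seven block combinations. A thin CLI wrapping these functions is
installed as `exec/circlass` (subcommands `simulate`, `prep`,
`features`, `train`, `cv`, `grid`, `predict`).

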