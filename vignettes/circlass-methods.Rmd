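---
title: "Classifying plant circRNAs from sequence features: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant circRNAs from sequence features: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(circlass)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor is joined
back to an upstream acceptor, producing a covalently closed transcript.
In plants they are abundant but hard to tell apart from long noncoding
RNAs (lncRNAs): both are long, both lack protein products. circlass
classifies candidate transcripts as circRNA versus lncRNA-like using
only their sequence and, when available, the genomic context of their
two splice sites. The intended inputs are candidate sets that upstream
tools have already produced (e.g. back-splice candidates from chimeric
read evidence together with curated lncRNAs as the background class).

## The feature model

Each candidate is mapped to a fixed 543-dimensional vector built from
three blocks.

**k-mer composition (341 features).** For every k-mer $i$ of length
$k \in \{1,2,3,4\}$ the feature is the length-scaled frequency

$$f_i = \frac{x_i \cdot k}{L},$$

where $x_i$ is the number of occurrences of $i$ over all $L-k+1$
overlapping windows (stride 1) and $L$ is the transcript length. That
is $4+16+64+256 = 340$ features, plus GC content, 341 in total. Note
$f_i$ is deliberately *not* a probability — for $k>1$ it can exceed 1
(for "AAAA", $f_{AA} = 3\cdot2/4 = 1.5$). We keep the formula exactly
as defined rather than renormalizing: the downstream random forest is
insensitive to feature scale, and a stable definition beats a cosmetic
one. Windows containing `N` are counted toward no k-mer while $L$ stays
the full length, so ambiguous bases shrink a sequence's k-mer mass
instead of redistributing it. Only the forward strand is counted; k-mer
content is not collapsed with its reverse complement.

**ORF features (2 features).** circRNAs tend to carry shorter, sparser
open reading frames than coding or coding-contaminated sequences. The
package scans all six frames (three per strand) for maximal
`ATG ... stop` spans, stop codon included; an ORF must terminate before
the sequence end (open-ended spans are not ORFs), internal `ATG`s are
not separate ORFs, and sequences are treated as linear — no ORF wraps
across the back-splice junction, since the junction coordinates inside
the candidate are not assumed known. The optimal ORF is the longest
(ties: smaller start, then `+` strand), and the feature pair is

$$X_{ORF} = \{\,10 \cdot L_{ORF}/L,\; L_{ORF}\,\}$$

— ORF coverage standardized by a factor of 10, and ORF length in nt.
A sequence with no ORF contributes $(0, 0)$.

**Splice-junction sequence coding (200 features).** The genomic
sequence 50 bp upstream and 50 bp downstream of each of the two splice
sites is extracted (half-open window $[site-50, site+50)$, 0-based BED
coordinates; the site base is the first downstream base) and encoded
positionwise with the integer hash

$$\{A \to 1,\; T \to -1,\; C \to 2,\; G \to -2,\; N \to 0\}.$$

The hash is a bijection on `{A,C,G,T}` that maps complementary bases to
negated codes, so reverse-complementing a window reverses and negates
its code array — a symmetry the tests assert exactly, and the reason
`N` must map to 0. Each site contributes 100 codes; the site5 window
comes first, 200 codes per record. On the `-` strand windows are
reverse-complemented so "upstream" is transcript-upstream and
donor/acceptor context is strand-invariant. lncRNA negatives have no
back-splice, so their transcript's genomic start and end stand in as
the two sites. With no genome at all, a degraded FASTA-only mode takes
the candidate's own first/last 50 nt padded with `N` to 100 per site
and flags the table's `sjsc_mode` attribute.

Two conventions here were genuinely open and are our documented
choices: junction coordinates are interpreted as 0-based half-open (the
BED convention; nothing in the input formats pins this down), and "the
100 bp junction sequence" is read as 100 bp *per site* (200 codes
total) rather than 100 bp overall, because each site gets ±50 bp.

## Dataset preparation

Before training on real collections the package removes redundancy and
length outliers, because public circRNA/lncRNA databases contain many
near-identical isoforms and a few extreme transcripts:

* **Cross-set dedup** — any circRNA/lncRNA pair with identity above
  95% is removed from *both* sets (ambiguous class membership).
* **Within-set dedup** — greedy clustering in decreasing length order;
  a record is dropped when its identity with an already-kept record
  exceeds 95%, so the longest representative of each cluster survives.
* **Length filter** — Tukey box-whisker fences
  $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, quartiles by
  linear interpolation (`quantile()` type 7). The 1.5 multiplier is the
  standard whisker constant.

Identity is computed from a global Needleman–Wunsch alignment (match 1,
mismatch 0, gap −1) as matches over aligned columns, gaps included.
"Above 95%" is strict (> 0.95). At the scale this package targets
(hundreds to a few thousand curated records) exact global alignment is
affordable; a length-ratio upper bound skips pairs that could not reach
the threshold. For genuinely large collections a dedicated clustering
tool should be run upstream instead.

`split_train_test()` draws a seeded, stratified sample per class for
training (the protocol's 4000 + 4000 design) and keeps the remainder as
an independent test set.

## Classifier and evaluation protocol

The primary model is a random forest with 100 trees; comparison
algorithms are an RBF-kernel SVM ($C = 10$, $\gamma = 0.001$, no
feature rescaling), 7-nearest-neighbours (Euclidean distance, uniform
weights) and Gaussian naive Bayes (defaults). All other backend
settings are defaults. The decision threshold on the circRNA class
probability is 0.5.

Evaluation is stratified ten-fold cross-validation, averaged over
folds, repeated ten times with fresh fold assignments, and the repeat
means averaged — metrics are averaged per fold, not computed on pooled
predictions, matching the protocol's "average, then repeat, then
average" wording. Reported metrics are recall, precision, accuracy, F1
and the Matthews correlation coefficient

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with MCC defined as 0 whenever a denominator factor vanishes (the
formula is undefined there; 0 is the standard convention and matches
the chance-level value). Recall, precision and F1 are likewise 0 on a
0/0. ROC and PR curves come from a threshold sweep over the unique
pooled held-out scores, and AUC by trapezoidal integration.
`feature_combination_grid()` runs the same protocol for every non-empty
subset of the three blocks (7 combinations), with a shared seed so all
cells see the same fold structure.

One master seed drives fold assignment and every stochastic fit, so
every CV table is bit-for-bit reproducible. Stratification is not part
of the original protocol description; we stratify because the
train/test design is class-balanced and unstratified folds at k = 10
can otherwise starve a fold of one class.

## The synthetic fixture generator

Real plant circRNA/lncRNA collections require external downloads, so
the package ships a generator that emulates the *decision structure* of
that data — two classes separated in exactly the three feature families
the classifier uses — without pretending to genomic realism.

Defaults (chosen once as the package's study conditions): 400 records
per class, transcript lengths uniform on 500–1000 nt, positives
rejected until their optimal ORF is ≤ 300 nt, negatives given an
embedded stop-free reading frame of ≥ 450 nt, a GC offset of 0.06
between classes (positives 0.47, negatives 0.53 — comparable to real
AT-richness differences and large relative to the per-transcript GC
standard error of ~0.02), canonical `AG`/`GT` dinucleotides planted at
the acceptor/donor positions of positive junctions, and no label noise.
The sizes match the package's own acceptance analyses: 800 records for
signal recovery, 400 (as 200 + 200) for the null calibration. Each
transcript sits on the `+` strand of one toy chromosome with 60 nt of
background on each side, so every ±50 bp window fits; sites are the
genomic transcript ends, which for positives means the planted motifs
appear at window offsets 48–49 (site5) and 50–51 (site3). Minus-strand
window extraction is exercised by unit tests on hand-built genomes
rather than by the generator.

The background model is i.i.d. nucleotides with class-specific
composition — deliberately simple. What the generator does **not**
emulate: intron/exon structure, repeats, codon bias, isoform families,
real splice-site context beyond the planted dinucleotide, or class
imbalance. Passing tests on these fixtures therefore demonstrate that
the pipeline recovers signal that is present and reports chance when it
is absent; they do not certify accuracy on real plant data, where the
class signal is weaker and correlated with confounders.

`generate_null_dataset()` draws every record from one neutral profile
and assigns labels by permutation, so any detectable label signal in it
is a bug; the package checks that repeated-CV accuracy on it stays
within three binomial standard errors of 0.5.

## Numerical and edge-case conventions

* Sequences are normalized once: uppercase, `U → T`, anything outside
  `{A,C,G,T}` becomes `N` (idempotent).
* `k > L` yields all-zero counts with a warning, not an error; an
  all-`N` sequence has GC content 0 with a warning; an empty sequence
  is an error.
* Window positions beyond chromosome ends are padded with `N`.
* Tie-breaks are total and documented (ORFs: length, start, strand;
  dedup order: length then id), so all filters are order-stable.
* Confusion products are computed in double precision (integer
  overflow in the MCC denominator is otherwise possible at realistic
  sizes).

## Problem sizes used in the shipped analyses

The package's own test-suite analyses run at: n = 800 (default
fixture) for signal recovery with 10 × 10-fold CV; n = 400 for the null
calibration, also 10 × 10; n = 300 with 2 × 5-fold CV for the
ORF-only feature-combination ranking (7 combinations); 500–1000
randomized cases per formula-fidelity check; and 100-record fixtures
for the exact filter comparisons. These sizes give stable estimates —
the binomial standard error at n = 400 is ~0.025 — while keeping a full
run of the suite in the minutes range on one core.

## Known limitations

* The pairwise-identity engine is exact but quadratic; it is meant for
  curated candidate sets, not genome-scale redundancy removal.
* The FASTA-only SJSC fallback encodes transcript ends, not genomic
  junction context; models trained in one mode should not score
  records extracted in the other (the schema matches, the semantics do
  not — check `sjsc_mode`).
* KNN stores its training matrix in the model bundle; bundles are
  correspondingly large for big training sets.
* The six-frame ORF scan requires a stop codon; very short fragments
  of long coding sequences may be assigned $(0,0)$.
* Real-data performance claims require real data; the shipped analyses
  establish correctness and calibration, not field accuracy.
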