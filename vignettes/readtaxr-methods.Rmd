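---
title: "Methods: lineage-level read assignment with a logistic hit filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-level read assignment with a logistic hit filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readtaxr)
```

## The problem

Metatranscriptome sequencing of environmental samples dominated by
microbial eukaryotes (protists) produces millions of short mRNA reads from
organisms that are mostly absent from sequence databases. Read-level
species assignment is therefore hopeless; what is attainable is assignment
to broad taxonomic *lineages* (e.g. Chrysophyceae, Chlorophyta) nested in
the seven eukaryotic supergroups, searched against a small, taxonomically
balanced protein reference. The price of searching distant homologs with a
permissive E-value cutoff is a high rate of spurious best hits, so the
central statistical question becomes: *given a read's best hit, is the
lineage it implies trustworthy?*

## The model

For each read we retain up to 20 hits (E ≤ 1e5) and reduce them to two:
the best hit **BH** (rank 1 by E-value) and the **next lineage hit NLH**,
the first lower-ranked hit whose lineage differs from the BH's (hits in
between share the BH lineage and are skipped). Five properties summarize
how decisively the BH beats the competition from other lineages:

| feature | definition | intuition |
|---|---|---|
| `x1` | percent identity of the BH | absolute alignment quality |
| `x2` | identity ratio BH / NLH | relative advantage in identity |
| `x3` | log10 E-value of the BH | absolute significance |
| `x4` | log10 E(NLH) − log10 E(BH) | significance gap to the next lineage |
| `x5` | database size (residues) of the BH's lineage | exposure to lucky hits |

The acceptance probability is a binary logistic regression,

$$P(y = 1 \mid x_1,\dots,x_5) \;=\; \frac{1}{1 + e^{-(\beta_0 + \sum_k \beta_k x_k)}},$$

where $y=1$ means the BH lineage is correct. Coefficients are estimated by
maximum likelihood (`stats::glm`, binomial family; IRLS) from reads of
known origin labeled by whether their BH lineage matched the truth. A read
is *assigned* when $P \ge$ cutoff, *filtered* when $P <$ cutoff, and
*unclassified* when it has no hits at all; the three statuses partition
every input read. The default cutoff 0.58 is the published operating point
for a false positive rate below 0.1 and is exposed everywhere as a
parameter.

## Parameters that matter

* **`max_hits = 20`, `log10_evalue_cutoff = 5`** (`search_config()`): the
  loose search contract. The cutoff is on the log10 scale internally;
  BLAST-style raw E-values are converted on read (E = 0 clamps to −400).
* **cutoff (probability, default 0.58)**: the single operating knob.
  Raising it trades sensitivity for specificity; 1.0 rejects everything
  with certainty (the model's probabilities are kept strictly below 1).
* **NLH imputation (`impute_policy()`)**: when no second-lineage hit exists
  among the retained 20, the read is maximally unambiguous. A pseudo-NLH is
  placed at the search E-value cutoff (log10 E = 5) with a floor identity
  of 20%, giving a large `x4` and `x2`; the `nlh_imputed` flag is carried
  to output for audit. Alternative: dropping such reads would discard the
  least ambiguous assignments, which we consider wrong.
* **`x4` sign convention**: NLH − BH, so larger = more trustworthy
  (the direction is not fixed by the published feature list).
* **group size unit**: residues, not nucleotides. The reference stores
  amino-acid sequences; only the relative scale of `x5` matters to the
  regression, and the unit is recorded as an attribute.
* **features enter untransformed** — matching the direct feature listing;
  the numerical consequences are handled inside the fitters (see below).

## The built-in search

External tabular hit files (RAPSearch2, DIAMOND, BLASTX; m8 / outfmt 6)
are first-class input and the production route. The built-in search exists
so that tests and demos run with no external binary: six-frame
translation, candidate subjects found by exact seed matches of reduced
4-mers (Murphy 10-letter alphabet: LVIM / C / A / G / ST / P / FYW / EDNQ
/ KR / H), Smith–Waterman extension (BLOSUM62, gap open 11 / extend 1,
via `Biostrings::pairwiseAlignment`), and Karlin–Altschul scoring with the
ungapped defaults λ = 0.267, K = 0.041 (E = m·n·2^(−bits), m = frame
length, n = total database residues). It is a transparent test oracle, not
a re-implementation of any production search tool; its tests compare it
against an exhaustive all-frames × all-subjects alignment with no seeding.

## What the synthetic data emulates — and what it does not

`make_refdb()` builds a reference with the real schema (taxa → 28 lineages
→ 7 supergroups) but random proteins whose amino-acid composition is
skewed per lineage (a Dirichlet mixture; `lineage_skew = 0.5` by default)
so lineages are separable in 4-mer space, which the diversity statistics
(`group_diversity()`, maximum/mean Bray–Curtis over 4-mer spectra,
computed on relative frequencies so proteome size cancels) can verify.
`make_reads()` emits the three evaluation classes: exact back-translations
of database proteins (true positives), mutated copies standing in for
related species absent from the database but whose lineage is present
(default 10% amino-acid substitution — a realistic congeneric distance),
and i.i.d. random nucleotides with truth label `"none"` (any assignment to
them is a false positive). Reads default to 100 nt, matching the 50–101 bp
evaluation reads. Back-translation uses the first codon of the standard
code per amino acid — deterministic, and sufficient for identity-level
search tests.

Not emulated: codon usage, expression levels, sequencing error and quality
realism, shared conserved domains between lineages, and real database
redundancy. A green pipeline test therefore establishes the *mechanics*
(conservation of reads, correct BH/NLH logic, correct bookkeeping), and
the separable-limit tests establish behaviour at the easy extreme; neither
certifies real-data accuracy, which depends on reference coverage.

## Numerical choices

* **Probabilities are clamped to the open interval (0, 1)** after the
  logistic transform. `plogis` saturates to exactly 1.0 beyond a linear
  predictor of ~37, which would silently break the guarantee that a
  probability cutoff of 1.0 filters every read.
* **Complete separation**: `glm` diverges on separable data. The fit
  detects this (non-convergence, saturated fitted probabilities, or
  exploding coefficients) and falls back to an L2-ridge (λ = 1e-6) Newton
  solver with a warning. The ridge solver standardizes features
  internally and maps coefficients back — with `x5` spanning 1e4–1e7 the
  raw-scale Hessian is numerically singular.
* **Order independence**: rows are sorted before fitting, so the MLE does
  not depend on input order.
* **Deterministic tie-breaks** throughout hit processing: equal E-values
  are ordered by bit score descending, then subject id lexicographically.
  A rank-1 tie spanning two lineages thus yields `x2 = 1`, `x4 = 0` and a
  near-certain rejection — ambiguous reads are never favored (a tested
  invariant).
* **ROC thresholds** are the exact unique scores (plus a sentinel above
  the maximum); AUC is the trapezoid area, which equals the normalized
  Mann–Whitney concordance with ties counted ½ (tested against that
  oracle). Accuracy/FPR curves on random reads use a uniform grid of 1001
  cutoffs in [0, 1].
* **Cross-validation**: a stratified 20% holdout is split off once; each
  of the (default 100) Monte Carlo rounds re-splits the remainder 80/20
  stratified, refits, and evaluates on test, holdout and (optionally) the
  random-read set. Reported cutoffs are means over rounds. The whole
  procedure is bit-reproducible given the plan's seed.

## Open design points, resolved

* *Concordance level for mate pairs*: "same taxonomic group" is read at
  lineage level by default (configurable to supergroup); under
  `concordant`, a template with hits on only one mate is unassigned
  (strict reading; `allow_single` relaxes it).
* *Best-mate comparison*: by BH E-value (combination precedes filtering in
  the five-step flow), tie-broken by bit score.
* *E-value cutoff "1e5"*: raw-E and log-scale readings coincide in
  behaviour at this looseness; the number is exposed in `search_config()`.
* *The separable limit in the pipeline world*: with `mutation_rate = 0`
  and no random reads, every mapped read's BH lineage equals its truth —
  all labels are positive, and an AUC is undefined on a single class. The
  acceptance test therefore asserts the error-free pipeline directly and
  checks the AUC-1 limit on a deterministic, margin-separated labeled
  feature set; the chance-level null uses shuffled labels at n = 20 000.
  A Bernoulli draw from a steep logistic is *not* exactly separable, which
  is easy to forget.

## Known limitations

* The built-in search is quadratic-ish in candidates and meant for small
  fixtures (hundreds of reads, tens of reference proteins per lineage);
  real samples should come in as external m8 files.
* No shipped fitted coefficients: the original model's β values are not
  public, so a model must be trained (`fit_filter`) or supplied.
* Lowest-common-ancestor assignment, TMM normalization, ordination and
  differential expression are deliberately out of scope.
* Scaled-down test worlds (6–8 lineages, a few thousand reads) keep the
  suite inside CI budgets; they exercise every code path but not
  large-database statistics.
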