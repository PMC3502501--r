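---
title: "Comparative SAGE analysis with sagedge: models, statistics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative SAGE analysis with sagedge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagedge)
```

## The measurement model

Serial Analysis of Gene Expression (SAGE) measures a transcriptome by
counting short sequence tags.  An anchoring enzyme (NlaIII, recognition
site `CATG`) defines, for each transcript, a single diagnostic tag: the 10
nucleotides immediately 3' of the 3'-most `CATG` site.  Tags are ligated
pairwise tail-to-tail into 20-nt *ditags* (the second tag entering as its
reverse complement), the ditags are concatenated into clones separated by
`CATG` anchors, and the clones are sequenced.  A library is then a
multiset of tags, and a tag's count is a digital estimate of its
transcript's abundance.

Two artifacts shape the computational pipeline:

* **PCR duplicates.** The same ligation product can be amplified and
  sequenced repeatedly.  Because two independent ditags rarely coincide
  exactly, ditags with identical sequence are collapsed to one
  representative before counting (`dedup_ditags()`; exact full-sequence
  equality, with tag-pair-level collapsing available behind a flag).
* **Ambiguity of short tags.** A 10-nt tag can be shared by transcripts
  of different genes.  Annotation therefore runs against *virtual tag
  databases* extracted from cDNA collections (`build_tag_db()`), flags
  shared tags as ambiguous, and excludes them along with single-copy tags
  (`annotate_tags()`, `min_count = 2`).

This package implements that pipeline for a two-library comparison — a
disease-model library against a resistant comparator, as in the kidney
transcriptome study of a nephron-deficient mouse that develops focal and
segmental glomerulosclerosis (FSGS) on one genetic background but not
another — together with a synthetic-data generator that makes every stage
testable against a known ground truth.

## Two-library differential expression

For a tag with counts $x$ and $y$ in libraries of sizes $N_1$ and $N_2$,
`sage_dge()` computes three significance measures:

* **Audic–Claverie** (`audic_claverie_p()`, the default primary test).
  With $r = N_2/N_1$, the probability of seeing $k$ in the second library
  given $x$ in the first is
  $$P(k \mid x) = \frac{r^k\,(x+k)!}{x!\,k!\,(1+r)^{x+k+1}},$$
  the posterior predictive of a Poisson rate under a flat prior.  The
  two-sided p-value doubles the smaller tail at $y$ and caps at 1.
* **Fisher's exact test** (`fisher_exact_p()`) on the table
  $[[x, N_1-x], [y, N_2-y]]$, two-sided by the point-mass rule; its right
  tail is also the enrichment statistic used for gene sets.
* **Pooled two-proportion z** (`proportion_z_p()`), the binomial
  normal approximation.

The published analysis did not pin down which method produced its printed
p-values, and the printed values are internally inconsistent (the same
gene appears with two different p-values in two tables; a perfectly tied
contrast carries p = 0.038, which no symmetric two-library test
reproduces at these totals).  The package therefore treats printed
p-values as fixture data, computes all three statistics, and enforces the
published claim that "rank orders were comparable" as a *property*:
Spearman's rank correlation between the Audic–Claverie and Fisher
p-values exceeds 0.9 on library-scale simulations (in practice ≈ 0.98).

Numerical choices worth knowing:

* $P(k \mid x)$ is exactly the negative-binomial mass with size $x+1$ and
  success probability $N_1/(N_1+N_2)$, so both tails are evaluated with
  `pnbinom()` (regularized incomplete beta).  Computing the upper tail as
  $1 - \sum_{k<y}$ loses all precision once the tail drops below
  $\sim 10^{-15}$; the beta route does not.  Test oracles still sum the
  closed form term by term, forwards in both directions.
* The Audic–Claverie test conditions on the library-1 count, so swapping
  the libraries changes the p-value by at most one point mass
  $P(y \mid x)$.  Fisher and z are exactly swap-symmetric; the test suite
  asserts exactly that distinction.
* p-values are floored at the smallest positive double, never 0; a
  contrast with $x + y = 0$ has no information and returns 1.
* Fold changes normalize counts to the larger library
  ($x' = x \cdot \max(N_1,N_2)/N_1$) and add a pseudocount of 1, so a
  15-vs-0 contrast at equal totals gives fold change 16 rather than
  infinity.  Ties classify as "down": with one tied gene in the published
  glomerular table, the tie-down rule is the only one reproducing its
  printed 53 up / 14 down tally.
* Multiplicity correction is Benjamini–Hochberg (`adjust_p()`), the
  standard for expression screens; the original text says only "corrected
  for multiple testing".  Bonferroni is available.
* Focus-gene selection (`select_focus_genes()`) mirrors the published
  and/or criterion: fold change strictly above 2 **or** adjusted p
  strictly below 0.05 by default.

## The synthetic-data generator

`sage_sim_config()` fixes the study conditions; all randomness flows from
its single seed, and every product (ground truth, cDNA, counts, reads) is
a deterministic function of the configuration.

* **Abundance law.** Transcript proportions follow a Zipf law over
  permuted gene ranks.  The defaults — 30,000 genes, exponent 0.8, library
  totals 22,989 and 26,599 — were chosen so the simulated libraries match
  the reference libraries' printed scale: expected unique-tag counts of
  roughly 10,300/11,300 (published: 9,580/11,014) and a top tag in the
  several hundreds (published: 873).  A steeper exponent such as 1.1
  concentrates more than 9% of a library on its top gene and produces only
  ~6,000 unique tags at these totals, which contradicts that scale, so
  0.8 is the default; the exponent remains a free parameter.
* **Differential structure.** `round(frac_differential * n_genes)` genes
  (default 1%) alternate up/down with fold changes cycled from
  `fold_changes`.  A fold change $f$ is imposed by scaling the two
  libraries' proportions by $\sqrt f$ and $1/\sqrt f$ and renormalizing
  only the *null* genes, so each differential gene's proportion ratio
  equals its assigned fold change exactly; `frac_differential = 1` is
  rejected because no null mass would remain to absorb the
  renormalization.
* **Sampling.** Each library is one multinomial draw of exactly the
  configured total over the tagged genes' renormalized proportions —
  a pooled-library design with no per-animal replication, matching how
  the original libraries were built (RNA from three animals pooled per
  strain) and implying no overdispersion model.
* **Concatemers.** Tags are drawn without replacement and paired into
  20-nt ditags; an odd leftover is paired with a recorded filler tag.
  Duplicates are injected at `duplicate_ditag_rate` (default 5%) as
  verbatim copies of emitted ditags — the PCR-artifact model — and logged.
  `ledger_tag_counts()` states exactly what extraction should recover:
  the tag counts of the *unique* emitted ditags.
* **What is deliberately unreal.** Tag sequences are drawn without
  internal `CATG` and with junction constraints (no terminal `C`, no two
  tags meeting `CA`|`CA`) so that no ditag can contain an anchor site and
  parsing round-trips the ledger exactly; real tag space has no such
  restriction, and a real extractor loses the rare ditag with an internal
  anchor.  There is no sequencing-error model (an optional uniform
  substitution rate was considered and left out as a non-goal), no
  linkers, no quality scores, and cDNA records carry exactly one
  transcript per gene.  Passing round-trip tests therefore validates the
  bookkeeping, not robustness to sequencing noise.

## What the tests establish

Beyond unit examples, the suite asserts, under fixed seeds:

* exact-test implementations agree with brute-force enumeration oracles
  to within $10^{-10}$ relative on a grid of contrasts ($x, y \le 50$,
  totals to 2,000);
* concatemer extraction reproduces the generator ledger exactly at zero
  error rate, invariant to read order, with totals equal to twice the
  retained ditag count;
* annotation recall is 100% for unambiguous synthetic tags with count
  ≥ 2, and ambiguity flags match the ground truth exactly;
* on null libraries (totals 25,000/25,000, 2,000 genes, 10 seeds) the
  Fisher two-sided positive rate at $\alpha = 0.05$ stays below 6% —
  exact tests on counts are conservative, ~2% in practice;
* 4-fold differential tags (25 of 500 genes, totals 25,000) are recovered
  by the default pipeline at ≥ 80% sensitivity with ≤ 10% false
  discoveries at BH-adjusted p < 0.05, averaged over 10 seeds.

Problem sizes in the routine suite (a few hundred genes for round-trip
tests, 500–2,000 genes × 10 seeds for the statistical properties, one
full-scale pair of libraries for the rank-concordance check) were chosen
as the smallest instances at which the asserted behavior is stable, so
the whole suite runs in seconds.

## The packaged reference tables

`sage_fixture()` ships verbatim transcriptions of the published summary
tables: library sizes (`T1`), the top-50 differential tags (`T2`), the 67
glomerular genes (`T3`) and the cross-species comparison (`T5`).  They
are data, not corrections — printed inconsistencies are preserved, which
is why printed p-values load as character strings.  Three published
numbers are recomputable from them and are re-derived by
`scripts/acceptance.R`: the combined totals (49,588 tags, 20,594 unique),
the 53/14 direction tally, and the count of 13 human glomerular genes at
q ≤ 0.05 (the boundary is inclusive; one gene is printed exactly at
0.05).  The printed "17 concordantly regulated" genes are *not*
recomputed: one row of the published table is sign-discordant as printed
(mouse up, human logFC −0.07), and `concordance_table()` reports it
discordant rather than reproducing the label.

## Worked example

```{r example}
cfg <- sage_sim_config(n_genes = 2000, library_totals = c(8000, 9000),
                       frac_differential = 0.02, seed = 101)
sim <- sage_simulate(cfg)

# extract libraries back out of the concatemer reads
lib1 <- extract_library(sim$concatemers[[1]]$reads, name = "model")
lib2 <- extract_library(sim$concatemers[[2]]$reads, name = "control")

# annotate through the virtual tag database and fit the contrast
db  <- build_tag_db(sim$cdna, tier_name = "refseq")
ann <- annotate_tags(lib1, db)
fit <- sage_dge(lib1, lib2, annotation = ann)
summary(fit)
```

Note that the extracted libraries differ slightly from `sim$counts`:
duplicate-ditag exclusion removes the injected PCR duplicates *and* any
true ditag that collides with another by chance, exactly as in the real
protocol.

```{r plot, fig.width = 6, fig.height = 4}
plot(fit)
```

## Known limitations

* Libraries are pooled; there is no replicate-level variance model, so
  p-values quantify sampling error only, not biological variability.
* Annotation is exact string matching of tags and gene symbols; there is
  no sequence-similarity fallback, no EST clustering, no orthology
  mapping (cross-species matching relies on symbols as provided).
* Human q-values are consumed as given; the microarray significance
  analysis that produced them is out of scope.
* The single-copy exclusion threshold applies per library by default
  (the original text does not say whether it was applied per library or
  to the pooled tag set); `min_count` is exposed to change it.
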