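---
title: "Methods: MIG essentiality, gene age, and enrichment testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIG essentiality, gene age, and enrichment testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migessentials)
```

## The scientific question

Minor introns (U12-type introns, removed by the minor spliceosome) sit in
fewer than 600 human genes, yet they are deeply conserved in animals and
plants. One explanation is that minor intron-containing genes (MIGs) are
disproportionately *essential* for the survival of rapidly cycling cells,
so that losing a minor intron — and with it reliable expression of its host
gene — is rarely tolerated. `migessentials` implements the analysis chain
needed to examine that idea quantitatively:

1. build **essentialomes** (sets of essential genes) from genome-wide
   CRISPR knockout screens across many cell lines;
2. test gene-set **overrepresentation** of MIGs (and control gene lists)
   in those essentialomes with exact Fisher tests;
3. stratify by **evolutionary gene age** from ortholog-group membership,
   separating genes tracing to the last eukaryotic common ancestor (LECA)
   from younger genes, to remove age as a confounder;
4. classify **cell-cycle expression stability** of MIGs from TPM tables of
   FUCCI-sorted populations (early G1, late G1, S, G2/M);
5. quantify MIG sharing among cross-species **candidate domestication
   gene** (CDG) lists, and count **minor-intron gain events** by collapsing
   gene families to single events.

A seeded synthetic-data module generates all of these inputs with planted,
known effect structure, so the whole pipeline is testable without any
external download.

## Essentialome construction

The input is a genes-by-cell-lines matrix, either of continuous gene-effect
scores or of binary calls. Three deliberate conventions:

* **No default score threshold.** Published screens rarely state a portable
  cutoff, and essentialome sizes are extremely sensitive to it. In scores
  mode the threshold is mandatory (`call = score <= threshold`, boundary
  inclusive, since more negative gene effect means stronger dependency);
  pre-called binary matrices are first-class input.
* **Missing is not zero.** An `NA` score yields an `NA` call, and an `NA`
  call never places a gene in any essentialome. Zero-filling would
  fabricate non-essential calls for genes a line simply did not measure.
* **Rules.** With per-line essentialomes $E_1,\dots,E_L$: the *total*
  essentialome is $\bigcup_l E_l$ (essential in at least one line), the
  *core* is $\bigcap_l E_l$, and the *majority* essentialome at fraction
  $f$ keeps genes essential in at least $\lceil fL \rceil$ lines. The
  ceiling interprets "at least 95% of lines" as a lower bound, so $f=0.95$
  over 341 lines means 324 lines, and $f = 1$ coincides with the core.
  Group (e.g. cancer-type) essentialomes take the union within each group
  of lines, the most direct reading of "combining" per-line essentialomes;
  recomputing a majority rule within groups is possible by calling
  `majority_essentialome()` on the group's lines directly.

All rules are checked in the test suite against brute-force per-gene
counting on random matrices, together with the nesting property
core ⊆ majority(f) ⊆ majority(f′) ⊆ total for f′ ≤ f.

## Exact enrichment testing

Overrepresentation of a feature list (say, $K$ MIGs in a universe of $N$
interrogated genes) within a query set ($n$ genes, $k$ of them MIGs) is
tested with the exact hypergeometric (Fisher) test. Conventions that
matter:

* **Two-sided, minimum-likelihood rule.** The p-value sums $P(X = x)$ over
  all $x$ whose point mass does not exceed $P(X = k)$, with a $10^{-7}$
  relative tolerance for ties. This is the dominant convention in
  scientific software and the one that reproduces the published worked
  examples this package re-derives (e.g. the human-CDG table 33/742 versus
  648/20,444 giving $P = 0.0535$). A one-sided reading would not.
* **Background convention.** The query is part of the background
  (`universe_includes_query`): the 2×2 is
  $[[k, n-k], [K-k, N-n-K+k]]$. We verified numerically that treating
  externally printed genome totals (648 of 20,444) as *containing* the
  query reproduces the published p-values (0.0535, 0.0067), while
  subtracting the query does not (0.0564); the includes convention is
  therefore the default. When both sets are supplied as gene lists and the
  query is inside the universe, the excludes convention stacks the query
  onto the query-free background and yields the same 2×2 cells; the two
  conventions genuinely differ only for external background totals.
* **Numerics.** Point masses are evaluated in log space
  (`dhyper(log = TRUE)`), so genome-scale tables ($N > 20{,}000$) lose no
  precision; no normal approximation is used anywhere. Degenerate tables
  ($n = 0$, $K = 0$, $K = N$) return $p = 1$. The implementation is checked
  against an independent binomial-coefficient enumeration oracle for every
  feasible table with $N \le 60$ (agreement within $10^{-12}$) and against
  `fisher.test()` on random larger tables.
* **Reporting.** Fold enrichment is $(k/n)/(K/N)$ on unrounded fractions;
  only the reporting layer rounds to one decimal. Raw p-values are reported
  by default (matching single-test reporting conventions); Benjamini–
  Hochberg adjustment across a control battery is available with
  `adjust = "BH"`.

## Gene age assignment and stratification

Phylostratigraphy assigns each gene the oldest clade among its
ortholog-group memberships (eggNOG-style tables: gene, group, taxonomic
level). The clade ladder is configuration, not code — the default runs
Eukaryota (collapsing all pre-LECA ages into one oldest rung) through
Opisthokonta, Metazoa, Eumetazoa, Bilateria, Deuterostomia, Chordata,
Euteleostomi, Amniota, to a species-specific rung — because taxonomic
level sets vary across ortholog-database versions. Genes with no
membership at all are assigned the youngest rung and tracked as
`unassigned`: absence of detectable orthologs is the standard
phylostratigraphic signal of recency. A `strict` mode excludes them
instead.

Age-stratified enrichment restricts universe, query and feature to one
stratum (ancient = at or before the boundary clade) before testing, which
removes gene age as a confounder: ancient genes are both more often
essential and more often MIGs, so an unstratified test conflates the two.
The ancient and younger tables sum cell-wise to the unstratified table,
which the suite asserts.

## Cell-cycle expression

A gene is *expressed* in a stage iff its replicate-mean TPM is at or above
the threshold (default 1, inclusive); a per-replicate mode requiring every
replicate to clear the threshold is available. Raising the threshold can
only shrink the expressed-in-some and expressed-in-all counts
(monotonicity, tested).

Successive-stage differential expression compares each ordered stage pair
(early G1→late G1, late G1→S, S→G2/M). The default test is a two-sample
Welch t-test on $\log_2(\mathrm{TPM}+1)$ across replicates at $p < 0.05$
per pair, with the gene-level verdict the OR over pairs. This is an
explicit stand-in: published analyses of this design rarely state their DE
procedure, and stage-pair DE counts are method-dependent, so the package's
claims about DE rest on synthetic calibration (null flag rate ≈ α;
sensitivity ≈ 1 for a planted 4-fold step at 5% replicate CV with 3
replicates) rather than on reproducing any particular published count. A
fold-change-only method (`method = "fold_change"`) covers replicate-poor
tables, where Welch is undefined. Zero-variance degenerate pairs are
resolved by effect: equal means give $p = 1$, different means count as an
exact step.

## Domestication-gene sharing and gain events

CDG lists are compared after symbol normalization through the shared alias
map, since cross-species symbol drift is the dominant failure mode.
`shared_cdg(collection, k)` keeps genes in at least $k$ species lists
(monotonically nested in $k$; an exact-$k$ mode exists because "shared
among three species" is ambiguous between the two readings). The MIG
enrichment tests for CDGs run against a *fixed printed genome background*
(648 MIGs of 20,444 protein-coding genes by default) supplied as counts,
not against a screen universe — the two analyses intentionally use
different backgrounds.

Gain-event counting collapses each minor-intron-rich gene family to a
single event in its ancestral gene: events = genes outside any family +
families with at least one member present. Families must be disjoint;
family members absent from the input are ignored with a warning.

## The synthetic-data generators

Every generator is a deterministic function of (config, seed) via R's
default Mersenne-Twister stream; identical inputs give identical outputs,
and each generator returns a `truth` attribute recording every planted
parameter, sufficient to score the downstream stage without re-deriving
ground truth.

* **Universe** (default 17,000 genes): MIG flags Bernoulli at 3.5%; ages
  multinomial over the default ladder with 66.8% at Eukaryota and a
  tapering younger tail; MIG families of sizes 3, 2, 2 planted among the
  MIGs.
* **Essentiality**: each gene draws a consensus essentiality call. The
  base rate (overall 0.10) is higher for ancient than younger genes
  (odds boost 2.6, with the overall rate held fixed), reflecting the
  empirical pattern that ancient genes are more often essential; MIG odds
  are multiplied by the planted odds ratio (default 2.5), optionally per
  age stratum. Per-line calls then deviate from the consensus
  *asymmetrically*: an essential gene is dropped in a line with
  probability 0.02, while a non-essential gene gains a spurious call with
  probability only 2×10⁻⁴. The asymmetry is deliberate. The total
  essentialome is a union over lines, so a symmetric per-line gain rate of
  0.02 would sweep roughly two-thirds of never-essential genes into the
  total over 50 lines and destroy the correspondence between the planted
  odds ratio and anything measurable downstream; with the small gain rate
  the union contaminates by about 1%, the total-essentialome odds ratio
  sits within ~8% of the planted value, and the drop rate still separates
  core, majority and total non-trivially (about 36% of consensus-essential
  genes survive all 50 lines into the core).
* **Expression**: per-gene log-normal baseline TPM (log2 mean 3, sd 2)
  shared across stages; a 1% fraction of genes receives a 4-fold step
  (random direction) at one random successive stage boundary;
  multiplicative log-normal replicate noise at 5% CV.
* **CDG lists**: configured numbers of genes are planted into exactly
  three and exactly two species lists (defaults 6 and 45, so 51 genes are
  shared by at least two species); all remaining genes are sampled
  species-unique, with MIG odds multiplied by the planted CDG–MIG odds
  ratio (default 1.4). Keeping non-planted genes unique to one species
  makes the planted sets exactly the multi-species overlaps, so sharing
  structure is fully known; the cost is that accidental overlaps, which
  real lists would contain, are absent by construction.

What the generators do *not* emulate: the marginal score distributions of
real CRISPR screens (we generate calls, not CERES-style scores),
correlated essentiality within pathways, ortholog-detection error in age
assignment, between-stage library-size artifacts in TPM, or cross-species
ortholog mapping noise in CDG lists. Passing the synthetic suites
therefore demonstrates correctness of the *inference machinery* under a
known generative model, not that any particular biological conclusion
transfers to real data.

## Monte-Carlo problem sizes

The calibration and recovery suites use problem sizes chosen to estimate
each rate tightly while keeping the default test run fast: null
calibration of the MIG-enrichment test at 2,000 genes × 10 lines over
1,000 replicates (rejection rate at α = 0.05 must stay within two binomial
standard errors of 0.05; Fisher is conservative, so observed rates sit
near 0.03–0.045); odds-ratio recovery at the full 17,000 genes × 50 lines
over 200 replicates (planted OR 3 recovered within ±25%); age-stratified
specificity at 4,000 genes × 20 lines over 200 replicates with ancient OR
4 and younger OR 1 (the effect must be detected in the ancient stratum and
not in the younger one). The same computations, re-seeded from the
command line, are what `scripts/acceptance.R` reports.

## Known limitations

* Published headline counts that depend on unpublished inputs — the exact
  interrogated-universe size, the essentiality call rule behind specific
  essentialome sizes, the ortholog-database version behind age
  percentages, the DE method behind expressed/DE counts — cannot be
  reproduced from printed numbers alone. The package documents them as
  real-data expectations and covers the corresponding machinery with
  synthetic ground truth instead; reproducing them requires the original
  gene-effect matrix, MIG list, ortholog tables, TPM table and CDG
  supplements as user-supplied files.
* The MIG share of an interrogated universe is reported in the source
  material as both 3.5% and 3.4% for the same MIG list; the package takes
  such fractions as inputs where they matter and does not resolve the
  discrepancy.
* Welch DE on three replicates is approximate for strongly non-normal
  replicate noise; the calibration tests bound the practical size
  distortion under the generator's log-normal noise.
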