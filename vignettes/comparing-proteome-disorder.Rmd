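---
title: "Comparing intrinsic protein disorder between proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing intrinsic protein disorder between proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpcompare)
```

## The analysis

`idpcompare` asks where two proteomes differ in intrinsic disorder at the
level of Gene Ontology functional classes. The pipeline has five stages,
each exposed as ordinary functions so any stage can be run, inspected or
replaced on its own.

1. **Dataset construction.** Proteomes are read from FASTA and cleaned by
   the rules that residue-level disorder predictors require: repeated
   sequences (identical amino-acid string; the first occurrence is kept),
   header-flagged fragments, sequences with non-standard residues
   (selenocysteine U, pyrrolysine O) and sequences with ambiguity codes
   (B, X, Z, J) are removed. "Repeated" is interpreted at the sequence
   level rather than the accession level because identical sequences are
   what make downstream statistics double-count; the choice is surfaced in
   the filter rule set, and the filter report keeps the arithmetic
   auditable (removals always sum to input minus output).

2. **Per-protein disorder metrics.** Per-residue scores in [0, 1] are
   binarized at a threshold, boundary inclusive (score ≥ t ⇒ disordered).
   Inclusiveness matters at exactly two places — the binarization boundary
   and the ≥ 50% disordered-protein rule — and both are inclusive here,
   consistently with how such cutoffs are customarily quoted. From the
   mask we compute disorder content, long disordered windows (LDWs,
   maximal runs of at least 30 consecutive disordered residues), the
   residues covered by them, and the analogous counts for disordered
   binding regions (DBRs) from an ANCHOR-style binding track. The DBR
   minimum region length defaults to 6 residues: binding-region tracks are
   noisier than disorder tracks and a minimum length keeps single-residue
   flickers from counting as regions; it is a parameter, not a constant.

3. **Annotation expansion.** GO annotations are closed under the
   ontology's ancestor relation so that any two proteins are comparable at
   the most specific term they share, and obsolete terms are dropped
   before expansion. Traversal uses `is_a` only by default — it is the
   uncontested subsumption relation — with `part_of` available by
   configuration; the two modes can give different universes and neither
   is asserted as canonical. The comparative analysis runs on the terms
   annotated in both organisms.

4. **Class-level statistics.** Binary disorder criteria (≥ 50% content,
   ≥ 1 LDW, ≥ 1 DBR) lead to a per-class 2×2 contingency table and a
   Yates-corrected chi-square test with the correction capped at |O − E|,
   so equal observed and expected counts give a statistic of exactly 0
   (this is also the reference behaviour of `chisq.test`). A class is
   reported only when the observed disordered count in organism A exceeds
   the expected value by at least 5% — the analysis is deliberately
   directional, looking for classes where organism A concentrates
   disorder. Benjamini–Hochberg correction is applied across exactly the
   classes tested in a run: the hypothesis family is the set of tests
   actually performed, not the ontology. Quantitative criteria use a
   two-sided Wilcoxon rank-sum test on the per-protein values within the
   class (not organism-level pooling), with direction enforced as
   mean(A) > mean(B).

5. **Interpretation aids.** A single-organism enrichment of the
   disordered-protein set (hypergeometric tail or its EASE variant with
   one study hit removed, then adjusted p ≤ 0.05 and ≥ 2 hits), a
   three-way categorization of terms (enriched-only, comparative-only,
   both), SimRel-based semantic summarization, and an ortholog-restricted
   validation described below.

## Numerical and procedural choices

**Rank-sum p-values.** The exact two-sided p is computed by enumerating
all `choose(n+m, n)` labelings when the pooled sample is at most 12 and
untied. Beyond that, the normal approximation is sharpened with a
continuity correction and an Edgeworth kurtosis term: the rank-sum null
has excess kurtosis `−(6/5)(n² + m² + nm + n + m) / (nm(N+1))`, and
restoring it brings the approximation within 0.002 of the exact tail
already at n = m = 6 (a plain continuity-corrected normal is off by up to
0.015 there). With ties the variance is tie-corrected and the kurtosis
term is dropped.

**Degenerate tables.** A 2×2 table with a zero marginal is reported as
statistic 0, p 1, and flagged, rather than erroring: zero-disorder classes
are legitimate data. An expected disordered count of exactly 0 passes the
excess filter iff any disordered protein is observed.

**LDW count is not threshold-monotone.** Lowering the binarization
threshold can only grow the mask, so disorder content and LDW residue
coverage are monotone — but the LDW *count* can drop when a gap residue
crosses the threshold and two long windows merge into one. The property
tests assert monotonicity for the two percentage metrics only; treating
the count as monotone would be wrong.

**Information content and SimRel.** IC uses the natural log of the
annotation frequency against an explicit reference corpus (an expanded
annotation set); only ratios and the `1 − p(c)` factor matter for ranking,
but the base is documented to make values comparable across runs. The
reference corpus is a required argument because IC — and everything
downstream — changes with it. Clustering is greedy single linkage with
stated tie-breaks (representative = lowest p, then highest IC, then
lexically smallest id), which makes the output deterministic and makes the
cluster count monotone in the threshold; REVIGO's unpublished internals
are intentionally not imitated. Superclusters join cluster representatives
by the same procedure at a lower threshold (default 0.5).

**Ortholog validation.** Class-level disorder means recomputed over
ortholog pairs control for annotation bias: the same (comparable) proteins
enter both means. Pairs count for a class when either member is annotated
to it (default; maximizes usable pairs, configurable to both-members), and
the across-class test defaults to the paired t-test because the class
means arrive as natural matched pairs; Welch's two-sample test is offered
and both modes are reported by the pipeline when requested. Class-equal
weighting is the default for the grand means, protein-equal weighting
being recoverable from the per-class table.

**Built-in predictor.** So that the pipeline runs without external
predictor output, a simple charge/hydropathy sliding-window score is
included: the foldability index `f = 2.785·⟨H⟩ − |⟨R⟩| − 1.151` over a
51-residue window (Kyte–Doolittle hydropathy rescaled to [0, 1], mean net
charge from K/R/D/E), squashed so that f < 0 maps above 0.5. Windows
shrink at the termini instead of padding — there are no sentinel residues.
It is a composition heuristic, useful as plumbing and for exercising the
pipeline, and is not a substitute for a trained disorder predictor.

## What the synthetic generator emulates

The generator produces the full input bundle from one seed: two
proteomes, per-residue disorder and binding tracks, a rooted GO-like DAG,
leaf-class annotations, an ortholog map and a truth table. Its defaults
are the package's study conditions: 400 proteins per organism with lengths
100–400, a 40-term DAG (max 2 parents per term), leaf classes covering
half the proteome, 3 planted classes with disordered-protein rates 0.6
(organism A) vs 0.2 (organism B) against a 0.3 baseline in both, and an
ortholog fraction of 0.5. The baseline sits between the disorder shares
reported for real plant and animal proteomes; the planted effect is large
enough that a 200-per-side class separates decisively, which is what the
recovery suites assert. The null generator is the same machinery with zero
planted classes.

Tracks are segmental, not i.i.d.: disordered proteins get 55–85%
disordered residues including one run of at least 40, ordered proteins get
5–35% in runs shorter than 30 — i.i.d. per-residue flags almost never
produce 30-residue runs, which would make LDW statistics vacuous. Scores
are drawn per state and truncated away from the 0.5 boundary, so
binarization at 0.5 recovers the generating state exactly and the three
binary criteria coincide by construction. Sequences are drawn with
disorder-promoting residues (P, E, S, K, Q) enriched in disordered
segments so the built-in predictor sees realistic composition signal.

What this does *not* emulate, and what passing tests therefore do not
show: real predictor error profiles (scores here never straddle the
threshold within a segment), proteins where the three disorder criteria
disagree, multi-LDW proteins, annotation sparsity and evidence-code
structure of real GO releases, and one-to-many orthology. Results on
synthetic data validate the statistical machinery, not any biological
claim.

Planted classes overlap with other classes, and expansion propagates their
members upward, so ancestors of planted terms legitimately acquire part of
the signal — as they would in a real ontology. Recovery is therefore
asserted for the planted terms themselves, not exclusivity of the
significant list.

## Problem sizes and determinism

The property suites run at sizes chosen to exercise every code path while
keeping the whole suite in the low minutes: oracle comparisons on
thousands of random masks/p-vectors, DAGs up to 100 nodes, planted
recovery over 20 seeds at the default study size and null rates over 50
seeds at 200 proteins per organism. All randomness flows through R's
Mersenne-Twister from explicit integer seeds; generated studies, the
report bundle, and the clustering are bit-reproducible given seed and
configuration. For that reason the pipeline's run log records versions,
parameters, the seed and input checksums, but deliberately no wall-clock
timings — a log that changes between identical runs would break the
bundle's byte-level reproducibility contract.

## Known limitations

The chi-square path treats proteins as independent draws, which ignores
paralogy; the ortholog validation exists precisely to check conclusions
against that worry. The excess filter makes the comparison one-directional
by design — swap the organisms to ask the mirrored question. EASE/Fisher
enrichment here covers GO terms only, without DAVID's multi-source
aggregation or fuzzy clustering. The OBO reader implements the subset
needed for annotation propagation (`id`, `name`, `namespace`, `is_a`,
`relationship: part_of`, `is_obsolete`), not full OBO 1.4 semantics. And
whether a published analysis expanded annotations over `part_of` as well
as `is_a` is often unrecoverable; both modes are provided and the default
is stated, but results can differ between them.
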