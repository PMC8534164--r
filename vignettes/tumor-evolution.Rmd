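---
title: "Reconstructing tumor evolution from multi-lesion exomes"
author: "oncophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tumor evolution from multi-lesion exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncophylo)
```

## The analysis problem

Multi-region sequencing of a single patient — several lesions sampled over
the course of disease, plus a matched normal — captures tumor evolution as
differences between the lesions' somatic mutation sets. `oncophylo`
implements the downstream analysis that turns per-lesion annotated variant
tables and gene-level copy-number calls into that evolutionary picture:
somatic filtering, driver classification, mutational burden, signature
exposures, clonality partitioning and maximum-parsimony phylogenies.

The package deliberately *consumes* the outputs of upstream tools
(alignment, calling, annotation, copy-number segmentation are out of
scope) and treats each lesion as one taxon: presence/absence of an event
in a lesion is taken at face value from the filtered tables. This is the
same simplification the field's binary-character tree analyses make, and
its main consequence — absence by low coverage is indistinguishable from
true absence — is discussed under limitations.

## Filtering model

A call is kept only if all four rules hold (`filterVariants()`):

1. **Population frequency** (`popAfThreshold`, default 0.001, a
   fraction): the maximum allele frequency across population panels must
   be below the threshold. The maximum across panels is the conservative
   sufficient statistic for a rule phrased as "rare in every panel", so
   the table carries one `pop_af_max` column rather than three.
2. **Common SNP** exclusion, *unless* the variant is ClinVar-pathogenic.
   The rescue is read narrowly: it overrides only this rule, never read
   support or VAF — a pathogenic germline variant still needs credible
   evidence in the reads.
3. **Strand support** (`minStrandReads`, default 2 reads): at least two
   alternate reads on the forward *and* the reverse strand. The
   per-strand reading is chosen over "two reads total" because the
   latter is vacuous at exome depths; requiring both strands is the
   standard artifact guard.
4. **Allele fraction** (`vafThreshold`, default 0.05, inclusive).

Rules are evaluated conjunctively and every failure is recorded, so the
per-rule tallies in a `FilterReport` count each rule independently of the
others.

**Driver classification** (`classifyDriver()`) gates on a curated driver
gene list, then calls a variant pathogenic if *any* of three arms holds:
ClinVar-pathogenic, at least two of three in-silico predictors
deleterious, or a known hotspot. The disjunctive reading is a design
decision: requiring all three simultaneously would leave essentially no
driver callable from a single assay, and the field's practice treats
these as alternative evidence routes. Every satisfied arm is recorded, so
the call is auditable.

**Burden** (`computeTmb()`) is the exact ratio of filtered mutations to
the assayed coding size (`exomeMb`, default 37 Mb). All filtered coding
events count by default (synonymous, nonsynonymous, indels);
`nonsynOnly` restricts the numerator, since conventions differ between
laboratories.

**Copy number** (`filterCnvs()`) keeps only directionally coherent
events: amplifications (CN > 2) in oncogenes, deletions (CN < 2) in
tumor suppressors. Copy-neutral calls and genes without an assigned role
carry no directional interpretation and are removed with a reason.

## Signature model

SNVs are binned into the 96 pyrimidine-centric trinucleotide classes in
the COSMIC v2 order (substitution-major, then 5' and 3' flank), with
purine-reference calls reverse-complemented (`countContexts()`). Indels
carry no context and are skipped with a logged count; an SNV without a
context is an explicit error rather than a silent drop, because a
silently truncated spectrum biases the refit.

`refitExposures()` estimates per-sample exposures \(w\) against a catalog
\(P\) (signatures × 96) by **forward selection**: normalize the spectrum
to frequencies \(v\); repeatedly add the signature whose inclusion — with
all included weights re-optimized under \(w \ge 0\), \(\sum w \le 1\),
minimizing \(\lVert v - P^{\top} w\rVert^2\) — most reduces the error;
stop when the improvement falls below `tol` (default 1e-3). Weights below
the reporting cutoff (default 0.06, the convention of popular refitting
tools) are zeroed and the remainder re-optimized once. The inner solver
is projected coordinate descent to 1e-8; candidates tie-break by catalog
order, so the fit is fully deterministic. The residual \(1 - \sum w\) is
reported as unexplained signal rather than forced onto the catalog.

Samples are clustered on Euclidean distances between exposure vectors
(`clusterExposures()`). Average linkage is the default because only the
distance, not the linkage, is dictated by the analysis convention; the
cluster count `k` defaults to 3 to mirror the three shared-signature
groups the grouping step reports (`sharedSignatureGroups()`: the
signatures carried by *every* member of a cluster, bucketed as 1 / 2 /
≥3; an empty shared set yields the out-of-scheme label "0" with a
warning). Both are configurable. No exome-to-genome context
renormalization is applied.

## Phylogeny model

Events — SNVs, indels and directional copy-number events, keyed
`chrom:pos:ref:alt` and `gene:amp` / `gene:del` — are coded 0/1 per
lesion, with an all-zero normal taxon appended
(`buildBinaryMatrix()`). Clonality follows the standard partition
(`classifyClonality()`): truncal = present in all lesions, private =
exactly one, shared = otherwise.

Trees are sought by **exact maximum parsimony** (`searchParsimony()`):
all unrooted binary topologies are enumerated by stepwise addition for up
to 9 taxa; for 10–12 taxa the enumeration is pruned branch-and-bound
style using the partial-tree Fitch score, which is a lower bound because
restricting a character matrix to fewer taxa can only lower its length.
Pruning uses a strict inequality, so *all* minimum-score topologies are
returned, in lexicographic Newick order. Patient cohorts here have at
most 7 taxa (≤ 6 lesions + normal), where exhaustive search is cheap and
removes any heuristic nondeterminism. Characters are binary, unweighted
and unordered; no asymmetric (Dollo-style) penalty is imposed.

Scoring uses the Fitch state-set pass with duplicate columns collapsed to
weighted unique patterns. Rooting places the root on the normal taxon's
pendant branch. `assignBranchChanges()` fixes one minimal Fitch
assignment deterministically — state 0 preferred at the root, consistent
with the all-zero normal — and sets each branch length to the number of
events changing on that branch, so lengths always sum to the parsimony
score and a truncal event lands on the branch separating the normal from
all tumor taxa.

`bootstrapSupport()` resamples event columns with replacement (same
column count), recomputes the full minimum-score tree *set* per
replicate, and credits a clade only when it appears in the replicate's
strict consensus — ties therefore dilute support rather than inflate it.
Supports are percentages over `bootstrapReps` (default 100) annotated
onto the best tree. The conventional reporting thresholds are >95%
(strong) and 65–95% (moderate).

## What the simulator emulates — and what it does not

`simulatePatient()` generates the study design this pipeline targets:
patients with 2–6 lesions, each lesion sampling exactly one clone of a
rooted clone tree whose root carries the truncal events. The default
layout gives every lesion a private leaf clone; `lymphNodeEarly` inserts
two ancestral clones directly below the root so the lymph-node and tumor
lineages diverge first — the early-metastasis scenario — and
`nClones = 1` produces a purely clonal patient. Per clone,
`mutationsPerClone` events are drawn: SNV contexts from the clone's
signature mixture over a toy catalog (`makeToyCatalog()`: sparse random
spectra with pairwise cosine ≤ 0.7 so refitting is identifiable), 5%
indels without contexts, VAFs from Beta(20, 20) scaled by 0.5 purity,
depths Poisson(100) with a binomial strand split. Copy-number events are
planted per clone with the correct directionality, alongside copy-neutral
and role-less decoy rows. `plantFilterDecoys()` appends records violating
exactly one filter rule each, plus ClinVar-override records that must
survive. Everything is deterministic under the seed.

The generator is a validation instrument, not a sequencing simulator: it
has no subclonal mixing within a lesion, no copy-number-driven VAF
distortion, no coverage dropout, no FFPE artifacts, and lesions map to
single clones. Passing tests therefore demonstrate that the *analysis*
is correct under its own model assumptions — clean presence/absence
characters and identifiable mixtures — not that those assumptions hold
for any given real cohort.

## Numerical and degenerate-input choices

* Forward-selection stopping tolerance 1e-3 on squared-error improvement;
  coordinate-descent tolerance 1e-8; both chosen so desk-scale refits are
  exactly reproducible across platforms.
* Catalog rows must sum to 1 within 1e-6 on read; the reader errors
  rather than renormalizing, because a mis-scaled catalog is a data bug.
* All string orderings that feed output (Newick child order, event and
  sample ordering, manifests) use C-locale radix sorting, so runs are
  byte-identical regardless of locale.
* Degenerate inputs fail loudly: an all-zero spectrum, a single-sample
  clonality partition, k exceeding the sample count, more than 12 taxa,
  an SNV without context, a missing CNV table while copy-number tree
  characters are enabled.
* An event reported twice in one sample collapses to one matrix column;
  all-zero columns are dropped by construction.

## Validation scale

The test suite and `scripts/acceptance.R` validate against independent
oracles at these sizes, chosen as the package's own validation design:
200 random matrices (4–6 taxa, ≤ 12 columns) against brute-force
minimization over all internal labelings and complete topology
enumerations; 10 × 20 planted decoys per filter rule; 50 simulated
patients for clonality; 50 early-divergence simulations with 100
bootstrap replicates; 200 simulated spectra (500 mutations each) for
exposure recovery, with noiseless mixtures checked against dense
non-negative least squares; and byte-level comparison of repeated
pipeline runs for three seeds.

## Known limitations

* Presence/absence conflates absence with non-detection; no cross-sample
  re-interrogation of borderline calls is attempted, matching the
  upstream tables this package consumes.
* CNV events enter trees as single binary characters per gene and
  direction; dosage and segment structure are ignored (the
  `phyloUseCnv` switch removes them entirely).
* Signature refitting is limited to a user-supplied catalog (no de novo
  extraction) and to SNVs; indel/doublet signatures are out of scope.
* The parsimony search is exact but bounded at 12 taxa; cohorts beyond
  that need heuristic tree search, which this package intentionally does
  not provide.
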