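---
title: "Comparative gene- and genome-centric metagenome profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gene- and genome-centric metagenome profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgprofiler)
```

# Scope

`mgprofiler` implements the analysis layer of a comparative fecal-metagenome
study design: two host animals (for example a specialist and a generalist
herbivore), each shotgun-sequenced at several time-points, each host's reads
co-assembled, coding sequences (CDSs) predicted and annotated upstream with
KEGG Orthology (KO) labels and CAZy family domains, contigs binned into
population genomes with completeness and contamination estimates. Everything
upstream of the annotation tables — read QC, assembly, mapping, gene calling,
HMM searches, binning, marker-gene quality estimation — is out of scope and
enters only as validated input tables.

The package answers five questions about such data:

1. What is the community-wide capacity for lignocellulose degradation, and
   how does it compare across communities? (coverage-weighted CAZyme
   profiles, GH category tables, CAZy class tests)
2. Which metabolic pathways differ between the two hosts? (cumulative
   pathway profiles, Welch + Benjamini–Hochberg)
3. How do the communities cluster, and which lineages discriminate the
   hosts? (Bray–Curtis, UPGMA, effect-size ranking)
4. What do the population genomes contribute individually? (abundance,
   pathway coverage, PCA, contributor score, urea screen, genome-size
   summary)
5. How related are genome pairs across hosts? (reciprocal-best-hit average
   amino-acid identity)

# Coverage weighting

All gene-centric profiles use one weighting rule: a feature's weight in a
sample is the sum of the *mean contig read depths* of the CDSs that carry
the feature, divided by the summed contig depth of **all** CDSs, annotated
or not. The denominator choice makes profiles comparable across samples and
invariant to sequencing effort: multiplying every depth by a constant leaves
every profile unchanged (a tested invariant).

Two counting decisions matter:

* A CDS with domains of *k* distinct CAZy families contributes its contig
  depth once to each family, but repeated domains of the same family within
  one CDS count once. This prevents multi-domain genes from inflating their
  family. The same unique-CDS rule is used when reporting the percentage of
  lignocellulolytic CDSs among all CDSs.
* Per-CDS depth is the mean depth of the CDS's contig, not a per-base
  recomputation. Mean contig depth is what standard coverage tables carry;
  at typical contig lengths the difference is negligible and the choice is
  applied uniformly.

KO weights are assigned to **all** pathways a KO belongs to (a KO in *m*
pathways contributes its full weight to each). Pathways observed with fewer
than `min_kos_per_pathway = 3` distinct KOs are excluded from cumulative
profiles: a pathway attested by one or two KOs is more likely annotation
noise than genuine capacity, and its proportion estimate would be dominated
by a single gene.

The lignocellulolytic GH table restricts the CAZy profile to the 33 GH
families with known roles in plant-fiber degradation, in four categories
(cellulases; endohemicellulases; accessory hemicellulases;
oligosaccharide-degrading enzymes), renormalises per-family weights within
that scope so the four category subtotals sum to 100% per sample, and
averages across time-points with an unweighted arithmetic mean. Rounding to
one decimal happens only at presentation; all computation is on full
precision. The package ships the published cross-biome per-family
percentages (koala and wombat feces, wallaby foregut, cow rumen, termite
hindgut, switchgrass compost) as a static reference table
(`reference_gh_profiles()`); these literature columns are constants, not
recomputed quantities. Note that at one-decimal precision a few printed
subtotal cells in the original table differ from their printed row sums by
0.1 — rounding of the underlying unrounded values — so category subtotals
recomputed from the printed per-family values reproduce most, not all,
printed subtotals exactly.

The five-class CAZyme comparison (cellulose GH, hemicellulose GH,
oligosaccharide GH, auxiliary activity, other GH) classifies
hemicellulose-targeting enzymes as endo- plus accessory hemicellulases, and
"other GH" as any GH family outside the four lignocellulose categories.
Whether such class fractions should use unique-CDS or per-domain weighting
is not standardised in the field; this package applies the per-family-once
rule uniformly and documents it here.

# Differential statistics

Per feature (pathway, taxon, or CAZy class), group means are compared with
Welch's *t*-test (unequal variances, Satterthwaite degrees of freedom,
two-sided), implemented via `stats::t.test`. Compositional profiles
frequently contain degenerate features, so the conventions are explicit:

* both groups zero-variance with equal means → p = 1;
* both groups zero-variance with unequal means → p = 0;
* features that are all-zero across both groups are dropped before testing,
  with the count reported as an attribute.

Pathway-mode results are flagged at Benjamini–Hochberg *q* < 0.05
(`stats::p.adjust`); taxon-mode results at raw *p* < 0.05, matching the
different conventions used for pathway and community-structure comparisons
in this study design. Effect size is the difference in mean proportions
(group A minus group B) — small pathways necessarily have small effects, so
ranked reports are by |effect| among flagged features, with lexicographic
feature-id tie-break for reproducibility.

# Community structure

Taxon profiles are filtered at 0.05% relative abundance (retained if any
sample reaches the floor; removed mass is logged, never silently dropped),
renormalised per sample, and compared with abundance-weighted Bray–Curtis
dissimilarity, `1 − 2·Σ min(x,y) / Σ (x+y)`. Renormalising after the filter
is a documented choice: the filter removes at most a few tenths of a percent
of mass, and renormalisation keeps the dissimilarities on closed
compositions. Two all-zero samples are defined as distance 0 with a warning.

Clustering is UPGMA (average linkage), written in the package rather than
delegated to `stats::hclust` for one reason: the agglomeration order is made
deterministic and input-order invariant by sorting labels first and breaking
distance ties by the lexicographically smallest pair of cluster
representatives. On tie-free inputs it agrees with `hclust(method =
"average")` exactly (a tested oracle). Dendrograms export to Newick via
`ape`.

Family-level aggregation sums descendant lineages; rows unclassified at the
target rank aggregate under their deepest classified ancestor with an
`unc` label, following common community-profile presentation.

# Genome-centric metrics

* **Quality filter**: completeness ≥ 50% and contamination ≤ 10%, inclusive
  thresholds, rejects logged with reason.
* **Abundance**: a bin's relative abundance in a sample is its
  length-weighted depth fraction, `Σ length·depth` over bin contigs divided
  by the same sum over all contigs — the bin's share of sequenced bases.
  "Average coverage normalised to total coverage" is ambiguous about length
  weighting; the length-weighted form is the one that equals the read
  fraction a genome attracts, which is the quantity abundance plots report,
  and it makes bin abundances plus the unbinned fraction sum to exactly 1.
* **Top-N selection** (default 15 per community) sorts by median abundance
  across time-points, breaking ties by mean abundance (a genome with median
  0 can still be ranked by its mean), then bin id.
* **Pathway coverage** of a bin is |bin KOs ∩ universe| / |universe|, where
  the universe is the union of that pathway's KOs observed across *all*
  passing bins from both communities. Coverage is therefore relative to
  what the recovered genomes collectively encode, not to the full KEGG
  pathway definition, and is monotone under KO addition (tested).
* **PCA** of genome pathway profiles is column-centred covariance PCA (no
  scaling) via SVD, treating each genome as a composition of pathway
  proportions; scaling to unit variance would overweight rare pathways.
  Signs follow the largest-magnitude-loading-positive convention.
* **Contributor score** = number of distinct KOs of a bin that belong to at
  least one differential pathway, divided by completeness as a fraction.
  The source material describes this weighting both as "inversely weighted
  by genome completeness" and as "weighted by estimated genome
  completeness"; division by the completeness fraction is adopted — a
  50%-complete genome's observed KO count is doubled, correcting recovery
  bias — and flagged here rather than silently chosen. The ranking is
  invariant to expressing completeness in percent or fraction.
* **Urea screen**: transport-capable iff all five Urt ABC-transporter
  subunits or the monomeric Utp channel are present; ureolysis-capable iff
  all three structural urease subunits are present; `full_suite` is both.
  Accessory-protein completeness is reported but does not gate the call.
  The KO identifiers ship as an editable configuration
  (`urea_ko_config()`) because gene products, not KO ids, define the
  screen; defaults are the curated KEGG assignments for UrtABCDE
  (K11959–K11963), Utp (K08717), UreA/B/C (K01428–K01430) and UreD/E/F/G.
* **Genome-size summary**: abundance-weighted mean of size/completeness —
  a whole-community average of estimated complete genome sizes, a
  deliberately simple assembly-based companion to read-based
  average-genome-size estimators, which are out of scope.

# Average amino-acid identity

Orthologs between two proteomes are reciprocal best-scoring hits under
**exact** affine-gap Smith–Waterman local alignment (Gotoh recurrences) —
not a seeded heuristic — with BLOSUM62 and gap open 11 / extend 1, the
familiar protein-search defaults, so scores are comparable to BLASTP
conventions. "Best-scoring" uses the raw substitution score (bit-score
conversion would not change the ranking under fixed parameters). Hits must
reach 30% identity and 70% coverage; coverage is aligned columns (gap
columns included) divided by the length of the shorter sequence, and
identity is exact residue matches over aligned columns. Score ties break by
higher identity, then subject id. AAI is the mean of ortholog identities
with the population (n-denominator) standard deviation, since the orthologs
are the full population of interest, not a sample. Zero orthologs yield an
NA mean, never a silent zero.

Implementation note: the all-vs-all score matrix is computed with a lean
score-only kernel (C++), and identity/coverage are evaluated lazily, only
for best-hit candidates in descending score order, with caching across the
two directions. This is exact — every candidate that could be the best
passing hit is evaluated — and the fast path is tested against a
brute-force full-matrix enumeration on toy proteomes. Where two co-optimal
alignments exist, their column and match counts can differ; the DP prefers
substitution continuation over gap states, deterministically. All-vs-all
cost is O(n²·L²); 200-protein proteomes of length 300 take seconds, and
full bacterial proteomes (thousands of proteins) minutes to hours — sample
or restrict proteomes accordingly.

# The synthetic community generator

Because the study's sequencing data live in an external archive, the
package carries a generator (`simulate_community()`) that emulates the
study design with known ground truth; every downstream stage is tested
against that truth. The generative model:

* **Shape**: two hosts, 15 population genomes each (the analysis depth of
  the genome-centric stage), host A sampled at 3 time-points and host B at
  5, matching the study design. Genomes have 6–12 contigs of 25–45 CDSs
  (600–1500 bp), sized so that the default KO load always fits on distinct
  CDSs.
* **Abundances** are lognormal (σ = 1 on the log scale — a typical spread
  for gut communities, giving dominant populations around 10–20%) and
  *persistent*: a base abundance per genome is drawn once and jittered per
  time-point with CV 0.3, reflecting the temporal autocorrelation of gut
  communities sampled weeks apart.
* **Coverage** of a contig is `depth_mean × genome abundance × lognormal
  noise` with CV 0.2 per contig per sample — multiplicative noise on mean
  depths, not Poisson read counts, because the pipeline consumes mean
  depths; the CV is the single noise knob.
* **Function**: a catalog of 40 shared pathways plus 5 differential
  pathways per host, 8 KOs each; each genome carries each KO of a pathway
  with probability 0.25, raised 3-fold for its host's differential
  pathways. `spike_differential()` raises carriage of one pathway after the
  fact, for controlled detection experiments. GH domains land on 5% of
  CDSs, auxiliary-activity domains on 1% (×3 in host A when AA enrichment
  is simulated).
* **Bins**: completeness corruption removes whole contigs (the prefix of a
  random order whose size fraction is closest to a target drawn from
  60–95%), mirroring how incomplete bins actually lose sequence;
  contamination adopts foreign contigs from the removed pool (closest
  achievable to a 0–8% target), keeping bins disjoint. Reported
  completeness/contamination are the *achieved* values, so the metadata is
  always consistent with the contigs.
* **Proteomes** are i.i.d. residues from natural amino-acid background
  frequencies; divergent genome pairs are structural clones whose proteomes
  are mutated at a controlled per-site rate (`mutate_proteome()`), giving
  expected identity 1 − d. This is adequate for testing identity recovery
  and RBH logic, not for benchmarking aligner sensitivity on real protein
  families (no domain structure, no indels, no compositional bias).

What the generator does **not** emulate: assembly artifacts and chimeras,
strain mixtures, GC/mappability coverage bias, read-level noise,
phylogenetic correlation of gene content, real KEGG pathway topology.
Passing tests therefore demonstrate that the statistics and accounting are
correct under a controlled model — not that the pipeline is robust to every
pathology of real sequencing data.

## Null design for error-rate checks

A subtle point: two *independently generated* host communities genuinely
differ in pathway content (independent carriage draws), so they are not a
null. The type-I-error study therefore draws both sample groups from **one**
community process — one host simulated at 8 time-points, split 3 vs 5 — so
that no pathway truly differs and every flag is a false positive. The
power study spikes one shared pathway at fold-effect 4 in host A of a
two-host community and asks whether that specific pathway is flagged at
q < 0.05.

## Problem sizes used by the test and acceptance studies

The detection studies use 100 shared pathways (genomes enlarged to 10–15
contigs × 30–50 CDSs to carry the KO load), 20 null replicates and 50
spiked replicates; the weighting oracle uses 100 micro-communities of at
most 10 CDSs checked against brute-force enumeration at 1e−12; the AAI
study uses 200 proteins × 300 residues per proteome at divergences 0.05,
0.1, 0.2, 0.3, 0.5. These sizes give stable Monte-Carlo estimates (binomial
SE below 1.5 percentage points on the power estimate) while keeping the
whole suite within a few minutes on one core.

# Known limitations

* Coverage weighting uses contig mean depth; genes on unevenly covered
  contigs inherit the contig average.
* Welch's test on 3-vs-5 proportions has limited power and approximate
  calibration for strongly skewed features; the q-threshold controls FDR,
  not per-comparison error.
* The AAI thresholds (30%/70%) act on exact local alignments; heuristic
  tools applying the same thresholds to seeded alignments can return
  slightly different ortholog sets near the thresholds.
* The contributor score corrects KO counts for completeness linearly, which
  over-corrects genomes whose missing fraction is function-poor.
* All validation is against the synthetic model above; real-data behaviour
  depends on upstream annotation quality, which the package treats as given.
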