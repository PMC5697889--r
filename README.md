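# mgprofiler

Comparative gene- and genome-centric functional profiling of host-associated
metagenomes.

## The problem

Comparing the gut microbiomes of two host animals — say, a specialist
folivore and a generalist herbivore — from shotgun metagenomes requires a
chain of analyses downstream of assembly and annotation: community-wide
functional profiles weighted by how abundant each gene actually is,
statistical detection of pathways that differ between hosts, community
clustering from taxon tables, per-population-genome metrics (abundance,
pathway coverage, metabolic specialisation, urea recycling capacity), and
genome relatedness via average amino-acid identity (AAI). `mgprofiler`
implements that chain as tested, reusable functions for anyone analysing
per-CDS annotation tables, contig coverage tables, bin assignments, taxon
profiles and protein FASTA — the standard outputs of an
assembly-and-binning workflow.

## The methods at its core

* **Coverage-weighted profiles.** The weight of feature *f* (a CAZy family
  or a KEGG Orthology label) in sample *s* is

  w(f, s) = Σ_{CDS carrying f} depth(contig(CDS), s) / Σ_{all CDS} depth(contig(CDS), s)

  so profiles are relative to the whole gene complement and invariant to
  sequencing depth. Glycoside hydrolases are aggregated into the four
  lignocellulose-degradation categories (cellulases, endohemicellulases,
  accessory hemicellulases, oligosaccharide-degrading enzymes) and
  renormalised so the four subtotals sum to 100%; a published cross-biome
  reference table ships with the package for comparison.
* **Differential features.** Welch's *t*-test per feature across the two
  hosts' time-points, Benjamini–Hochberg FDR (pathways flagged at
  *q* < 0.05; taxa at *p* < 0.05), ranked by effect size = difference in
  mean proportions.
* **Community structure.** 0.05% abundance filter, abundance-weighted
  Bray–Curtis dissimilarity `1 − 2·Σ min(x,y)/Σ(x+y)`, deterministic UPGMA
  clustering, host-discriminating lineage ranking.
* **Genome metrics.** Bin quality filter (completeness ≥ 50%,
  contamination ≤ 10%), length-weighted abundance (a bin's share of
  sequenced bases), top-15 selection by median abundance, pathway coverage
  against the cross-community KO universe, covariance PCA of pathway
  profiles, a completeness-weighted differential-metabolism contributor
  score, and a urea transport/ureolysis screen.
* **AAI.** Orthologs as reciprocal best-scoring hits under exact affine-gap
  Smith–Waterman (BLOSUM62, gap 11/1; ≥ 30% identity, ≥ 70% coverage of the
  shorter protein), mean ± SD identity across orthologs. The alignment
  kernel is compiled (Rcpp) and cross-checked against
  `Biostrings::pairwiseAlignment`.
* **Synthetic communities.** A generator with known ground truth (true
  abundances, true differential pathways, true proteome divergence)
  emulates the two-host study design, so every stage is validated
  end-to-end without external data.

## Worked example

```r
library(mgprofiler)

# a two-host community: 15 genomes per host, 3 + 5 time-points,
# one genome pair at 20% proteome divergence
sim <- simulate_community(sim_config(seed = 42, proteome_divergence = 0.2))

# lignocellulolytic GH category subtotals for host A (percent)
gh <- gh_relative_profile(sim$cds, sim$cov, sim$catalog,
                          samples = sim$groups[[1]]$sample_ids)
round(gh$subtotals, 1)
#>                 cellulase         endohemicellulase   accessory_hemicellulase
#>                      22.6                      19.6                      26.3
#> oligosaccharide_degrading
#>                      31.5

# differential pathways between hosts (Welch + BH, q < 0.05)
m <- pathway_profile_matrix(sim$cds, sim$cov, sim$catalog)
res <- differential_features(m, sim$groups[[1]], sim$groups[[2]])
head(res[res$flagged, c("feature", "effect", "q", "enriched_in")], 3)
#>   feature      effect            q enriched_in
#>  path_b02 -0.01939049 1.228600e-07       hostB
#>  path_b04 -0.01704564 7.550578e-06       hostB
#>  path_b03 -0.01571142 1.851832e-04       hostB

# AAI between the simulated divergent genome pair (true divergence 0.2)
pair <- sim$truth$divergence_pairs
aai(sim$proteomes[[pair$genome_a]], sim$proteomes[[pair$genome_b]])
#> AAI: 80.0% (SD 2.6%) across 199 orthologs
```

The four subtotals sum to 100% by construction; the flagged pathways are
the generator's host-differential pathways (`path_a*`/`path_b*`), ranked by
how much their mean community proportion differs between hosts; the AAI of
the pair mutated at 20% per-site divergence recovers the expected 80%
identity.

## The analysis workflow

`analysis/` contains numbered drivers that run the whole study on a
simulated community and write tables under `results/`:

| script | writes |
| --- | --- |
| `01_simulate_communities.R` | community tables + ground truth |
| `02_gene_profiles.R` | GH category table, CAZy class fractions/tests |
| `03_differential_pathways.R` | differential pathway report |
| `04_community_structure.R` | family profile, Bray–Curtis matrix, Newick dendrogram, discriminating lineages |
| `05_genome_metrics.R` | top genomes, pathway coverage, PCA, contributor scores, urea screen |
| `06_aai.R` | AAI per divergent genome pair |

Run them in order with `Rscript analysis/0*.R` after installing the
package.

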