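---
title: "Strain phylogenomics from damaged ancient metagenomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain phylogenomics from damaged ancient metagenomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleostrain)
```

## The problem

Dental calculus preserves microbial DNA for tens of thousands of years, but in
a form that resists ordinary comparative genomics: reads are short (tens of
bases), carry characteristic cytosine-deamination damage at their ends, and
each sample covers any one genome unevenly and incompletely. `paleostrain`
implements the reference-anchored workflow used to reconstruct strain-level
phylogenies of oral archaea (e.g. *Methanobrevibacter*) from such material:

1. authenticate reads as ancient from their terminal misincorporation
   profile;
2. rebuild a per-sample draft genome by consensus over a strictly filtered
   pileup, gap-filling everything that does not meet the evidence thresholds;
3. screen samples by breadth of coverage;
4. stack draft genomes (and local-alignment hits of assembled contigs) into a
   reference-anchored whole-genome alignment and clean it;
5. build a distance phylogeny, iteratively masking homologous-recombination
   tracts until none are detected;
6. delimit species by average nucleotide identity (ANI) and derive core and
   species-specific gene sets from a pangenome presence/absence matrix.

Because the real data these procedures were designed for cannot be bundled,
the package ships a synthetic ancient-metagenome generator with complete
ground truth; every stage is validated by parameter recovery against that
truth.

## The synthetic generator and what it emulates

`sim_params()` fixes the study conditions. The defaults describe a small
archaeal community of the kind the pipeline targets:

* **Divergence structure.** A random ancestor (GC 0.30, typical of oral
  *Methanobrevibacter*) is evolved under the exact Jukes–Cantor kernel to
  `n_species` species ancestors and then along a Yule strain tree per species.
  Divergence parameters are *expected pairwise* substitutions/site: the strain
  tree is rescaled so its maximum root-to-tip depth is half
  `within_species_divergence` (default 0.01, matching the ~0–2% clonal
  spread seen among ancient strains), and species ancestors sit half of
  `between_species_divergence` (default 0.15) from the common ancestor, so
  between-species ANI falls below the ~95% species boundary by a wide margin.
  A fixed topology can be supplied where a determinate truth comparison is
  needed.
* **Recombination.** Imports arrive as a Poisson process per branch; tract
  lengths are geometric with mean `mean_tract_length` (default 2000 bp,
  kb-scale) and the imported copy carries `tract_divergence` extra
  substitutions/site (default 0.05), the direct analog of the
  rate/tract-length/divergence parameterisation used by clonal-frame
  detectors. Two donor models exist: `"external"` (default) mutates the
  recipient's own clonal frame — an import from outside the sample — while
  `"within"` copies the tract from another sampled lineage. The distinction
  matters: an external import adds the same extra distance from the recipient
  to every other taxon, which lengthens its pendant branch but provably cannot
  change the neighbor-joining topology of exact distances, so topology-level
  stress tests require the within-sample donor. `inject_recombination()`
  splices a single controlled import for such experiments.
* **Reads.** Fragment lengths are log-normal (mean 60 bp, floor 25 bp — the
  usual post-merging minimum). C→T substitutions are applied at the read 5'
  end with probability `damage_rate_5p * exp(-damage_decay * (pos - 1))`
  (defaults 0.3 and 0.5; the source studies show plots rather than numbers,
  so the magnitude is the conventional one), with symmetric G→A damage at
  the 3' end; reverse-strand reads are damaged in read orientation, as the
  chemistry dictates. Sequencing error is uniform per base. Emitted
  alignments are the *true* placements — no mapper is run — and simulated
  genomes are colinear, so those coordinates are valid against any genome of
  the set used as reference.
* **Coverage.** `coverage_mode = "uniform"` places fragments uniformly, which
  leaves terminal sites under-covered and interior depth Poisson-distributed
  — realistic, but incompatible with tests that require every site callable.
  `coverage_mode = "tiling"` lays staggered end-to-end passes so every site
  reaches at least `round(depth_per_strain)` reads; it exists purely as the
  controlled-truth mode for exactness tests.

What the generator does **not** emulate: library-preparation variants (UDG
treatment), paired-end merging artefacts, indels and rearrangements (genomes
are substitution-only and colinear), contamination from other taxa, and
mapping ambiguity (alignments are true placements). Tests passing on this
generator therefore demonstrate the correctness of the *inference rules*, not
robustness to mapping error or structural variation.

## Filters and boundary semantics

All thresholds follow one convention: the gap-filling conditions are stated as
strict "below" exclusions, so **equality passes**. A read with mapping quality
exactly 30, aligned length exactly 30 nt or identity exactly 0.97 is retained;
a site with depth exactly 3 or dominant allele frequency exactly 0.80 is
called. Read identity is matches over aligned columns with indel columns
counted as mismatches; a tie for the most frequent allele has no dominant
allele and is gapped. The breadth screen (present when at least 50% of the
reference is covered) uses the same inclusive depth-3 rule as the consensus
filter; the source text's "covered at >3X" conflicts with its own
"coverage < 3 folds" filter and the single reconciled rule `depth >= 3` is
used for both, configurable via `pipeline_config()`.

The alignment-cleaning rules are strict in the opposite direction, as printed:
rows are dropped when *more than* 50% gaps, then columns when *more than* 10%
missing among the surviving rows, in that order, exactly once ("and then").
Local hits enter the MSA only when *longer than* 500 bp and *above* 95%
identity. The core-gene rule is strict (presence in more than 90% of genomes)
while the species-specific rule is inclusive (at least 90% at home, zero
genomes elsewhere) — the latter is phrased as "shared by 90%" rather than
">90%", and the contrast is preserved deliberately; both are configurable.
One further convention: a terminal damage fraction is defined only where its
denominator is positive (a position with no reference-C observations is
reported as `NaN`, not 0).

## Numerical and algorithmic choices

* **Trees.** Maximum-likelihood estimation under GTR+Γ is not reimplemented;
  the built-in builder is neighbor joining on Jukes–Cantor distances with
  pairwise deletion, with two conventions pinned down for reproducibility:
  Q-matrix ties break on the lexicographically smallest pair of cluster ids
  (a cluster is named by its smallest member leaf), and negative branch
  lengths are clamped to zero with the deficit moved to the sister branch.
  `iterative_mask_phylogeny()` accepts any `function(msa) -> tree` builder, so
  an external ML tool can be substituted via aligned-FASTA/newick files; the
  loop structure, not the tree builder, is the contribution here. Distances
  with mismatch fraction ≥ 0.75 are saturated and reported as `NA`.
* **Recombination detection.** The clonal-frame detector is a windowed
  clustered-substitution scan: per row, substitutions are disagreements with
  the column majority (gaps excluded, ties broken A<C<G<T), and windows
  (default 1000 columns, step 100) are flagged when their count exceeds the
  Bonferroni-corrected Poisson critical value with rate = row substitution
  density × comparable sites in the window. This detector has a known blind
  spot that the full clonal-frame machinery does not: an import that moves a
  row *toward* the column majority (a donor lineage whose allies form half
  the alignment) is attributed to the minority rows instead. The bundled
  stress scenario therefore uses a 5+2 clade structure, where the recipient
  of a cross-clade import remains the column minority and is flagged
  correctly. Masking replaces tract cells with gaps; masked cells accumulate
  strictly, which (with the finite alignment) guarantees termination, and a
  detector that re-reports already-masked tracts terminates the loop rather
  than spinning.
* **Local alignment.** Hits are found by exact-word seeding (word size 9)
  with ungapped X-drop extension on both strands — sufficient for the
  substitution-only regime the generator produces and for ≤ ~15% divergence,
  where the expected score per column stays positive. Indels in real data
  split hits rather than extending through them. Reverse-strand hits are
  reported with forward query coordinates and reference-oriented aligned
  strings. Overlapping hits are resolved by identity, then length, then
  leftmost position; query insertions relative to the reference are dropped,
  which is what keeps the alignment rectangular in reference coordinates (the
  price, as with any reference-anchored model, is blindness to rearrangement).
* **ANI.** ANIm-style whole-genome alignment is approximated by cutting the
  query into consecutive 1000-bp fragments and taking each fragment's best
  local hit (ANIb-style decomposition); bit-compatibility with external ANI
  tools is not claimed — the acceptance standard is parameter recovery on
  simulated divergence. A best hit must be at least 100 columns long and 30%
  identical to count: without the length floor, spurious 9-mer matches
  between unrelated genomes would enter the mean with deceptively high
  identity. ANI is direction-dependent; both directions are computed and the
  symmetrised mean is used for single-linkage species delimitation at ANI
  distance strictly below 0.05.
* **Gene clustering.** Greedy centroid clustering: sequences sorted by
  decreasing length (ties by id) join the first centroid at or above the
  identity threshold under banded global alignment (matches over all
  alignment columns, end gaps penalised), or found a new cluster. Since
  identity cannot exceed the shorter/longer length ratio, pairs below the
  ratio are skipped without alignment. Paralog splitting and synteny, as in
  full pangenome pipelines, are out of scope; recovery of designed gene
  families is the validation standard. Core blocks are concatenated in
  sorted cluster-id order, each member projected onto its centroid's
  coordinates (degenerate centre-star without insertion columns — exact for
  the generator's equal-length families).

## Problem sizes

The bundled tests and the acceptance script run on deliberately desk-scale
problems chosen so that every quantity is still statistically decisive:
20–25 kb genomes, 3 species × 4 strains for ANI and delimitation, ~50,000
reads for damage recovery (binomial standard error ~0.005 at the terminal
position), 50 random 8-taxon trees for NJ recovery, 100 clonal replicates for
the detector's false-positive rate, and 200 gene families across 12 genomes
for the pangenome rules. The recombination stress scenario uses a 4 kb
alignment of seven strains with a single 2 kb within-sample import (ν = 0.05)
— an import spanning half the alignment, because a distance-based topology can
only be distorted when the imported fraction outweighs the internal-branch
signal, and at 10 × tract-length genome sizes such imports provably cannot
flip the tree. The demonstration (`run_demo()`) fixes a balanced 4-strain
topology so the truth comparison is determinate while mutations, fragments
and damage remain seed-driven.

## Known limitations

* The reference-anchored MSA inherits every limitation of the model: no
  rearrangements, no large indels, and regions absent from the reference are
  invisible.
* The windowed detector reports rectangular tracts at window resolution and
  mis-attributes majority-joining imports (see above); it is a surrogate
  honouring the iterate-until-clean loop, not a clonal-frame reconstruction.
* NJ on JC distances is a consistent but less efficient estimator than ML on
  a full substitution model; supports come from column bootstrap of the
  distance pipeline.
* ANI values are exchange-compatible with fragment-based ANI conventions but
  not bit-identical to any external tool.
* The damage model is unstranded single-end; UDG-treated or half-treated
  libraries would need their own terminal profiles.
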