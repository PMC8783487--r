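---
title: "Genome-based species delineation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based species delineation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxgenomics)
```

## The problem

Modern bacterial taxonomy places a new isolate by comparing its draft
genome against the type strains of its nearest phylogenetic neighbours.
Two overall genome relatedness indices carry the decision: the average
nucleotide identity (ANI), with a species boundary at about 95--96%, and
digital DNA--DNA hybridization (dDDH), with the classical 70% boundary
inherited from wet-lab hybridization. Around these sit supporting
analyses: 16S rRNA similarity with an explicit nucleotide-difference
count, distance trees, a reciprocal-best-hit pan-genome that partitions
genes into core, accessory and strain-specific sets with COG-category
profiles, a comparative feature table (genome size, G+C, rRNA/tRNA/CDS
counts, median CDS length) with a CDS-count-versus-size regression, and a
gene-inventory screen for plant-growth-promoting (PGP) functions. This
package implements that workflow end to end for *Nocardia*-scale
actinobacterial genomes, together with a synthetic genome evolution module
so that every stage can be validated against planted ground truth without
downloading assemblies.

## Fragment-based ANI

`orthoani()` follows the OrthoANI conventions: both genomes are cut into
non-overlapping 1020-bp fragments (trailing remainders discarded;
fragments with more than 20% ambiguous bases dropped), every fragment of A
is aligned against its best-matching fragment of B and vice versa, and a
fragment pair contributes only when the two fragments are each other's
best hits with identity at least 0.35 and aligned coverage at least 0.7 of
the fragment length. ANI is the mean identity over reciprocal pairs,
averaging the two alignment directions. The aligner is the package's own
seed-and-extend kernel (exact 13-mer seeds on both strands; banded
affine-gap dynamic programming with match +2, mismatch −3, gap open 5,
gap extend 2, band half-width 32 around the seeded diagonals). All
constants live in `ani_config()`.

Two properties anchor correctness. Self-comparison is exact:
`orthoani(g, g)` returns 100.0 and every fragment pairs with itself. And
on substitution-only simulations the estimator is unbiased to within
sampling noise: with per-site substitution probability $p$, the expected
identity of every reciprocal pair is $1-p$, so ANI should equal
$100(1-p)$; over a 200-kb genome (~196 fragments) the binomial standard
error is below 0.1 percentage points, and the test suite requires
agreement within 0.5.

```{r ani-demo}
sp <- simulate_genome_pair(102000, gc = 0.5, p = 0.05, seed = 1)
orthoani(sp$a, sp$b)
```

## Digital DDH distance

`ddh_distance()` implements the intergenomic distance preferred for draft
genomes: high-scoring segment pairs (HSPs) are collected from an
all-contig reciprocal search (every contig of A against B and the
reverse), and

$$ d_2 \;=\; 1 - \frac{\sum \text{identities}}{\sum \text{HSP length}} $$

over all retained HSPs. Identical genomes give $d_2 = 0$ exactly; a pair
with no retained HSP is flagged `no_homology` and assigned $d_2 = 1$ by
convention. HSPs come from the same seed-and-extend kernel run in local
(Smith--Waterman) mode within the band, so segments bounded by
non-homologous sequence are trimmed to their maximum-scoring extent;
retention requires at least 100 aligned columns, identity at least 0.3 and
a positive alignment score. The score floor matters: with affine gaps an
alignment can otherwise harvest spurious "identities" through cheap gap
columns in unrelated sequence.

The mapping from $d_2$ to a hybridization percentage is deliberately
pluggable (`ddh_config()`, backed by the packaged `ddh_mapping.json`). The
default is a logistic curve
$\mathrm{dDDH} = 100/(1+e^{-(a + b\,d_2)})$ with $a = 2.1494$,
$b = -38.754$, a calibration anchored at the field-standard species
boundary -- 70% dDDH at $d_2 = 0.0336$ -- and consistent with the
published pattern that genomes at about 80% ANI report dDDH near 24%. The
package validates any supplied mapping for monotonicity only; users who
need a specific published generalized-model coefficient set can supply it
directly, and the distance $d_2$ itself is always reported alongside the
mapped percentage so downstream comparisons need not depend on the curve.

Classification (`classify_species()`) uses ANI ≥ 95 (the conservative end
of the 95--96% range) or dDDH ≥ 70 to call two genomes conspecific;
either measure may be missing.

## 16S marker similarity

`pairwise_global_identity()` performs a semi-global alignment (terminal
gaps free; match +1, mismatch −1, gap −2 per column, via Biostrings) and
reports similarity under an explicit convention:

$$ \text{similarity} = 100 \cdot
   \frac{L - \text{differences} - \text{internal gap columns}}{L}, $$

where $L$ counts all columns between the first and last aligned pair,
`n_differences` counts substitution columns only and internal gap columns
are reported separately. Identification servers do not publish their
denominator; this convention reduces to $100(L-k)/L$ on gap-free pairs,
which makes the canonical calibration point exact: 20 differences over a
1523-bp marker is 98.69%. A served value of 98.6% for the same pair most
likely reflects a slightly shorter common region, which is why the package
asserts the difference count and the gap-free formula rather than
hard-coding either denominator choice.

## Distance trees

`neighbor_joining()` wraps classical NJ (via ape) with two guarantees:
input validation (symmetry to 1e-9, zero diagonal, at least 3 taxa) and
deterministic handling of negative branch lengths, which are clamped to
zero with the deficit moved to the sibling branch. On additive matrices NJ
is exact, which the suite verifies two ways: patristic distances of the
inferred tree reproduce the input matrix, and over random binary trees of
up to 12 taxa the Robinson--Foulds distance to the generating topology is
zero in 100/100 trials. Maximum-likelihood inference and bootstrap support
are out of scope: the distance pipeline does not retain site-level
characters to resample.

## Pan-genome orthology (POGs)

The pan-genome module replaces an external search tool with an in-repo
k-mer-prefiltered aligner. For each ordered genome pair every query
protein is aligned (full dynamic programming, BLOSUM62, gap open 11 /
extend 1) against candidate subjects that share at least one 5-mer; hits
below 30% identity or 50% query coverage are dropped. Reciprocal top hits
(ties broken by identity, then lexicographic gene id) define ortholog
pairs; `build_pogs()` merges them into pairwise orthologous groups as
connected components (single linkage). The merge rule is configurable
(`pair_only` keeps strict pairs) because "collections of reciprocally
linked orthologs" admits either reading; single linkage is the default as
the natural transitive closure. Partial genes left out of the graph are
attached afterwards by greedy centroid clustering at ≥95% identity
(inclusive), identity measured over the shorter sequence's length --
UCLUST's documented convention.

Core POGs have members in every genome; strain-specific genes belong to no
POG spanning two or more genomes; the rest are accessory.
`category_frequencies()` profiles one-letter COG categories separately for
the core and pan partitions, with unmapped genes counted as `unassigned`
so the characteristic contrast -- functional annotation coverage much
higher in the core than in the pan genome -- is visible in the output.

The prefilter is validated against a brute-force oracle (the same aligner
over all pairs, no prefilter): the prefiltered hit set must be a subset
and the per-query top hits identical. On simulated pan-genomes the
pipeline is required to recover at least 95% of planted families as single
POGs at 5% copy divergence and to classify every private gene as
strain-specific.

## Genome features, regression and trait screen

`feature_table()` assembles the comparative table (size in Mbp, G+C over
unambiguous bases to one decimal, rRNA/tRNA/CDS counts, median CDS
length). The median uses the lower-median convention for even counts --
a documented, tested choice where the source tables do not state one.
`ols_regression()` fits CDS count against genome size and reports
$R^2 = 1 - SS_{res}/SS_{tot}$; on the published six-genome feature table
this rounds to 0.94. Only $R^2$ is treated as a reproducible anchor: the
published regression-line notation is ambiguous about its coefficients, so
slope and intercept are reported but not asserted.

`trait_screen()` reads an editable catalog of PGP trait genes
(phosphate solubilization and regulation: *ppx-gppA*, *pstS*, *senX3*;
tryptophan/IAA pathway: *trpA/B/D/E/F*; auxin signaling: *pdxI*, *aad*;
ACC deaminase: *acc*; antibiotic and lytic functions: *fabG*, *bacC2*,
*hdhA*, *auaJ*, *tcmO*, chitinase, glucoamylase). A trait is present iff a
gene matches a symbol exactly (lowercased, hyphens stripped) or a
product-description pattern; every presence call records its evidence gene
ids so matches are auditable, and the screen is monotone: adding records
can never remove a presence.

## The synthetic data module

The simulators define the conditions under which the pipeline is tested,
and they are deliberately simple so every expectation is closed-form:

* `random_genome()` -- i.i.d. bases at a target GC, near-equal contigs.
* `mutate_genome()` -- per-site substitution with probability `p` to a
  uniformly chosen different base; substitution-only mode (the default)
  preserves length exactly, so expected identity is $1-p$. An indel mode
  (geometric lengths) exists to exercise gap handling but carries no
  closed-form acceptance value.
* `simulate_pangenome()` -- random coding genes (start codon, internal
  stops excluded by rejection so fixtures always translate), independently
  mutated per genome, embedded in random spacers on random strands, with a
  complete truth table. The default gene length range of 300--900 nt
  brackets the ~820--830 bp median CDS length of the actinobacterial
  genomes this workflow targets while keeping test runtimes at desk scale.
* `simulate_marker_pair()` -- exactly `k` planted substitutions, so the
  similarity is exact by construction.

Every generator runs in an isolated RNG scope seeded explicitly and
restores the caller's random state, so outputs are byte-reproducible and
independent of call order.

What these simulations do *not* emulate: rate heterogeneity, codon or
repeat structure, horizontal transfer, rearrangement, and real assembly
artefacts beyond simple N-runs. Passing tests therefore demonstrate the
correctness of the estimators under their own model assumptions -- an
unbiased ANI on i.i.d. substitution data, exact marker counting, complete
ortholog recovery at low divergence -- not that published values for real
genome pairs are reproduced to instrument precision. Reproducing the
published pairwise values requires the actual GenBank assemblies;
`analysis/06_reference_genomes.R` runs that comparison when pointed at a
directory containing them, with the expectation of agreement within about
0.5 ANI points and about 2 dDDH points given the aligner substitution.

## Numerical and design choices

* **Alignment determinism.** No randomness anywhere in the aligners;
  candidate and tie orders are fixed (score, then identity, then subject
  index/strand), so outputs are byte-stable across runs.
* **Local versus dovetail semantics.** Fragment pairing and HSP search use
  banded local alignment (alignments start and end anywhere in the band),
  which trims non-homologous ends; the partial-gene attachment step uses
  dovetail overlap alignment, which is the right notion for a fragment
  laid against a full-length centroid.
* **Ambiguity codes.** Accepted on input; anything other than A/C/G/T
  never counts as an identity, is excluded from the G+C denominator, and
  N-heavy fragments (>20%) are dropped before ANI.
* **Coordinates.** 1-based inclusive throughout (GFF convention);
  conversion to other conventions happens only inside the C++ kernels.
* **Repeat masking.** Seed k-mers occurring more than 64 times in a
  subject are ignored -- enough to keep simulated and draft-genome runs
  near-linear without distorting unique-sequence comparisons.
* **Problem sizes.** The test and acceptance runs use 100--500 kb genomes
  for self-comparisons, 200-kb pairs for estimator accuracy, a 4-genome /
  50-family / 220-gene pan-genome, and 100 NJ trials up to 12 taxa. These
  sizes put all closed-form expectations well inside their statistical
  tolerances while keeping the whole suite at desk scale; the kernels
  themselves run on full bacterial genomes (minutes per ~10-Mbp pair).

## Known limitations

* The dDDH percentage depends on the pluggable mapping calibration; the
  distance $d_2$ is the primitive quantity and should be preferred for
  quantitative comparisons across software.
* ANI/dDDH values for real genome pairs are approximated within the
  stated tolerances, not bit-reproduced, because the alignment kernel is
  not BLAST.
* The 16S similarity denominator is a convention (documented above);
  served values from identification databases may differ in the second
  decimal.
* The trait screen is annotation-driven: it finds what the supplied gene
  symbols and product descriptions say, with no remote-homology search
  behind it.
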