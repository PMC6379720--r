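---
title: "Measuring position-specific codon-pair conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring position-specific codon-pair conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircons)
```

## The question and the model

Synonymous codon choice modulates translation. Certain ordered pairs of
adjacent codons — typically built from suboptimal, wobble-decoded codons
such as CGA — inhibit translation in yeast well beyond what their two
codons do individually. If that inhibition is functional at specific gene
positions, purifying selection should keep the pair *in place*: across
closely related species, the identical pair should recur at the identical
alignment position more often than the conservation of its constituent
codons can explain.

`paircons` operationalizes this with strict-identity conservation against
a designated reference species. A reference codon is *conserved* when
every species in the alignment carries the identical codon in the same
alignment column; a reference codon pair is conserved when both columns
are conserved **and** the columns are consecutive, i.e. no species has an
insertion between them. Rates are

\[
c_i = \frac{\text{conserved occurrences of codon } i}
           {\text{reference occurrences of } i},\qquad
r_{ij} = \frac{\text{conserved occurrences of pair } (i,j)}
              {\text{reference occurrences of } (i,j)} .
\]

Under codon-wise evolution \(r_{ij} \approx \beta\, c_i c_j\); the package
fits \(\beta\) by least squares through the origin
(\(\beta=\sum xy/\sum x^2\)) and calls a pair an outlier when its residual
exceeds \(k\) sample standard deviations of the residuals (default
\(k=3\); positive means more conserved than predicted). Conservation in
excess of the codons is additionally scored within dipeptide families via

\[
\mathrm{score}_{ij} = \frac{r_{ij}+p}{(c_i+p)(c_j+p)}, \qquad
z_{ij} = \frac{\log \mathrm{score}_{ij} - \mu_{dp}}{\sigma_{dp}},
\]

where the family \(dp\) comprises every sense pair encoding the same
ordered dipeptide under the active genetic code, and \(\mu_{dp}\),
\(\sigma_{dp}\) are the family mean and sample standard deviation of the
log scores.

Assumptions worth keeping in mind: conservation is *identity*, not
similarity — there is no substitution model and no phylogeny; all species
in an alignment count equally; and the reference species defines both the
occurrence denominators and gene lengths.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k_sigma` | 3 | outlier threshold, in residual standard deviations |
| `pseudocount` | `"auto"` = 1 / total reference sense codons | additive constant in the normalized score; the smallest rate difference observable in the data |
| genetic code | table 1 (or 12) | table 12 (CUG as Ser) for *Candida*-clade genomes |
| `min_species` | 4 (of 5) | species that must carry a pair at the same location for gene-set membership |
| `window` | 10 codons | local conservation profile window |
| gap open / extend | 10 / 1, BLOSUM62 | protein-level alignment penalties |

The pseudocount default follows the logic that zero conservation cannot be
distinguished from conservation below one part in the reference codon
count. The log base in the z-score is irrelevant (it rescales scores and
family statistics jointly); natural log is used and a test asserts the
invariance.

## Alignment

Orthologous ORFs are aligned at the protein level and back-translated, so
alignment columns are codon-width by construction. The package ships its
own deterministic aligner — pairwise global Needleman–Wunsch with affine
gaps (Gotoh; end gaps penalized; ties broken diagonal > up > left),
assembled by center-star merging on the sequence with the highest summed
pairwise identity. This is not an attempt to match a production MSA tool
on hard cases; it keeps the artifact self-contained, and the downstream
statistics are alignment-agnostic. Externally produced codon alignments
can be ingested with `read_codon_alignment()`, which enforces codon-aware
gaps. When all member proteins are identical the gap-free alignment is
returned without dynamic programming — it is the optimum.

## Frame-shift and positional controls

If a pair's conservation reflected a conserved nucleotide motif rather
than translation, the same six-nucleotide sequence would look conserved in
any reading frame. `shifted_frame_conservation()` re-tokenizes the
reference nucleotides at +1 or +2, counts tri-nucleotide *units* (all 64;
frame-shifted units are not codons, so stops are not excluded) and unit
pairs under the same column-identity and no-insertion rules, and
`frame_shift_control()` z-scores each focal hexamer within the family of
unit pairs sharing its translated unit pair. Positional analysis records
each occurrence's relative position (first codon index over reference ORF
length, in (0,1]) and compares focal sets against random same-size pair
sets (`simulate_random_sets()`, seeded, uniform draws without replacement,
excluding the focal set by default).

## The synthetic-data generator

`generate_orthologs()` emulates the structure of a multi-species ortholog
dataset: hundreds of genes of 100–600 codons, codon sequences drawn from a
configurable frequency vector (uniform by default), and star-shaped
divergence — every non-reference species derives independently from the
reference/ancestor with a per-branch per-codon synonymous substitution
probability (default 0.3, giving per-codon conservation
\((1-0.3)^4 \approx 0.24\) across five species, in the range observed for
real yeast ORF sets), optional nonsynonymous substitutions and codon-level
indels (both 0 by default, which keeps proteins identical and alignments
trivially gap-free, isolating the statistics from aligner behaviour).

Planted codon pairs are written into the ancestor at uniform
non-overlapping positions (default: nine pairs, 50 occurrences each), and
a fraction of each pair's occurrences (default 0.4) is *locked*: copied
verbatim into every species and shielded from indels. A locked occurrence
is exactly what position-specific selection looks like to the statistics.
The default planted set uses nine rare-codon pairs (CGA-, CCG-, GCG-heavy)
chosen to encode nine *distinct* ordered dipeptides, so each family has
one planted member and within-family ranks have an unambiguous expected
winner; real inhibitory-pair sets share families (two Arg-Arg pairs, two
Leu-Pro pairs), which the ranking handles but which makes "ranks first in
its family" unattainable for both members at once.

What the generator does **not** emulate: realistic codon usage, tree-shaped
phylogeny, rate variation across genes and sites, GC/mutation bias, and
alignment error on diverged proteins. Passing recovery tests therefore
shows the statistics are correct and well calibrated under a neutral,
homogeneous null with planted signal — not that every property carries
over to real genomes.

## Calibration, and a caveat about the 3-sigma rule

On neutral genomes (no planted pairs) at the study scale — five species,
500 genes, substitution 0.3 — about 0.8% of the 3721 pairs land outside
the 3-sigma band (tests assert the mean stays at or below 1%), and the
fitted slope is 1 within ±0.05, matching the generator's neutral coupling.

The absolute number of flagged neutral pairs is, however, larger than a
normal 3-sigma tail (0.13% one-sided) would suggest, for two structural
reasons. First, the rule pools one residual sigma across pairs whose
sampling variances differ: pairs containing ATG or TGG — single-codon
amino acids that synonymous substitution cannot change, so their codon
conservation is 1.0 — have pair rates near 0.24 rather than 0.06, and
binomial variance up to four times the pooled value. They dominate both
tails (in a probe genome, 12 of 15 spurious above-line pairs and all
below-line pairs contained ATG or TGG). Second, with ~47 reference
occurrences per pair, binomial rate estimates are right-skewed. Both
effects shrink as the denominators grow (real five-species ORF sets have
hundreds to thousands of occurrences per pair), but at desk scale a
pooled-sigma rule should be read as a ranking device, not as a calibrated
0.1% test; the dipeptide-family z-score, which compares within families of
like composition, is the more robust discriminator. The recovery tests
reflect this: planted-pair recall and within-family ranks are perfect
across seeds while the count of spurious 3-sigma pairs per neutral genome
is ~15–25.

## Numerical and design choices

* **Pair adjacency.** Two consecutive reference codons always count toward
  the pair's denominator; conservation additionally requires consecutive
  alignment columns. An insertion from any species between the codons
  breaks positional identity but does not un-count the pair.
* **Outliers on residuals.** Outliers are defined on residuals of the
  origin-constrained fit of pair rate against codon-rate product (the
  operative scatterplot), not on normalized scores; the normalized score
  is used for the within-family z-scores and rankings.
* **Residual sigma** is the sample (n−1) standard deviation of residuals;
  at n ≈ 3721 the sample/population distinction is immaterial and is fixed
  for determinism. A zero sigma (degenerate, perfectly collinear input)
  yields no outliers and a warning.
* **Degenerate families.** Families with one member or zero spread (e.g.
  Met-Trp) get z = 0 with a `degenerate` flag rather than NaN.
* **Ranks** are "min" ranks: values 0.9, 0.5, 0.5, 0.1 rank 1, 2, 2, 4.
* **Undefined rates** (zero denominators) propagate as `NA` and are
  excluded from fits with a count, never treated as zero.
* **Initiator codons** are counted like any other sense codon; single-codon
  families keep their (high) conservation rather than being excluded.
* **Profiles.** The local conservation window is trailing and truncated at
  the ORF end; a window at least the ORF length returns the single
  whole-ORF rate.
* **Gene sets.** An ORF joins a focal/control set when a focal/control
  pair sits at the same aligned location in at least `min_species` species
  (reference included); ORFs qualifying for both go to the focal set and
  are reported as overlap.
* **Seeds.** Every stochastic operation takes an explicit seed; the
  pipeline driver derives stage seeds deterministically from the run seed,
  and reruns are byte-identical (provenance headers carry no timestamps).

## Problem sizes used by the test suite

The recovery and calibration suites regenerate twenty planted and twenty
neutral genomes at 500 genes x 5 species (~175,000 reference codons each),
the scale at which per-pair denominators average ~47; oracle-equivalence
suites use small random alignments where exhaustive nucleotide-level
comparison, alignment-path enumeration, margin-fixed Fisher enumeration
and KS permutation enumeration are feasible. These sizes were chosen so
the full suite exercises the pipeline end to end in a few minutes on one
core.

## Known limitations

* Strict identity makes no allowance for back-substitution or alignment
  ambiguity; conservation rates are lower bounds on positional constraint.
* The star-phylogeny generator cannot produce lineage-correlated
  conservation; real sensu-stricto trees will make species non-exchangeable.
* No masking of low-quality alignment regions is implemented.
* The positional null draws random pair *sets*; it does not model
  within-gene clustering of occurrences.
* GO-term enrichment and the derivation of external per-pair annotations
  (ribosome occupancy, expression scores) are out of scope; such data are
  consumed, if at all, as opaque annotation tables.
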