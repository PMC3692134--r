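---
title: "Structure-based prediction of DNA-binding specificity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based prediction of DNA-binding specificity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindspec)
```

## The problem and the model

A protein–DNA co-crystal structure fixes one binding sequence in one
geometry. `bindspec` estimates the *specificity* of the protein — how well
it would bind every nearby sequence — by exploiting two assumptions:

1. **Backbone rigidity.** A limited number of base-pair substitutions does
   not change the sugar–phosphate backbone conformation, so a mutant
   complex can be synthesized by replacing base moieties as rigid bodies on
   the fixed backbone. This is the central approximation; it degrades as
   the number of simultaneous mutations grows, which is why the default
   caps mutations at two.
2. **Statistical energetics.** The relative binding free energy of a
   complex can be ranked by a distance-dependent knowledge-based potential:
   atom-type pairs that occur at a given separation more often than the
   pooled background are favourable there.

The pipeline (`predict_specificity()`) enumerates all sequences within
`max_mutations` of the native site, synthesizes each mutant structure,
scores it, keeps the energetically plausible ones, and condenses them into
a position frequency matrix (PFM) that serves as the final, transferable
predictor.

## Rigid-body base replacement

Every base type carries a template in a canonical frame defined by three
geometric features of the base moiety:

* the **anchor**: the glycosidic nitrogen (N9 in purines, N1 in
  pyrimidines), placed at the origin;
* the **base plane**: the best-fit plane of all ring atoms (nine for
  purines, six for pyrimidines), its normal along +z;
* the **in-plane orientation**: the interior bisector of the flanking ring
  angle at the anchor (C4–N9–C8 for purines, C2–N1–C6 for pyrimidines),
  projected into the plane, along +x. This bisector is anti-parallel to the
  glycosidic bond direction, which is what makes purine-for-pyrimidine
  replacements geometrically sensible.

Mutation maps the template through the inverse frame of the base being
replaced — anchor onto anchor, normal onto normal, bisector onto bisector —
then deletes the old base atoms and renames the residue. Two numerical
choices matter here:

* **Plane-normal sign.** A best-fit normal is defined only up to sign; an
  inconsistent sign would flip bases by 180 degrees. The sign is fixed by
  the cross product of the two bisector-arm vectors at the anchor, which
  depends only on ring chirality and is therefore identical for a base and
  any proper rigid motion of it. (Tying the sign to an out-of-plane witness
  atom such as C1' was rejected as ill-conditioned: C1' lies essentially in
  the base plane.)
* **Proper rotations only.** Frames are orthonormal with determinant +1 by
  construction, so a placed base can never be the mirror image of its
  template.

`build_template()` implements template construction by structural
averaging: any number of base instances are mapped to the canonical frame,
averaged atom-wise (atoms missing from some instances are averaged over the
instances that carry them), and re-framed. The same procedure applies
whether five instances are averaged or ten thousand; the shipped defaults
are idealized regular-ring geometries (ring bond 1.38 Å, carbonyl 1.23 Å,
amino 1.34 Å, methyl 1.50 Å) generated in code.

RMSD between mutant and native is computed over equivalent atoms — same
chain, residue number, insertion code and atom name — **without**
superposition, because mutants live in the native coordinate frame by
construction; re-superposing would hide exactly the displacement the
number is meant to report.

## The knowledge-based potential

For protein atom type $i$, DNA atom type $j$ and distance bin $r$:

$$S(i,j,r) = -\ln \frac{P(i,j,r)}{P_{\mathrm{ref}}(r)}, \qquad
P(i,j,r) = \frac{N_{\mathrm{obs}}(i,j,r) + \epsilon}
                {\sum_r \left[N_{\mathrm{obs}}(i,j,r) + \epsilon\right]},$$

with $P_{\mathrm{ref}}(r)$ the type-pooled distance distribution. Because
distant shells contain many more atom pairs, $P_{\mathrm{ref}}$ grows with
$r$ and automatically shrinks $|S|$ at long range — it is the weight
function that damps long-distance noise. $\Delta G$ is the sum of $S$ over
all typed protein–DNA heavy-atom pairs within the cutoff, and
$\Delta\Delta G = \Delta G' - \Delta G_{\mathrm{native}}$.

Atom types are residue-specific, enumerated from the standard heavy-atom
dictionaries: 167 protein types (20 amino acids; OXT excluded so the
catalogue stays closed) and 82 DNA types (11 sugar–phosphate atoms per
nucleotide plus 10/11/8/9 base atoms for A/G/C/T). Waters, ligands and
nonstandard atoms are untyped and silently contribute nothing.

Tunable parameters, all arguments of `train_potential()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_width` | 0.5 | Å | fine enough to separate hydrogen-bond from van-der-Waals shells, coarse enough to populate bins at small training scale |
| `cutoff` | 15 | Å | beyond this, pooled mass dominates and scores are ~0 anyway |
| `pseudocount` | 0.5 | counts per (pair, bin) | keeps scores finite for unseen combinations; set to 0 for exact count-ratio arithmetic |

Two edge conventions: distance bins are left-open at multiples of
`bin_width` with the exact-cutoff distance assigned to the last bin, and a
bin with **zero pooled mass** (no training pair of any type at that
distance) scores 0 for every type pair — there is no information there,
and returning $-\infty$ would poison sums. Energies are reported
dimensionless ($kT = 1$).

## Selection, the PFM, and scoring

The flexibility criterion sets
$T = |\min_{\mathrm{mutants}} \Delta\Delta G|$ and keeps every mutant with
$\Delta\Delta G \le T$: a negative change is preferred, but a positive
change within the range indicated by the best mutant is still acceptable.
The native record is always kept. The selected sequences form the PFM with
unweighted counting (one vote per sequence, no pseudocount at
construction; energy-weighted voting was considered and rejected as an
extra free parameter with no calibration data at this scale).

Sequences are scored as
$\sum_j \log_2\left[(P[S_j, j] + 0.01) / 0.25\right]$ (bits against a
uniform background, pseudocount 0.01). Any strictly monotone transform of
the per-position product leaves every ranking unchanged, so evaluations
that use only rank order (AUC, top-k) are insensitive to this choice.
Within the pipeline the alignment offset is fixed at $k = 1$, because
mutant sequences are constructed pre-aligned to the PFM; scanning and
reverse-complement modes exist for external sequences
(`predict()` defaults to both).

The Psi divergence between two column-normalized PFMs,
$\Psi = \frac{1}{w}\sum_j \sum_i
(\hat w_{ij} - w_{ij})^2 / (\hat w_{ij} + w_{ij})$ with $0/0 = 0$, is 0 on
identical matrices, symmetric, bounded, and smaller for more consistent
motifs. Unequal widths are handled by `align_pfms()`, which scans all
ungapped offsets on both strands and minimizes the overlap-averaged Psi
(ties prefer larger overlaps, then the forward strand). The per-width
normalization and the exact constant of this form are a documented
convention, isolated behind `psi_test()`.

## Pairing, contacts and parsing conventions

* Bases pair when they are Watson–Crick complementary and their pivot
  atoms (purine N1, pyrimidine N3) lie within 3.5 Å; a duplex needs at
  least three consecutive pairs and strictly antiparallel partner order.
  The criterion is deliberately cheap and exact on both idealized fixtures
  and well-formed crystal structures.
* A base pair contacts the protein when any heavy atom of either **base
  moiety** is within 4.5 Å of any protein heavy atom. Sugar–phosphate
  atoms are excluded: backbone-only contacts are not base-readout and
  would flag pairs whose identity the protein cannot see. This is a
  documented judgment call; the threshold and the atom set are arguments.
* Parsing keeps heavy atoms only (hydrogens and deuteriums dropped), keeps
  the blank/'A' alternate location, treats MSE as MET, accepts both DA/DT
  and legacy A/T nucleotide names plus star-prime/O1P/C5M atom dialects,
  and retains insertion-coded residues under composite numbering.
  All positions are 1-based along strand A, 5'→3'.

## What the synthetic fixtures emulate — and what they do not

`build_bdna()` produces an idealized antiparallel B-form duplex: full
heavy-atom nucleotides, planar bases, uniform rise (3.38 Å) and twist
(36°), Watson–Crick pivot separation 2.9 Å, no propeller, roll or
sugar-pucker variation, and a schematic (bonded-geometry, non-crystallographic)
backbone. `add_probe_protein()` places single amino-acid residues at exact
distances from chosen pairs, which gives training sets with *known*
atom-pair distance distributions and complexes with *known* contact maps.

This supports every structural claim the tests make: parser and duplex
ground truth, exact mutation geometry, oracle equality of energies, and
recovery of a planted specificity signal end-to-end. It deliberately does
**not** establish accuracy on real crystal structures: real base pairs are
non-planar and sequence-dependently distorted, real proteins present
folded interfaces rather than isolated probe residues, and a potential
trained on a handful of synthetic fixtures has none of the statistical
depth of one trained on a curated database of complexes. Passing tests
demonstrate correctness of the machinery, not biological calibration.

The planted-signal study used throughout (`make_planted_site_fixture()`)
trains on 20 small complexes in which arginine is observed 3.2 Å from
guanine pairs but only 7.5 Å from other bases, with serine at a neutral
4.2 Å from every base type; the test complex carries one close arginine at
a G position and neutral serines at three flanking positions. The test
then asks that the fitted PFM concentrate more than half its column mass
on G at the arginine-contacted position. Problem sizes throughout the test
suite and the acceptance script (6–8 bp duplexes, 2–4 mutable positions,
10–20 training complexes, 500–10 000 random negatives) were chosen so the
full suite exercises every code path at desk scale while each quantity
remains statistically unambiguous.

## Known limitations

* No backbone relaxation, sugar-pucker adjustment or minimization; mutant
  RMSDs reported here are lower bounds on true conformational change.
* The exact bin scheme and reference-state constant of the potential, and
  the constant of the Psi form, are conventions; results that depend only
  on ranking are invariant to them, absolute values are not.
* mmCIF input, RNA duplexes, protonation, and crystallographic symmetry
  expansion are out of scope; single-model PDB files are expected.
* The flexibility criterion keys off the single best mutant, so one
  outlier mutant can widen the selection; with idealized fixtures this is
  deterministic and visible in the reported threshold.
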