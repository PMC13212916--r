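---
title: "Methods: pucker-dependent rotamer libraries and nucleotide repacking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pucker-dependent rotamer libraries and nucleotide repacking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpack)
```

## Conformational coordinates

A standard nucleotide's conformation, on a fixed backbone, is captured
by two torsional coordinates.  The furanose pucker is summarized by the
pseudorotation phase $P$ and amplitude $\tau_M$, obtained from the five
endocyclic torsions $\nu_0,\dots,\nu_4$ (quadruples in the standard
furanose convention, e.g. $\nu_2$: C1$'$–C2$'$–C3$'$–C4$'$) through the
Altona–Sundaralingam inversion

$$\tan P = \frac{(\nu_4+\nu_1)-(\nu_3+\nu_0)}{2\,\nu_2(\sin 36^\circ +
\sin 72^\circ)},$$

with $180^\circ$ added when $\nu_2 < 0$; this branch rule separates
mirrored twist conformations and extends $P$ over the full circle.  The
implementation realizes both branches in one step through
`atan2(numerator, denominator)`, which also resolves the $\nu_2 = 0$
boundary by the sign of the numerator; an all-zero (planar) torsion set
is an explicit error, as a planar ring has no phase.  The amplitude is
$\tau_M = \nu_2 / \cos P$ away from the degenerate phases; within
$|\cos P| \le 0.1$ (near $P = 90^\circ/270^\circ$) a least-squares fit
of the amplitude over all five torsions against the cosine model
$\nu_j = \tau_M \cos(P + 144^\circ (j-2))$ is used instead, which is
numerically stable where the direct quotient is not.

The base orientation is the glycosidic torsion $\chi$
(O4$'$–C1$'$–N9–C4 for purines, O4$'$–C1$'$–N1–C2 for pyrimidines).
Internally all dihedrals live in $(-180^\circ, 180^\circ]$ under the
right-hand convention; $P$ and $\chi$ are reported in $[0^\circ,
360^\circ)$, the domain on which the mixture models operate.

Sugars are classed 2$'$-endo-like when $80^\circ \le P < 260^\circ$ and
3$'$-endo-like otherwise.  The published class intervals are open at
both ends, leaving the two boundary points unassigned; we close the
2$'$-endo interval on the left ($P = 80^\circ \to$ ENDO2, $P =
260^\circ \to$ ENDO3) so that classification is total — an arbitrary
but documented and testable choice.

Residues with non-standard names are skipped with a warning rather than
coerced; on file input, alternate conformers are reduced to the
highest-occupancy altloc (ties broken by label), with a warning.

## Library derivation

$\chi$ samples are grouped by nucleoside and (for the pucker-dependent
flavor) pucker class, and each group is fitted with univariate Gaussian
mixtures by expectation–maximization.  Numerical choices:

* **Initialization and restarts.** Five k-means++-style seeded
  restarts per component count, best log-likelihood kept.  The EM
  tolerance is $10^{-4}$ on the per-observation log-likelihood gain;
  component standard deviations are floored at $10^{-3}$ degrees to
  avoid singular components.
* **Domain.** The $[0^\circ, 360^\circ)$ range is treated as linear.
  $\chi$ distributions have no mass near the $0/360$ boundary, so no
  circular statistics are required; this assumption is asserted by the
  generators used in testing and should be checked for unusual input
  data.
* **Model selection.** Component counts $k = 1..20$ are scanned and
  the first local minimum of $\mathrm{BIC} = -2\ln L + k\ln N$ is
  selected ($\mathrm{BIC}_k < \mathrm{BIC}_{k-1}$ and
  $\le \mathrm{BIC}_{k+1}$); scanning stops once that minimum is
  confirmed, and a monotone-decreasing curve selects $k_{\max}$ with a
  warning.  The free-parameter count is $k = 3c - 1$ ($c$ means, $c$
  variances, $c-1$ free weights).
* **Curation.** A selected model containing two neighbouring means
  (adjacent after sorting; the domain is non-circular) separated by
  less than $10^\circ$ is rejected, and the next-smaller component
  count whose model passes is used — a deterministic automation of a
  curation step that is otherwise manual.  Components with weight
  below 1% or standard deviation above $50^\circ$ are removed and the
  remaining weights renormalized exactly; log-likelihood and BIC are
  then recomputed from the stored samples so the BIC identity always
  holds.  Final means are rounded to integer degrees; probabilities
  are not re-fit after rounding, which perturbs them by far less than
  their sampling uncertainty.

The basic (pucker-independent) flavor fits one Gaussian per
user-specified $\chi$ window by in-window moments, with probabilities
equal to each window's share of the total fitted mass.  The peak
windows are configuration, not constants: the appropriate windows
depend on the data set.

`example_library()` provides a small synthetic reference library with
modes in the +sc (~65°), −ap (~200°) and −ac (~250°) regions.  It is a
generator for round-trip tests and demonstrations, not a statistical
survey of experimental structures.

## Nucleotide building

At each position the residue is reduced to its main-chain atoms (P,
OP1, OP2, O5$'$, C5$'$, C4$'$, C3$'$, O3$'$).  Idealized sugar
templates are then superposed onto C3$'$/C4$'$/C5$'$ by least squares
(proper rotations only): three conformers at canonical $P = 0, 18,
36^\circ$ for 3$'$-endo-like positions and four at $P = 180, 162, 144,
126^\circ$ for the broader 2$'$-endo-like class.  The canonical phases
follow the $18^\circ$-spaced pseudorotation wheel; template amplitudes
default to the observed distribution maxima, $37^\circ$ for
deoxyribose and $40^\circ$ for ribose.  Templates are generated once
per session by the fixture generator (cosine-model torsions closed by
least squares under ideal bond lengths and angles) and cached.

Bases are idealized planar nucleobases (force-field-optimized
heavy-atom geometry projected onto the base plane) bonded at C1$'$ with
a 1.48 Å glycosidic bond; the attachment solves the in-plane rotation
so the measured $\chi$ matches the request to $10^{-2}$ degrees.
Candidates are expanded by $\delta\chi$ increments (default $-7, 0,
+7^\circ$; base atoms rotate about the glycosidic axis, the sugar is
untouched), by alternative H placements (default 1; `h_placements = 3`
samples the staggered ribose 2$'$-OH rotamers), and finally by backrub
rotations (default $-7, 0, +7^\circ$) about the C3$'$–C4$'$ axis, or
about P(i)–P(i+1) when the following phosphate is available — in that
case every atom except the two axis phosphorus atoms rotates.  $\chi$
expansion precedes backrub, matching the build order of the procedure;
backrub is the only step allowed to move main-chain atoms.  The
candidate count at a position is exactly
$\sum_{\text{nucleosides}} n_\text{rot} \times n_\text{sugar} \times
n_H \times |\delta\chi| \times |\text{backrub}|$.

Superposition onto the three anchor atoms only (not O3$'$) follows the
procedure as written; re-anchoring on O3$'$ as well was considered and
rejected because it over-constrains the template against backbones
whose O3$'$ deviates from ideal geometry.

## Energy model and search

The published method does not disclose its energy function, so the
scoring here is a package design choice, isolated behind
`energy_model()` so alternatives can be plugged in:

* capped 6–12 Lennard-Jones on per-element radii (C 1.70, N 1.55,
  O 1.52, P 1.80 Å; well depth 0.1 kcal/mol; per-pair cap 10 kcal/mol;
  8 Å cutoff).  The O3$'$(i)–P(i+1) bonded pair across residue
  boundaries is excluded from the clash term;
* a geometric hydrogen bond: donor–acceptor distance 2.6–3.4 Å with
  the partner inside the donor's and acceptor's interaction cones
  ($40^\circ$ about the outward bisector for ring atoms, $85^\circ$
  for terminal amines/carbonyls whose protons and lone pairs fan out
  to about $60^\circ$), worth $-1.5$ kcal/mol;
* a mismatch penalty of $+1.5$ kcal/mol for frontal donor–donor or
  acceptor–acceptor apposition of nucleobase atoms at H-bond distance.
  This term is what distinguishes a Watson–Crick partner from a
  wobble-like mismatch on a rigid frame, where distances alone cannot;
* a rotamer prior $-0.5 \ln p$ from the library probability.

Energies are strictly pairwise-decomposable (candidate self energies
against the fixed environment plus symmetric pair tables), so the GMEC
is found by iterated Goldstein singles dead-end elimination — provably
sound, never removing a candidate of a true optimum — followed by
exhaustive enumeration when the residual space has at most $10^6$
combinations (which guarantees the exact optimum on test-scale
problems) and Monte-Carlo/simulated annealing otherwise (Metropolis
single-position moves, geometric cooling from $T = 10$ to $0.05$ over
4000 steps, three restarts, best-seen assignment returned;
deterministic under a fixed seed).  Energy ties resolve to the lowest
(position, candidate) index pair, so outputs are reproducible.

## Evaluation metrics

* **Pooled side-chain RMSD**: one RMSD over all included atoms of all
  compared residues, with the main-chain atoms excluded (P, OP1, OP2,
  O5$'$, C5$'$, C4$'$, C3$'$, O3$'$ for nucleotides; N, CA, C, O, CB
  for amino acids) and no superposition — both structures share the
  rigid backbone frame.  Pooling weights every atom equally;
  per-residue-averaged RMSDs would be systematically smaller on
  heterogeneous errors and are not reported.  Identity-redesigned
  residues have no comparable atom set and are excluded and counted
  separately; their $\Delta\chi$ is likewise undefined and excluded
  from recovery statistics.
* **Recovery rate**: the percentage of positions with absolute
  circular $\Delta\chi$ strictly below $15^\circ$; $15.0^\circ$
  exactly is not a match.  The same circular-difference primitive
  backs the mean $\Delta\chi$.
* **INF**: $\sqrt{\mathrm{PPV}\times\mathrm{STY}}$ over base-pair and
  base-stack edges.  Edge detection is a geometric re-implementation
  (pair: $\ge 2$ donor–acceptor contacts within 3.4 Å, roughly
  in-plane, planes within $30^\circ$; stack: ring-centroid distance
  $< 4.5$ Å, planes within $30^\circ$, in-plane centroid offset
  $< 2.5$ Å), not a call to an external assessment toolkit, so
  absolute INF values may differ slightly from toolkit-derived ones;
  the thresholds are configurable.
* **lDDT** with the published standard parameters (inclusion radius
  15 Å; thresholds 0.5/1/2/4 Å), per residue and averaged.
* **F_nat** with a 5 Å heavy-atom contact cutoff (the common docking
  convention), over protein-residue/nucleotide pairs.

## Synthetic fixtures

The fixture generator produces furanose rings at any $(P, \tau_M)$
(ring closure by least squares under ideal bond lengths/angles;
achieved phase within $2^\circ$ of request), complete idealized
nucleotides, χ populations drawn from a library group, and toy
duplexes: B form with rise 3.38 Å, twist $36^\circ$, 2$'$-endo sugars
($P = 162^\circ$, $\tau_M = 37^\circ$) and $\chi = 250^\circ$ (−ac);
A form with rise 2.81 Å, twist $32.7^\circ$, 3$'$-endo sugars
($P = 18^\circ$, $\tau_M = 40^\circ$) and $\chi = 200^\circ$ (−ap).
Watson–Crick pair poses are solved at run time by in-plane least
squares on the canonical donor–acceptor distances (2.9 Å), the
C1$'$–C1$'$ distance (10.5 Å) and the donor H directions; base atoms
are coplanar, so each nucleotide's superposition onto its pair pose is
disambiguated by an out-of-plane pseudo-point whose sign is chosen so
the 5$'$-phosphate stub points 5$'$-ward — this is what makes the two
strands antiparallel.

What the fixtures do *not* emulate: crystallographic disorder and
experimental noise; sequence-dependent helical parameter variation,
propeller twist and groove asymmetry; backbone continuity (each
residue carries its own idealized 5$'$-phosphate stub, so consecutive
residues are connected only approximately); solvent and ions.  The
A-form generator in particular is a classification and pair-detection
fixture: its inter-strand backbone ribbons approach each other more
closely than in fiber-diffraction geometry, so packing-energy
benchmarks use the B-form duplex.  Consequently, passing tests
demonstrate internal consistency of the method and exact behaviour of
its algorithms on idealized geometry — not accuracy on experimental
structures, which depends additionally on the realism of the energy
function.

## Problem sizes used by the test suite

The suite exercises library recovery on 16 groups × 5,000 χ samples,
GMEC optimality on 50 random instances of 4 positions × ≤5 candidates
against brute-force enumeration, and full redesign of one strand of a
10-bp B-form duplex (4 identities × 2–3 rotamers × 4 sugar conformers
per position).  These sizes keep the whole suite near a minute while
leaving every code path, including the annealing fallback, covered.

## Known limitations

* The energy function is a plausible, deliberately simple surrogate;
  absolute energies are meaningless and only rankings on idealized
  geometry are validated.
* Mixture fitting assumes no density at the $0^\circ/360^\circ$
  boundary; libraries for syn-dominated unusual systems would need a
  circular treatment.
* Modified nucleotides are skipped, not modelled; protein side chains
  are fixed context, never rebuilt.
* Crystallographic symmetry expansion is not performed during sphere
  extraction; inputs are assumed pre-expanded.
* Sphere extraction keeps whole residues rather than clipping at the
  atom level, so every retained nucleotide has computable descriptors;
  files produced by atom-level clipping tools will differ at the
  sphere boundary.
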