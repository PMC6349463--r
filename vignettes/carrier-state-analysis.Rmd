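---
title: "Dissecting alternating access in mitochondrial carriers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting alternating access in mitochondrial carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carriergate)
```

# The structural model

Mitochondrial carriers are built from three homologous ~100-residue domains
arranged with approximate three-fold symmetry about an axis normal to the
membrane. Each domain contributes an odd-numbered transmembrane helix, a
short matrix helix, and an even-numbered transmembrane helix. Two charged
networks seal the translocation pathway in turn: a matrix network assembled
from the Px[DE]xx[KR] signature motifs of the odd helices, and a cytoplasmic
network from the [YF][DE]xx[KR] motifs of the even helices, reinforced by
tyrosine (or arginine) braces one helical turn away and by a hydrophobic
plug beneath them.

The package treats the transition between the cytoplasmic-open (c) and
matrix-open (m) states as rigid-body motions of six structural elements.
Each domain splits at its *contact point* — the substrate-binding residue at
the kink pivot of the even helix — into:

* a **core element**: everything from the domain start up to the residue
  before the contact point (odd helix, matrix helix, linker, N-terminal part
  of the even helix);
* a **gate element**: the even helix from the contact point (inclusive) to
  the domain end.

The pivot residue is assigned to the gate element because it moves with the
kink. `derive_elements()` enforces that the two elements partition the
domain exactly; a contact point at a domain boundary is rejected because it
would leave an empty element. Between the c- and m-states the core elements
undergo a rocking rotation of roughly 15° and the gate elements rotate
toward or away from the pseudo-C3 axis with the contact points acting as a
fulcrum.

A `CarrierTopology` pins all of this to author residue numbering. The
shipped `ttaac_topology()` uses domains 13–107, 116–211 and 220–306 with
contact points 88, 192 and 287, and carries the binding-site, network,
brace, plug and ceiling residue sets. The transmembrane helix spans
(H1 16–45, H2 74–107, H3 116–145, H4 177–211, H5 220–250, H6 273–306, plus
the matrix helices) are *annotations*, chosen from the helical regions of
the deposited model; the package deliberately does not assign secondary
structure algorithmically, so that every result is reproducible from the
configuration alone. The signature prolines (35, 140, 240) are derived from
the Px[DE]xx[KR] motif anchored on the matrix-network positions. For a
homolog, `map_topology()` transfers the annotation through a
sequence-alignment correspondence rather than shipping a second hand-made
table.

# Superposition and correspondence

`kabsch()` computes the least-squares rigid superposition from the SVD of
the covariance of the centered point sets, with the reflection branch
corrected so the result is always a proper rotation. The test suite checks
it against a brute-force rotation-grid search on small instances.

`iterative_superpose()` emulates the cycle-and-reject behaviour of
interactive alignment tools with pinned parameters: per-residue rejection on
backbone atoms (N, CA, C, O), rejection threshold 2.0 × the current RMSD,
at most 5 cycles, and a hard floor of 50% of the input atoms. These values
are conventional rather than canonical — different tools reject slightly
differently, and element RMSDs on real structures can shift by a few tenths
of an Ångström depending on the rule — which is why they are explicit
arguments rather than constants.

Residue correspondence between homologs is sequence-based only:
`align_sequences()` performs global Needleman–Wunsch alignment with
BLOSUM62, gap opening 10 and gap extension 0.5. The scoring is pinned for
reproducibility; percent identity uses the number of alignment columns
excluding terminal gaps as its denominator, which is stated here because
identity figures are notoriously denominator-dependent. Structure-based
alignment is out of scope by design: the analysis needs a residue-number
mapping that is independent of the conformational change being measured.

# Helix axes and kink angles

`fit_axis()` uses the bisector construction: for interior Cα *i* the vector
(p[i−1] − p[i]) + (p[i+1] − p[i]) points from the helix toward its axis, and
cross products of bisector pairs lie along the axis — exactly so for ideal
helical geometry, independent of segment length. This matters because the
default kink flank is 7 residues (about two turns): a plain principal
component of 7 raw Cα positions is biased by several degrees by the helical
wobble, and windowed averaging cancels the wobble only for full turns. The
bisector axis recovers generator-planted kinks of 10–90° exactly at zero
noise; with coordinate noise of a few tenths of an Ångström the short flanks
make single measurements noisy (degrees, not tenths), so kink angles from
noisy models should be averaged or taken with wide error bars.

`kink_angle()` fits independent axes to the `flank` residues on either side
of the break residue (the break residue itself belongs to neither fit) and
reports the angle between the two N→C directions: 0° means straight, and
the angle grows as the helix bends. The printed kink angles of the
inhibited carrier states are interpreted under this convention; if a
deposited structure were to yield angles systematically near 180° minus the
expected value, the complementary convention should be evaluated and the
discrepancy reported rather than silently switched — the convention is an
argument of the interpretation, not of the code.

# Interaction networks

`find_polar_contacts()` is deliberately minimal: a salt bridge is a
side-chain nitrogen of K/R/H within 4.0 Å of a side-chain carboxylate
oxygen of D/E; a brace hydrogen bond is a hydroxyl/amide side-chain atom
(Y-OH, S-OG, T-OG1, N/Q amide) within 3.6 Å of a charged O/N. There is no
hydrogen placement and no angular criterion, because the analysis operates
at crystal-structure resolutions where donor hydrogens are unobserved.
Histidine is counted as a positively charged donor (an inclusive default
that does not affect the carrier networks, which contain no histidine).
"Weak" interactions are not a separate class: a pair either passes the
cutoff or it does not, and the distance is reported so weakness is
inspectable. Each residue pair is reported once, at its minimum-distance
atom pair, with salt bridges taking precedence. Network membership
(matrix/cytoplasmic/other) is decided by the topology's residue sets, and
`compare_states()` reduces two states to formed/broken/retained contact
sets keyed by residue pair.

# Building the uninhibited state models

Both inhibited crystal structures are distorted by their inhibitors, so the
package builds uninhibited models before measuring inter-state motions.

**Symmetrized m-state.** `symmetrize()` iterates: estimate the pseudo-C3
axis; rotate each domain's symmetry-triplet Cα set into a common sector
(0/−120/−240°); average the three copies into a template; rigid-fit each
whole domain back onto the template rotated into its own sector; repeat
until no atom moves more than `tol` (0.01 Å default, 50 iterations
maximum). Domains move strictly as rigid bodies — intra-domain geometry is
preserved to machine precision — which is the large-weight limit of a
restrained-optimization protocol; the conventional restraint weight of 2 is
recorded in `symmetrize_params()` as documentation but does not enter the
computation. Two numerical choices make the procedure robust to the very
asymmetry it must remove:

* *leave-one-domain-out axis estimation*: a domain displaced as a rigid
  body corrupts the two inter-domain transforms that involve it but leaves
  the third exact, so each of the three pairwise transforms proposes an
  axis and the proposal whose two source domains agree best after sector
  mapping wins;
* *consensus template weighting*: the sector-mapped domain copies are
  averaged with iteratively reweighted weights (1/(msd + 0.04 Å²), five
  rounds), so an outlier domain does not drag the template toward itself.

With these, a planted single-domain displacement of 3–25° is removed to
well under 0.5 Å Cα RMSD at zero noise, the procedure is idempotent, and on
an already-symmetric structure it is the identity. The final model is
re-anchored on domain 2 — in the inhibited m-state the least-displaced
domain — so the output frame is comparable with the input; the choice of
anchor affects only the global frame, never the internal geometry.
`repeat_correspondence()` provides the symmetry triples by aligning domain
1 to domain 2 and domain 2 to domain 3 and keeping positions placed by both
alignments, refusing to proceed with fewer than 50 triples.

**Hybrid c-state.** `build_uninhibited_c()` superposes each of the six
elements of the m-state structure independently onto the corresponding
residues of a c-state template (backbone least squares). Iterative outlier
rejection is enabled only for the elements known to be distorted by
inhibitor binding in the template — core element 2 and the H2 gate — and
plain least squares is used elsewhere, mirroring the distinction between
elements that superpose well and those that need rejection. Linker residues
between elements are bridged by per-atom linear blending between the two
flanking element placements, weighted by residue number. No template-based
loop rebuilding and no energy minimization are performed: the models exist
to carry geometry metrics (angles, distances, accessibility), not
stereochemistry, and blended linkers are flagged by their clash scores
rather than hidden by minimization.

# Morphing and the occluded state

`interpolate_states()` morphs element-wise: for each element the A→B rigid
transform is fitted, its rotation is interpolated at constant angular
velocity about the fixed rotation axis through the element centroid, the
centroid translation is linear, and any residual non-rigid difference is
blended in linearly so that the first and last frames reproduce the inputs
bit-for-bit. The construction is symmetric — morphing B→A gives the same
frames in reverse order — and the midpoint of a 30° element rotation is
exactly 15°. Linker atoms interpolate linearly. A whole-molecule morph is
deliberately not offered: interpolating a single global transform opens
clefts in the lipid-facing surface and never produces an occluded
intermediate, which is the observation that motivates the element-wise
treatment.

`gate_metrics()` operationalizes alternating access as a grid flood fill:
cells within (vdW radius + probe radius) of an atom are blocked (fixed
radii C 1.7, N 1.55, O 1.52, S 1.8 Å; probe 1.4 Å; grid 1.0 Å with a 6 Å
margin), the free cells are flooded separately from the two faces of the
box along the membrane normal, and a side is *accessible* when its flood
reaches a free cell within 4.0 Å of a binding-site atom. The flood is
confined to a cylinder of radius 10 Å about the pseudo-C3 axis: the
membrane forbids lateral solvent passage around an isolated protein, and
without this bound the two face floods would trivially merge in bulk
solvent and every state would read open from both sides. The cylinder
radius must exceed the cavity mouth (~7–8 Å here) and stay below the
protein's lateral radius; 10 Å satisfies both for the carrier fold and for
the synthetic fixtures, and the accessibility booleans are checked to be
stable under grid halving. A state is *occluded* exactly when neither side
is accessible. `gate_thickness` is this package's operationalization of the
closed span: the axial extent of the widest contiguous slab (within 8 Å of
the axis, inside the model's axial extent) containing no solvent-connected
free cell. Because the measurement protocol behind published "~15 Å gate"
figures is not standardized, this quantity should be read as a 10–20 Å
band, not an exact target.

# What the synthetic generator does and does not emulate

`make_pseudo_c3_bundle()` builds idealized α-helices (rise 1.5 Å/residue,
twist 100°/residue, Cα radius 2.3 Å, backbone N/CA/C/O placed on a
cylindrical template) at 0/120/240° about z, with even helices antiparallel,
a numbering gap standing in for loops, pseudo side-chain atoms for planted
charged pairs (K-NZ/D-OD1 or Y-OH/D-OD1 placed at exact distances), and a
CB atom on each contact-point residue displaced toward the axis so the
binding site lines a central cavity. Defaults — six helices of 30 residues
at bundle radius 8 Å — give a carrier-sized bundle (~60 Å tall, cavity
radius ~5 Å). Rigid perturbations and Gaussian coordinate noise are planted
with recorded ground truth, and identical spec + seed is bit-reproducible.

The generator emulates exactly what the pipeline measures: helical
geometry, pseudo-symmetry, element rigidity, charged-group distances,
cavity accessibility. It does **not** emulate side-chain rotamers, loops
with atoms, lipids, crystallographic noise structure (which is neither
isotropic nor independent), or sequence divergence between domains beyond
planted point differences. Passing the recovery suite therefore
demonstrates the correctness of the geometric machinery — that planted
parameters are recovered at their stated tolerances — not that real
crystal-structure measurements will reach the same precision; on real
structures the dominant uncertainties are the element boundary choices and
the outlier-rejection rule, not the algebra.

# Problem sizes and numerical conventions

The test and acceptance runs use bundles of 6 × 30 residues (~730 atoms),
accessibility cages of ~420 pseudo-atoms, grids of 1.0 and 0.5 Å spacing,
20-replicate noise sweeps at σ = 0.3 Å, and 3–11-frame morphs; the full
suite completes in well under a minute on one CPU, and the same code scales
directly to carrier-sized inputs. Degenerate inputs are rejected loudly:
fewer than 3 superposition points, collinear geometry, axes from fewer than
4 Cα, kinks too close to a span end, contact points on domain boundaries,
inter-domain rotations under 30° (no C3 axis), and empty atom selections
(unless explicitly allowed). Rotation angles use the trace convention
(acos((tr R − 1)/2) ∈ [0°, 180°]); near 0° the axis is reported as (0,0,1)
by convention and near 180° it is recovered from R + I. Residue ranges are
author-numbered and inclusive on both ends throughout.

# Known limitations

* Accessibility is a geometric channel test, not an electrostatic or
  energetic one; it cannot distinguish a narrow hydrated channel from a
  functionally closed one at the probe resolution.
* Distance-only hydrogen-bond criteria over-count at the margins; the
  distances are reported precisely so borderline contacts can be audited.
* Kink angles from 7-residue flanks are exact on ideal geometry but
  noise-sensitive on real coordinates.
* The symmetrized m-state and hybrid c-state models have unphysical
  linkers (blended, not rebuilt) and inherit the side chains of their
  source structure; clash counts quantify, but do not repair, this.
* Sequence-based correspondence will misalign if the homologs diverge
  enough that the global alignment breaks; the 50-triple floor and the
  per-element minimum of 3 matched residues are guardrails, not proofs.
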