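---
title: "Switching energy landscapes for SMC-kleisin DNA translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching energy landscapes for SMC-kleisin DNA translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

SMC-kleisin complexes are ring-shaped ATPase motors built from two ~50 nm
coiled-coil arms that dimerize at a hinge, two ATPase head domains at the arm
bottoms, and a largely disordered kleisin subunit whose N- and C-terminal
domains bridge the two heads and close the ring. The nucleotide state of the
heads selects one of three architectures: the apo rod (heads together through
the apo interface, arms juxtaposed; here called *disengaged*), the ATP-bound
open ring (heads rearranged into a different dimer interface, arms apart;
*engaged*), and the ADP-bound state with dissociated heads (*vshape*).

`smcgo` represents this machine as a structure-based (Go-type) bead model.
Each nucleotide state is an energy landscape funneled toward its reference
structure; the ATP cycle is modeled as instantaneous switches between these
landscapes in the order disengaged, engaged, vshape, disengaged
(a "vertical excitation" between surfaces -- the model therefore says nothing
about transition rates or barriers, only about the relaxation dynamics that
follows each chemical event). What is switched:

* the **native-contact groups** that are active -- the apo head-head
  interface, the engaged head-head interface (strengthened twofold, which is
  what accelerates the rearrangement), the hinge dimer interface, the
  kleisin-terminus attachments, and the inter-arm "zipper" contacts that act
  only in the final disengaged segment of a translocation cycle;
* the **hydrogen-bond term** between head-top donor beads and DNA phosphates
  (engaged state only; the dissociated V-shape heads offer no composite
  binding surface);
* the **flexible hinge-arm junction**, whose angle terms are softened 20-fold
  in the engaged and V-shape states so the ring can open.

DNA is a three-site-per-nucleotide duplex (base, sugar, phosphate beads on an
ideal B-form helix, 5'-terminal phosphates omitted). Protein and DNA interact
only through excluded volume, Debye-Huckel electrostatics with the dual
phosphate-charge convention (-0.6 e for DNA-DNA pairs, standing in for
counter-ion condensation; -1.0 e for protein-DNA pairs), and the directional
hydrogen-bond term. No base pairing, stacking, or sequence-dependent
mechanics: duplex integrity is maintained by an elastic network (see below),
and the mechanism under study is architectural rather than sequence-specific.

## The synthetic complex

`build_toy_complex()` replaces the homology model that a structure-derived
study would start from. Its architecture keeps what the mechanism needs and
discards everything else:

* **Arms** are straight bead chains (3.8 A spacing, harmonic bonds and
  angles; bending persistence length ~400 A, rod-like at the sizes used).
* **Heads** are compact lattice blocks (7.5 A spacing, large excluded-volume
  radius). The top face is basic: the central row are arginine hydrogen-bond
  donors, the flanks and outer face charge-only lysines (the side patch that
  guides DNA around the rim). Each head hangs from its arm through a short
  joint whose bonds, angles and dihedrals are rigid; the single soft degree
  of freedom is the spin of the head block about the vertical axis through
  its neck bead -- and an 85-degree spin about exactly that axis *is* the
  engaged-state rearrangement, so switching the interface contacts drives
  the rearrangement without fighting any bonded term.
* **The hinge** is two bonded half-clusters held together by dimer contacts.
  Cross-subunit junction angles pin both arm directions to the dimerized
  hinge; they belong to the flexible-junction set, which is what lets the
  engaged/V-shape states open while head and hinge interactions alone
  maintain the apo rod.
* **The kleisin** is the asymmetry carrier: a structured NTD bound along the
  front face of one arm ("blue"), a structured CTD bound under the front of
  the other head ("red"), and a disordered 63-residue linker (bonds only --
  an IDR carries no angle terms) whose 5-lysine DNA-binding patch sits at
  the position corresponding to the patch of the natural sequence
  (fraction ~0.75 along the linker). The reference linker path is drawn on
  the front (+y) side; `insert_linker()` splices GGGGS repeats on both sides
  of the patch. Linkers elongated far beyond the wild type are drawn as a
  compact alternating-side coil instead of one giant front lobe, which is
  both the more realistic coil proxy and removes a one-sided initialization
  bias from path-distribution statistics.

All bonded rest values are computed from the disengaged reference, following
the source convention that arms and hinge keep their apo reference in every
state; the engaged reference differs in the head placement (whose interface
contacts take engaged rest values) and the drawn arm arcs of the O-shape,
which are for visualization and Q-score reference only. Engaged-interface
contact pairs that are *compressed* in the apo pose are dropped: under
instantaneous landscape switching such a pair would start deep inside the
12-10 repulsive core and eject beads; this filter is the numerical price of
vertical excitation in a coarse toy geometry.

## Numerical choices

* Units: Angstrom, kcal/mol, intrinsic time tau = sqrt(amu A^2 / kcal/mol).
  kBT(300 K) = 0.5962 kcal/mol. The step size is 0.2 in this unit; a step is
  of order a picosecond of effective time, a mapping used for reporting only.
* Integrator: BAOAB Langevin splitting with exact Ornstein-Uhlenbeck noise,
  a counter-seeded xoshiro generator (independent streams per segment and
  replica, so branched continuations are reproducible), bead mass 50 amu and
  friction 0.02/tau by default. The masses and friction are free parameters
  of the coarse model (the source engine's defaults are not printed); the
  strongly underdamped choice keeps every stiff bonded mode far below the
  stability limit at dt = 0.2 and maximizes conformational exploration per
  step, which matters because the desk-scale schedules compress the
  production segments a thousandfold. Equilibrium averages are independent
  of both parameters. A per-bead displacement limiter (1 A per half step,
  about fifty standard deviations above thermal speeds) is a numerical
  safeguard that never engages in healthy dynamics.
* Electrostatics: Debye-Huckel with eps_r = 78, truncated and shifted. The
  function default cutoff is 50 A; production configurations use a cutoff
  scaled to the screening length (15 A at 300 mM, 20 A for protein-only
  ensembles at 150 mM; the discarded tail is a few percent of an already
  screened interaction).
* Excluded volume: purely repulsive (sigma_ij/r)^12, shifted to zero at
  2 sigma_ij; per-bead sigma (chains 4 A, hinge and head beads 8 A).
* The hydrogen-bond term is -eps G(r) G(theta) G(phi) with eps = 4.0 kBT,
  each factor a Gaussian inside a hard filter window that reaches exactly
  zero at three widths, so forces act only at short range and specific
  orientation. The angular factor acts on cos(theta) (width matched to a
  theta-Gaussian at the peak), which keeps forces finite at collinear
  geometries; the dihedral factor is disabled by default in the toy model
  (sigma_phi = Inf) and available for parameter sets derived from atomistic
  geometry histograms via `derive_cg_params()`/`as_hbond_model()`. In the
  toy the donor orientation reference is the lattice bead below each donor,
  making the bond top-face selective (theta0 = 135 degrees).
* DNA: the duplex is held by an elastic network (pairs within 8 A and at
  most 2 bp apart, k = 2 kcal/mol/A^2). The measured tangent-correlation
  persistence length is roughly 150-250 A -- deliberately softer than real
  B-DNA, so that the bending energy of a desk-scale captured loop (radius
  ~30 A at the miniature ring size) is comparable to that of a full-scale
  ~200-bp loop in the reference architecture. Near-diagonal duplex pairs
  (up to 4 bp apart) are excluded from the nonbonded terms, which the
  elastic network already governs.

## Analysis conventions

Protein-DNA contacts use a 10 A cutoff with strict inequality, grouped into
kleisin, heads, the three arm thirds (equal-count partitions: hinge side,
middle, head side), and hinge. The captured-loop size is the absolute
difference between the average base positions contacting the kleisin and the
coiled-coil arms over the final fifth of the engaged segment (the window
scales with the schedule). The step size is the signed difference of the
kleisin-contact means between the final and initial disengaged segments.
A run is classified *translocation* when the loop survives the V-shape
segment and the kleisin mean jumps by more than max(25 bp, three within-
segment standard deviations); *slippage* when kleisin contact is continuous
but the loop is lost; *arm_trap* when DNA-arm(mid) contacts persist at the
end without a jump; *no_capture* when no loop formed; otherwise
*incomplete*. Q-scores count native contacts formed at r < 1.2 r0. Ring
threading is decided by the parity of signed crossings of the per-bp DNA
centerline through a fan triangulation of the closed ring polygon (kleisin
ring: NTD-linker-CTD closed through the two head necks; SMC ring: arms,
hinge, necks). The patch side distribution aligns each frame's head dimer
onto the engaged reference by least-squares superposition and takes the sign
of the patch centroid's y coordinate; the front (+y) side is defined by the
kleisin attachment.

## Desk-scale studies and what they do (and do not) show

The `*_study()` drivers fix the desk-scale conditions used by the tests and
the acceptance script: a 20-bead-arm complex (76 A arms -- about 15% of the
full architecture) and, for the translocation campaign, 250 bp of DNA
threaded through the kleisin ring at 300 mM salt with every ATP-cycle
segment scaled to 5e4 steps.

What the desk-scale runs reproduce robustly:

* stability of the apo rod (head-interface Q-score stays above 0.8 over
  1e6 steps) and the switching response (the apo interface melts and the
  engaged interface forms within a few thousand steps of the switch);
* the zipping order -- relaxing the V-shape under the final disengaged
  landscape closes the inter-arm zipper from the hinge side before the head
  side in essentially every run, the geometric mechanism behind directional
  pumping;
* DNA capture onto the head tops in the engaged state, driven by the
  hydrogen-bond term plus the basic top surface (electrostatics alone leave
  the DNA on the side faces), with typical bound states of five to fifteen
  bonds.

What they do not reproduce at this scale: complete translocation events.
In the source conditions the capture of a large DNA segment is already the
slowest step (a minority of engaged segments of 5e7 steps succeed); the
desk-scale schedule compresses time a thousandfold, and the compensations
available here (shorter distances, lighter/underdamped beads, softened DNA)
recover only one to two orders of magnitude. In campaign runs the captured
loop rarely grows beyond ~10 bp before the engaged segment ends, so the
kleisin-contact jump that defines a translocation is not observed, and the
step-size statistics remain undefined. The estimators themselves (loop size,
step size, outcome taxonomy, threading parity) are therefore validated
against brute-force oracles on constructed trajectories, where their
arithmetic is exact. The same holds for the kleisin-path side bias: the toy
reproduces the *direction* of the effect (pooled 20-seed ensembles give a
side asymmetry of about 0.70 for the wild type versus about 0.57 with ten
GGGGS repeats per side), but with a head dimer only ~50 A wide the patch can
slip beneath the heads, so the wild-type contrast is much weaker than in the
full-size architecture, where the path is sterically confined to one side.

These are limitations of the miniature study conditions, not of the
machinery: all system sizes, schedules, and replica counts are parameters,
and the full-scale campaign (130-bead arms, 800 bp, 5e7-step segments,
replica trees widening at the V-shape and final disengaged states via
`branch_runs()`) is expressible with the same calls, at cluster cost.

## The atomistic hydrogen-bond pipeline

The coarse-grained hydrogen-bond parameters are designed to be derived from
all-atom simulations of the head-DNA complex: `detect_hbonds()` applies the
Baker-Hubbard criteria (hydrogen-acceptor distance strictly below 2.5 A,
donor-hydrogen-acceptor angle strictly above 120 degrees), and
`bond_fractions()` reports per-residue bond occupancies after an
equilibration cut plus the per-frame total bond count series.
`select_hb_residues()` keeps at most the top fifteen residues with fraction
above 0.05, and `derive_cg_params()` histograms the bond geometry (default
bins 0.1 A and 5 degrees) and takes peak positions, with ties broken toward
the smaller value and near-uniform distributions flagged. The package ships
no atomistic trajectories; the pipeline is validated by planted-truth
recovery (occupancies within binomial error, peaks within one bin width, and
closure: parameters derived from synthetic geometry samples place the
coarse-grained energy minimum at the planted geometry).

## Known limitations

* Toy DNA is softer than B-DNA and carries no sequence dependence, twist,
  or supercoiling; safety-belt anchoring and loop extrusion are out of
  scope, as in the source model.
* Landscape switching is instantaneous and the segment lengths are fixed,
  so state lifetimes and their coupling to DNA motion are inputs, not
  predictions.
* The desk-scale campaign demonstrates the capture machinery and the
  estimator pipeline, not quantitative step-size statistics (see above).
* The head blocks are rigid lattice clusters; intra-head flexibility and
  surface charge heterogeneity beyond the basic patches are not modeled.
* Dihedral terms are smoothly damped as either inner bending angle
  approaches collinearity (a `sin^2/(sin^2 + 0.02)` factor per flank), where
  the torsion is geometrically undefined; forces are the exact gradient of
  the damped energy, so they remain bounded and consistent everywhere.
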