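---
title: "Modelling domain-swapped misfolding of tandem repeat proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling domain-swapped misfolding of tandem repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapfold)
```

## The problem

Proteins built from tandem repeats of a single domain can misfold into
*domain-swapped* states: two native-like folds assembled from exchanged
halves of adjacent repeats.  The misfolded "central domain" formed by the
middle of the sequence is a circular permutant of the native fold — the same
chain, cut at a loop position K and with the original termini joined.
swapfold implements a complete apparatus for studying this process at coarse
grain: structure-based (Gō-type) tandem models whose native wells are
duplicated so that swapped contacts are exactly as favourable as native
ones, Langevin first-passage campaigns that classify final states by
frame-shifted contact coordinates, umbrella sampling with WHAM for
circular-permutant stabilities, a Wako–Saitô–Muñoz–Eaton (WSME) Ising model
with a midpoint strain penalty, an alchemical join-and-cut predictor of
permutant destabilization, and the rank-correlation analysis linking
stability to misfolding propensity.

## The energy model

Each residue is one bead at its C-alpha position (coordinates in nm
throughout; energies kcal/mol; `kB = 0.0019872`).  Native contacts are
C-alpha pairs within 0.8 nm separated by at least three residues, the field's
common cutoff definition for one-bead models.  Relative well depths follow
the dominant rank-one (hydrophobicity) component of the Miyazawa–Jernigan
statistical contact potential, reconstructed from their published
per-residue contact-energy scale and rescaled so the mean well depth is a
configurable energy unit (default 1 kcal/mol per contact).  The bonded and
nonbonded terms are a documented simplified variant of the usual
structure-based force field:

* harmonic bonds at the native distances (k = 500 kcal mol^-1 nm^-2 — soft
  enough that a joined-termini bond strained by a tenth of a nanometre costs
  a few kcal/mol, the physically expected scale of circular-permutant
  strain);
* angle terms harmonic in cos(theta) about the native angle (curvature
  matched to 12 kcal mol^-1 rad^-2; the cosine form has no colinear
  singularity).  Linker beads and any triple spanning the inter-repeat
  junction instead get a soft turn-capable prior (1 kcal mol^-1 rad^-2
  equivalent at 92 degrees): a structureless Gly/Ser linker bends about as
  readily as a native loop, and the hinge between repeats is floppy.  Both
  choices matter for the misfolding competition — a stiff or
  extended-biased junction acts as a large hidden strain penalty on every
  circular-permutant fold;
* a two-term cosine dihedral biased to the native torsions
  (k1 = 0.15, k3 = 0.075 kcal/mol) on quadruples interior to a domain
  repeat.  The local bias is deliberately weak: folding is driven by the
  contact wells, and heavily pre-formed local structure makes domain
  folding a pure local zipper, which unrealistically starves cross-junction
  (misfolded) nuclei;
* a 12-10-6 native well of depth |epsilon| at the native distance.  The
  additional r^-6 term produces a desolvation-style barrier outside the
  contact minimum; without it the one-bead model folds downhill with no
  two-state barrier, and barrier-limited folding is essential both for
  realistic kinetics and for the misfolding competition itself;
* an r^-12 excluded volume (0.4 nm radius, 0.35 nm for Gly/Ser) on all other
  pairs.

Nonbonded terms are truncated and shifted (natives at 3 r0, repulsions at
2.5 sigma), and dynamics use a Verlet neighbour list.  For a tandem dimer
with repeat length L (domain plus linker), every native contact (i, j)
appears four times with identical depth and distance: (i, j), (i+L, j+L) and
the swap copies (i, j+L), (j, i+L).  This duplication is what allows a
native-*like* misfold to complete without any non-native energetics.

## Reaction coordinates and classification

For a cut position K the central-domain ("in") and terminal-domain ("out")
contact sets are obtained from the native set by the step-function frame
shift; the convention here is that the step function is 1 at zero, so
residue K itself belongs to the terminal side and the central domain spans
K+1 ... K+L.  Q_K is the logistic fraction of formed contacts
(beta = 50 nm^-1, lambda = 1.2) over a set.  The usual statement of Q_K
leaves its normalisation ambiguous (N is described as the total number of
native contacts while the sum runs over the central-domain set only);
swapfold normalises by the size of the set actually summed over, keeping every
variant of the coordinate in [0, 1], and exposes "in", "out" and "both"
variants.  A configuration is classified as fold K when both Q_in,K and
Q_out,K reach 0.8 — comfortably above the logistic midpoint and below the
native plateau; ties go to the largest min(Q_in, Q_out).  State bookkeeping
("formed" contacts, the nucleus coordinate ij-bar) uses the sharp criterion
r < lambda r0.

## Sampling

Dynamics are underdamped BAOAB Langevin steps with friction 0.1 ps^-1 and a
10 fs time step, bit-reproducible for a fixed seed (an internal
xoshiro256++ generator).  Umbrella sampling adds 0.5 k (Q - Q0)^2 windows
along Q; windows are seeded from high Q downward so the low-Q windows start
from partially unfolded configurations.  WHAM uses 0.01-wide bins and
iterates to 1e-7 kcal/mol; profiles are reported with their minimum at
zero.  Basin decomposition smooths the profile with a 3-bin running mean,
finds the global minimum and the local minimum with the largest intervening
barrier prominence, then refines all three positions on the raw profile, so
exact constructed profiles are reproduced exactly while noisy WHAM output is
handled robustly.  The folded-state stability is reported as
dG_s = kT ln(Z_fold / Z_unf) — positive when the fold is more stable, the
sign convention used for printed stability tables.

The working temperature for kinetic campaigns follows the standard
prescription of a folding barrier near 2.5 kT, located by bisection on
umbrella/WHAM profiles; the melting temperature (dG_s = 0) is reported
alongside.

## The synthetic test fold

`make_toy_structure()` builds an antiparallel beta-meander on a regular
lattice: strands of equally spaced beads (0.38 nm) at 0.42 nm inter-strand
spacing, loops laid at equal arc length on an outward bulge, and a
controllable N-to-C termini separation achieved by curling the sheet around
an axis — from a flat sheet (maximal separation) to a closed, cyclically
symmetric barrel (minimal separation, with first/last-strand contacts).
Two-strand specs build flat hairpins.  The seed perturbs the frame rigidly,
so different seeds give different coordinates but exactly the same contact
topology.

What the toy emulates: a compact two-state fold with identifiable loops,
swap-compatible topology and tunable termini strain.  What it does not
emulate: heterogeneous real contact networks, side-chain packing, or the
sequence-specific loop geometries of real domains — so campaign populations
on toys demonstrate the mechanism and the machinery, not the quantitative
misfolding propensities of any real protein, which require the full
published campaign scale (1024 trajectories of 12 microseconds on
experimentally determined structures).

The packaged demonstration (`demo_campaign_spec()`) uses a two-strand
hairpin domain (8-residue strands, 5-residue loop) joined by a 5-residue
structureless linker of the same length as the loop.  The tandem then holds
three near-equivalent turn sites — loop, linker, loop — and the swapped
"central" hairpin closes a turn geometrically equivalent to the native one,
so the native/misfolded competition is decided kinetically, as in real
misfolding-prone tandems.  At 300 K, 256 trajectories of at most 6 ns
finish in a few minutes and typically yield ninety-odd percent native folds
and a few percent complete domain-swapped misfolds; the control system — a
flat four-strand meander whose termini sit 1.25 nm apart with no linker —
yields none, because its central domain would have to bridge that distance
with a single backbone bond.  Larger meander toys fold natively with
essentially no misfolding at this scale: their folding is a local zipper in
which intra-domain nuclei always outrun cross-junction ones, a genuine
small-system effect worth keeping in mind when reading toy campaigns.

The alchemical predictor is validated on a family of four-strand toys
whose termini separation (and hence termini-joining cost) varies from a
closed barrel to a flat sheet (`permutant_stability_study()`).  Because
family members have different contact maps and melting temperatures, each
is evaluated at its own working temperature — found by a fixed
scan-and-band rule on the wild type — and the simulated quantity compared
with the predicted destabilization is the permutant stability *relative to
its own wild type*, which is exactly what the join-plus-cut decomposition
predicts.  One-sided profiles (permutants with no folded basin) fall back
to a fixed dividing surface at Q = 0.5.  Two resolution limits are worth
stating plainly: the predictor is a step function of the number of peeled
residues, so nearly identical structures can straddle a peel-count
boundary and receive very different scores; and desk-scale umbrella
estimates of a permutant stability carry roughly 1–2 kcal/mol of
occasionally outlier-prone noise.  The coarse trend — minimal-strain
permutants near-isostable with wild type, strongly strained ones
destabilized by several kcal/mol — reproduces robustly, while fine-grained
rank order within a strain level is at the edge of what this sampling
scale resolves.

## The WSME model

The Ising picture keeps one contiguous native segment on the 2L-residue
tandem (single-sequence approximation), with
G = sum(eps over contacts inside the segment) - N_f T ds + Ep theta, where
theta = 1 when the segment crosses the midpoint — such a segment is
necessarily a circular-permutant fold and pays the termini-joining strain
Ep.  Segments longer than L are rejected (only first-domain formation is
modelled).  Because any window of length L in the duplicated map contains
exactly one copy of every native contact, all full-length segments are
degenerate at Ep = 0; the model isolates, in its purest form, the effect of
permutant strain on the competition.  Near-junction swap copies with short
sequence separation are retained in the map for exactly this reason.  Exact
enumeration (the state space is only O(L^2)) serves as the oracle for the
Metropolis chain.  The Monte Carlo move set flips one residue among the
segment ends and their outer neighbours (any residue can nucleate from the
empty state); since that proposal set is asymmetric between the empty state
and one-residue segments, the acceptance includes the proposal-ratio
correction, keeping the chain in exact detailed balance — without it the
empty-state occupancy is biased.  Default temperature for surface plots is
525 K.  The per-residue entropy ds and uniform eps are user parameters (the
published account prints Ep and T but not its eps/ds pair); the package
default ds = -0.004 kcal/mol/K places the folding transition of a toy-sized
domain in the few-hundred-kelvin range.

## The alchemical predictor

The stability change of a circular permutant relative to wild type is
dG_J + dG_C: join the termini, then cut the loop at K.  Joining searches
peel windows (up to nine residues off each terminus); a candidate is
feasible when the anchors sit closer than (n_peeled - M) * 0.35 nm, with
M = 6 when the termini point in opposite directions (about six residues form
the joining turn) and 0 otherwise.  With no residues peeled the printed
condition can never hold, so feasibility additionally accepts termini
already within one peel length (0.35 nm) — this is what makes "join for
free" possible for folds whose termini touch.  Peeling costs every broken
contact once (counting each broken contact twice, once per endpoint, would
double-count the physical energy) and gains T |ds| per peeled residue that
carried contacts; residues with no native contacts (counted by kappa) gain
nothing.  The same no-contact rule is applied in the cut step: without it
the window search would always favour unfolding the maximal contact-free
stretch and report a spurious negative dG_C, whereas a cut in a
contact-free loop should cost exactly zero.  The per-residue entropy is
ds = sum(eps) / (T N), the value that makes the total entropic cost cancel
the total contact energy at the folding temperature.  Ties in the window
searches resolve to the fewest-residue choice.

## Statistics

Rank correlations use mid-rank (fractional) ties — required to reproduce
published correlation values where populations are tied — and populations
carry the binomial standard error sqrt(p(1-p)/n).  The packaged reference
table (`misfolding_reference()`) holds the published per-fold properties and
end-of-campaign populations for seven tandem-repeat proteins;
`correlation_report()` reproduces its bracketed rank correlations.  Because
that table prints its columns rounded to one decimal, two of the fifteen
correlations (computed upstream from unrounded inputs) differ from a
recomputation by up to 0.01; the rest agree to 0.005.

## Numerical choices and limitations

* Forces are capped at 2000 kcal/mol/nm per component and pair cores are
  flat below 0.1 nm; both guards act only in catastrophic geometries.
* The dynamics RNG is the package's own xoshiro256++/Box–Muller stream, so
  trajectories are reproducible across platforms and independent of R's
  global RNG state; R-side stochastic helpers restore the caller's RNG.
* WHAM bins never visited are dropped rather than imputed; WSME surface
  cells never visited are NA ("unreachable"), never zero.
* The toy lattice cannot represent termini separations outside the range
  spanned by the flat sheet and the closed barrel for a given strand count;
  requests outside that range (beyond 10%) are errors.
* Tandem first-passage campaigns on toys under-sample rare misfolds by
  construction at desk scale; the classification threshold (0.8) and
  campaign sizes are stated with every summary so populations can be
  compared across runs.
* PDB input keeps the first alternate location, drops heteroatoms and
  renumbers contiguously; chain breaks are recorded as warnings on the
  structure, since a one-bead chain model needs contiguous beads.

## A worked micro-example

```{r example, eval = FALSE}
spec <- demo_campaign_spec()
toy <- make_toy_structure(spec$friendly_toy)
model <- build_go_model(toy)
tandem <- build_tandem_model(model, spec$friendly_linker)
enumerate_cut_sites(model)
campaign <- first_passage_campaign(
  tandem, n_traj = spec$n_traj_friendly,
  params = langevin_params(spec$temperature, spec$t_max, seed = 7),
  check_every = spec$check_every
)
campaign$summary
autoplot(campaign)
```
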