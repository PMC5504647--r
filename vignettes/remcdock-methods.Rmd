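---
title: "Methods: replica-exchange docking samplers with Pareto-front replica selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replica-exchange docking samplers with Pareto-front replica selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(remcdock)
```

## The sampling model

`remcdock` samples protein–small-molecule poses from the Boltzmann
distribution of a pluggable energy model.  A pose is a rigid receptor, a
discrete ligand conformer library, and the ligand rigid-body placement
(conformer index, rotation, centre).  One Metropolis step proposes a
perturbed pose, scores it, and accepts with probability

$$ p(\mathrm{old}\to\mathrm{new}) =
   e^{\min(40,\,\max(-40,\,(E_\mathrm{old}-E_\mathrm{new})/T))}, $$

with the Boltzmann constant set to 1 so temperature is measured in
energy units.  The exponent clamp keeps the arithmetic finite against
the capped-but-large repulsive energies of clashing poses; a fast path
accepts downhill moves without evaluating the exponential and agrees
with the direct rule exactly (this equivalence is asserted over $10^5$
random tuples in the test suite).  When a proposal is rejected, the
chain's retained sample for that step is a duplicate of the previous
accepted pose; it is that retained sample, with an `accepted` flag, that
enters the history archive.  This convention makes the last `numR`
archive entries exactly the current states of the `numR` replicas, so
the classic replica-exchange selector is a true continuation of each
chain, and a one-replica exchange run is bit-identical to plain
Metropolis under the same stream.

### Replica exchange

`remc_run()` maintains `numR` replicas on a geometric temperature ladder
spanning `[minT, maxT]` (geometric spacing is the standard choice for
roughly uniform acceptance between neighbouring rungs; only the
endpoints are inputs).  Each outer cycle has three phases:

1. every replica advances `numC` local Metropolis steps at its rung's
   temperature, in lockstep (step *k* of every replica before step
   *k*+1), pushing retained samples onto the shared archive;
2. exchanges are attempted for the even rung pairs (1,2), (3,4), …
   only, accepting with probability 1 when
   $\Delta=(\beta_j-\beta_i)(E_i-E_j)\le 0$, rejecting outright when
   $\Delta>75$ (no random number is consumed), and with $e^{-\Delta}$
   otherwise;
3. a selector rebuilds the replica ensemble from the archive.

The even-pair-only scheme is implemented deliberately, although it
breaks detailed balance and, structurally, partitions the ladder into
disconnected rung pairs: rungs 2 and 3 never exchange, so a given
replica label only ever visits the two rungs of its pair.  States still
cross the whole ladder under the Pareto selectors, which may re-seed any
rung from any archived sample.  A config flag
(`alternate_odd_pairs`) additionally attempts the odd pairs on even
cycles; it is off by default to keep the reference scheme.

### Replica selection

Selection is what distinguishes the samplers.  Objectives are
$(x, y) = (\text{global MC step}, \text{TScore})$ over the archive;
because steps are strictly increasing, the min-min Pareto front is the
sequence of strict record minima of the score history and the max-min
front is the strict suffix minima (most recent records).  The general
sweep in `pareto_front()` supports all four minimise/maximise scenario
combinations and is tested exactly against an independent $O(n^2)$
dominance scan.

* `last` — the `numR` most recent entries; each replica continues from
  its own state (classic parallel tempering).
* `mo` — the min-min front; if larger than `numR`, its `numR`
  lowest-TScore members (ties to the more recent entry); if smaller,
  completed with the most recent non-front entries.
* `hmo` — the union of the min-min and max-min fronts, truncated to the
  `numR` lowest-TScore members or completed from the most recent
  entries.

Selected poses are assigned to rungs in order of increasing TScore →
increasing temperature, so the best template explores from the coldest
rung.  For the `last` selector this re-assignment is skipped — the
entries *are* the replicas' current states, and re-sorting continuing
chains across temperatures outside the Metropolis exchange would
distort the per-rung canonical distributions that the occupancy
diagnostics rely on.  Selected energies are re-used from the archive
(scores are deterministic, so re-scoring would be redundant).  Both MO
selectors provably retain the archive's global TScore minimiser.

The archive is global across cycles by default ("history-dependent"
selection); `archive_mode = "cycle"` restricts the selection window to
the current cycle.

### Reproducibility

One master seed drives everything.  Replica *i* draws from its own
stream seeded with `derive_stream_seed(seed, i)`
(`(seed · 48271 + i · 1000003) mod (2^31 − 1)`), and the exchange sweep
from stream 0, so results are independent of the order in which
replicas are advanced between exchange points — a serial run reproduces
a parallel schedule bit-for-bit, and replicas may safely be evaluated
concurrently between exchanges.

## Energy models

The energy-model contract is a deterministic `score(state)` function;
docking scores and analytic test landscapes implement it equally, which
is what lets million-step oracle tests run on the same sampler code
that docks poses.

The coarse-grained contact score is
$S_{cg} = R - \min(A/N, 0.85)$ with clash radius 2.25 Å (strictly
within; receptor backbone and Cβ atoms only) and contact band
(2.25, 4.75) Å against any receptor atom; a clashing atom is never also
counted as a contact, and hydrogens are excluded throughout.  Band
boundaries are exclusive — the bands are open intervals, so an atom at
exactly 2.25 Å counts in neither.

The full-atom score is a weighted sum $\sum_i w_i s_i$ over named score
items with shipped "hard" (repacking) and "soft" (minimisation) weight
presets.  The term functions are *simplified surrogates*, documented in
`?surrogate_params`:

| parameter | default | meaning |
|---|---|---|
| `lj_rmin` | 3.6 Å | pair-potential minimum distance |
| `lj_depth` | 0.2 | base well depth (energy units) |
| `lj_cutoff` | 12 Å | interaction cutoff |
| `rep_cap` | 1e4 | finite repulsion cap at overlap |
| `hbond_d0`, `hbond_sd`, `hbond_depth` | 2.8 Å, 0.3 Å, 1.0 | Gaussian H-bond well |
| `sol_sd`, `sol_scale` | 3.0 Å, 0.05 | Gaussian burial penalty |

Attractive terms (split Lennard-Jones and the H-bond wells) scale with
a per-receptor-atom multiplier `eps`, which is how toy fixtures plant a
binding pocket; sequence-statistics items (pair energy, backbone
dihedral preferences, reference energies, intra-receptor hydrogen
bonds) are constant-zero stubs under the rigid-receptor model and are
listed in every breakdown so the weighted-sum engine sees the full item
vocabulary.  The finite repulsion cap (with squared distances floored
at $10^{-12}$ Å²) keeps exactly overlapping atoms finite so Metropolis
arithmetic never sees `Inf`.

Movers are functional (the input pose is never mutated) and preserve
ligand atom identity and intramolecular geometry exactly, since
coordinates are derived from the stored conformer plus a rigid
transform.  Default magnitudes — trial 0.2 Å / 5° with conformer-swap
probability 0.2, repack 1.0 Å / 30° with a forced uniform conformer
resample every `repackNth`-th step — are package choices (the sampling
algorithms themselves do not prescribe them) and are configurable.
Rotation proposals use an axis uniform on the sphere with a Gaussian
angle, an unbiased small-rotation proposal.

## Synthetic fixtures: what they do and do not emulate

`make_discrete_system()` and `make_double_well()` provide landscapes
whose Boltzmann behaviour is available in closed form (enumeration,
resp. quadrature via `integrate()`), giving exact oracles for
stationarity, exchange statistics and barrier crossing.

`make_toy_complex()` builds a spherical-cap receptor shell
(Fibonacci-lattice pseudo-atoms, default 150) with a pocket of deepened
`eps` near the pole, a compact ligand (default 8 atoms within 0.9 Å of
the centroid) with a jittered conformer library, a planted native pose,
and a randomised start inside the cavity.  Design notes:

* the ligand is kept compact so that any orientation at the correct
  centre stays within the 2 Å success radius — orientation is only
  weakly coupled to the toy energy, and a larger ligand would make the
  success criterion test orientation search rather than pocket finding;
* the start pose is placed *inside* the cavity because the surrogate
  potential is short-ranged: outside the shell a random walk feels no
  gradient and is transient in three dimensions;
* the native centre is located by optimising the model energy along the
  pocket axis at fixture-build time, because the compromise between the
  Lennard-Jones and hydrogen-bond optimal distances depends on the
  ligand's shape; orientation/conformer search can still find slightly
  deeper poses in the same pocket (within the success radius);
* generators are pure functions of their spec (including the seed) and
  never disturb the ambient RNG.

What passing on these fixtures does **not** show: chemically realistic
ligand topologies, receptor flexibility, solvent, or agreement with any
production docking score on real complexes.  The fixtures validate the
*samplers and selection machinery*, not the physics.

## Analysis conventions

Ligand RMSD is computed over non-hydrogen atoms in the fixed receptor
frame, without superposition; ≤ 2 Å is the success criterion.
Near-duplicate filtering visits decoys in a seeded random order and
drops any decoy within $0.65\sqrt{N}$ Å of an already-kept one.  Decoy
ranking discards non-touching decoys (no ligand atom within 4.75 Å of
the receptor, re-using the outer contact radius), keeps the
$\max(1, \lfloor 0.05m \rfloor)$ lowest-energy survivors (the floor plus
minimum-one rule never empties a non-empty pool), and sorts by interface
delta.  The interface delta separates the ligand by 500 Å; with a 12 Å
cutoff any separation beyond the cutoff is equivalent.  Temperature
occupancy is reported as normalised per-replica visit frequencies (rows
sum to one) with mean/variance summaries.

## Test problem sizes and observed behaviour

The packaged checks run, per invocation: $10^3$ random point sets
(n ≤ 200, all four scenario orientations) against the brute-force
dominance oracle; $10^6$-step chains on the 3-state system at T ∈
{1, 2, 4} (total-variation distance from the exact distribution is
measured, with 0.01 as the acceptance band); $10^5$ exchange attempts at
Δ = 1.25; double-well runs (barrier 6, asymmetry 2, proposal sd 0.4,
ladder 2–4 with 4 replicas, numC 16, 2×10⁵ total steps, 20 seeds); and
20-seed toy-docking runs with configuration (8, 8, 3, 2, 4) capped at
$10^5$ total steps.  Asymmetry 2 was chosen so the two wells have
genuinely different Boltzmann mass (ratio ≈ 0.40 at T = 2) and the
cold-rung occupancy comparison is non-trivial; "visiting the second
well" means reaching x ≥ +0.8 from a start in the deeper well, and the
cold-rung statistics discard the first 20% of each run as burn-in.

One observed behaviour deserves a note.  On the double well, the
first-visit medians computed by `scripts/acceptance.R` consistently
show replica exchange far ahead of single-chain MC, but the hybrid
Pareto selector *behind* plain replica exchange.  This is expected from
the mechanism: re-seeding replicas from low-energy archive records each
cycle interrupts the sustained uphill excursions that first passage
into a higher-energy basin requires.  Greedy history-based selection
accelerates convergence *toward* low-energy basins — its design goal —
and is at best neutral for escaping them; on a landscape this small
(barrier/minT = 3), many seeds also cross before the methods have
diverged, so the remaining difference is dominated by the reset
penalty.

## Known limitations

* The surrogate terms are not a physical force field; absolute energies
  are meaningful only within a model.
* The even-pair exchange scheme breaks detailed balance and confines
  replica labels to rung pairs (see above); the `last`-selector sampler
  is therefore only approximately canonical, though the measured
  cold-rung occupancy error on the double well is at the percent level.
* Only rigid-receptor, discrete-conformer docking is modelled; no
  torsional ligand flexibility beyond the conformer set.
* k > 2 objectives and diversity-preserving selection (crowding and the
  like) are out of scope.
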