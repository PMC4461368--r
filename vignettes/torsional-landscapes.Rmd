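---
title: "Hierarchical conformational analysis of backbone torsional dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical conformational analysis of backbone torsional dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionfel)
library(dplyr)
```

## The model

A folded globular protein does not occupy a single structure but a
hierarchy of conformational substates (CSs): combinations of discrete
torsional states of its backbone dihedrals $\phi_i$, $\psi_i$ (and,
optionally, side-chain $\chi$ rotamers). torsionfel analyzes this hierarchy
directly in torsion space:

1. **Torsional states.** Each dihedral's pooled angle distribution is
   histogrammed in 1° circular bins. Effective local minima of the
   distribution — after merging minima closer than 60°, keeping the deeper
   one — cut the circle into cyclic arcs; each arc is one torsional state.
   Dihedrals with exactly two effective minima are two-state degrees of
   freedom (DOFs) and carry one bit of conformational information each;
   three-state $\chi$ rotamers carry two bits.

2. **Temporal resolutions.** A DOF's kinetics is summarized by its mean
   waiting time $t_w = T_\mathrm{total} / N_\mathrm{trans}$, the total
   simulated time over the number of observed frame-to-frame state changes.
   DOFs are stratified into decade bands: $t_w \in [2, 20)$ ns is T4,
   $[20, 200)$ ns is T3, up to $[20, 200)\ \mu$s for T0. Internally the
   bands are decade bins of $N_\mathrm{trans}$ scaled by
   $s = T_\mathrm{total} / 200\,\mu\mathrm{s}$, which is algebraically the
   same thing for any ensemble length.

3. **Hierarchical clustering.** At resolution Tk, every frame is assigned a
   key built from the states of all DOFs in band Tk *or coarser* (faster
   DOFs are treated as single-state and ignored). Two frames belong to the
   same CS exactly when their keys are equal. Because the coarse DOFs form a
   bit-prefix of the fine keys, the partition at T(k+1) refines the
   partition at Tk by construction; grouping is a radix sort over machine
   integers, so clustering $10^7$ frames costs seconds.

4. **Transition networks.** Consecutive frames with different keys define an
   (undirected, counted) edge between two CSs. The network's shape is
   summarized by the *max-degree share* — the fraction of distinct edges
   incident to the highest-degree node (1 for a perfect star) — and
   per-node $N_\mathrm{conn}/W$, the transition count normalized by
   statistical weight, whose low outliers are kinetic traps.

5. **Transition-state ensembles (TSE).** Around each effective minimum a
   transition-state arc is defined: a fixed 5° arc (±2.5°) for T3/T4 DOFs;
   for slower DOFs the arc grows outward in 2.5° bins until the flank counts
   jump — the first $i$ with
   $N_{\pm(i+2)} - N_{\pm(i+1)} \ge 3\,(N_{\pm(i+1)} - N_{\pm i})$, both
   differences positive, includes bins $1..i+1$. A maximal run of frames
   inside the arc is a TSE event only if the frames immediately before and
   after the run belong to different clusters; its lifetime is the run
   length times the frame interval.

6. **Structural properties and dPCA.** Per-snapshot radius of gyration,
   native contacts (non-sequential residues, C$\alpha$ < 6.5 Å, present in
   ≥ 2/3 of a reference ensemble), hydrogen bonds (donor–acceptor < 3.5 Å,
   D–H–A > 130°), hydrophobic solvent-accessible surface area
   (Shrake–Rupley, 1.4 Å probe radius), pairwise backbone RMSD after Kabsch
   superposition, and dihedral PCA on $q_{2i-1} = \cos\phi_i$,
   $q_{2i} = \sin\psi_i$ (with the full sin/cos representation available).

## The synthetic generator

MD trajectories long enough to populate five decade bands are not shipped
with a package, so every stage is validated against a seeded telegraph
generator (`telegraph_spec()`, `ensemble_spec()`, `simulate_ensemble()`).
Each DOF is a continuous-time Markov chain over its states — dwell times
exponential with per-state exit rates — *sampled on the saved-frame grid*,
so transitions completed between two saved frames are invisible, exactly as
in real snapshot data. Angles are emitted with von Mises noise about the
state centers, optionally truncated so an emitted angle never leaves its
state's arc.

Three mechanisms extend the bare telegraph process:

* **Master–slave coupling** (`master`, `coupling`): a slave copies its
  master's state with per-frame fidelity `coupling`, else shows its own
  independent telegraph state. This is the simplest mechanism that creates
  a dominant shared substate at coarse resolution — a hub.
* **Barrier transits** (`transit_mean_frames`): at each state flip, a
  geometric number of frames is emitted within ±2.4° of a crossing minimum
  (one of the two cyclic routes, chosen uniformly), moving from the
  departing side to the arriving side. This emulates the finite
  barrier-crossing time of real torsions, which is set by the local barrier
  shape and not by the waiting time between flips — the physics behind
  rate-independent TSE lifetimes. It is off by default.
* **Counter-based seeding**: each (trajectory, DOF) pair gets its own
  deterministic stream derived from one integer seed, so ensembles are
  reproducible in any iteration order.

What the generator does *not* emulate: Cartesian geometry and sterics,
state-dependent rates (a slave's deviations are per-frame noise rather than
activated events), correlated multi-DOF barrier crossings, and solvent or
temperature effects. Passing tests therefore demonstrate that the analysis
machinery recovers known torsional kinetics — not that any particular
protein behaves this way.

## Study designs

Three canned designs fix the conditions under which the qualitative claims
are tested; their parameters were chosen once, on kinetic grounds, and are
part of the package (`hub_ensemble_spec()`, `tse_ensemble_spec()`,
`dpca_ensemble_spec()`, `rate_recovery_spec()`).

**Hub vs network** (`hub_ensemble_spec`): one slow master with a 98%
dominant state ($t_w \approx 0.56\ \mu$s, band T2), eight slaves at
fidelity 0.99995 whose own hidden states are biased opposite to the
master's dominant state — so their rare deviations are visible precisely
when the system sits in the dominant cluster, attaching every satellite to
the hub — and six independent fast DOFs ($t_w \approx 6$ ns, T4).
5 trajectories × 2 µs at 50 ps spacing. At T2 the transition network is a
star (max-degree share 1); at T4 the six fast DOFs shatter the landscape
into hundreds of clusters with share ≈ 0.03.

**TSE lifetime invariance** (`tse_ensemble_spec`): four independent DOFs
with identical emission and transit parameters but waiting times of 4 ns,
40 ns, 400 ns and 4 µs (bands T4–T1), 4 trajectories × 40 µs at 200 ps.
Group-mean TSE lifetimes agree within a factor of ~1.2 while the waiting
times span three decades.

**dPCA contrast** (`dpca_ensemble_spec`): a four-DOF collective mode
(waiting 20 ns) plus four DOFs frozen on the single-trajectory timescale
(waiting 100 µs) with random initial states. One trajectory's variance is
dominated by the collective mode (top-1 fraction ≈ 0.9); pooling ten
trajectories adds four independent directions and roughly halves it.

**Rate recovery** (`rate_recovery_spec`): one symmetric DOF simulated for
316 expected waiting times at a frame interval of $t_w/50$, so
discretization hides under 2% of transitions — small against the
$3 t_w/\sqrt{N_\mathrm{trans}} \approx 17\%$ sampling tolerance.

## Numerical choices

* **Angles** live in $(-180, 180]$ degrees; bin $i$ covers
  $[-180+i, -180+i+1)$; arcs are half-open $[\mathrm{start}, \mathrm{end})$
  in the direction of increasing angle, so an angle exactly on a minimum
  belongs to the arc it starts.
* **Minima on finite histograms.** Histograms built from tens of millions of
  snapshots are smooth; finite samples are not. Detection
  therefore (a) smooths with a 5° circular moving average (window 1
  disables), (b) collapses minima whose separating maximum holds less than
  `1e-4` of all snapshots (floor: 3 smoothed counts) — stray counts inside
  an empty barrier region do not split it, (c) drops dips whose density
  exceeds half the lower flanking peak (`min_prominence = 0.5`), and
  (d) re-centers each surviving minimum at the circular midpoint of its
  valley floor (the region below half the lower flanking peak), which keeps
  the boundary at the barrier top even when transition-state density puts a
  small bump exactly at the minimum. Plateaus resolve to their central bin,
  ties to the lower index.
* **Merging order**: the closest pair of minima is resolved first, repeated
  to fixpoint; the deeper (smaller-density) minimum survives. The opposite
  reading of the merge rule is available via `keep = "shallower"`.
* **State indices** are assigned by descending occupancy (0 = most
  populated), which makes bit encodings stable across runs of the same
  data.
* **Keys** are doubles holding up to 52 bits; wider DOF sets fall back to
  string keys with identical grouping semantics.
* **TSE growth rule**: "much greater" is quantified as ratio 3 with both
  successive differences positive and the outer flank count at least 10;
  unresolvable flanks (fewer than 3 usable 2.5° bins before the next
  minimum, or no jump) fall back to the fixed 5° arc with a warning.
* **SASA probe**: the water probe is a 1.4 Å *radius* by convention;
  pass `probe_radius = 0.7` to read a "1.4 Å diameter" literally.
  Sphere sampling uses a deterministic golden-spiral point set (960 points
  by default; the isolated-atom area is then exact to ~0.2%).
* **Hydrophobic residues** default to ALA, VAL, LEU, ILE, PRO, PHE, MET,
  TRP; both the set and the element radius table are arguments.
* **Degenerate inputs**: flat histograms yield zero minima (single-state
  DOF); constant dPCA input yields all-zero eigenvalues, not an error;
  DOFs with no observed transitions are excluded from banding rather than
  given an infinite waiting time.

## Design choices that were genuinely open

* **Coupling mechanism.** No quantitative model of inter-DOF correlation is
  implied by backbone-torsion clustering itself; per-frame master copying
  was chosen as the simplest mechanism producing a hub. Activated,
  state-dependent couplings would be more physical but add rate parameters
  the analyses never see.
* **TSE flank example.** The growth rule stops at the first $i$ satisfying
  the jump inequality and includes bins $1..i+1$; for flank counts
  10, 12, 14, 40 at ratio 3 that is $i = 2$, i.e. three bins (7.5°) per
  side.
* **Event linkage.** An event's cluster pair is taken from the frames
  flanking the in-arc run at the event's own resolution. When an unrelated
  DOF flips during the run, that pair may have been traversed through an
  intermediate key, so a small fraction of events link pairs that are not
  single-step network edges; this is inherent to per-DOF events in a
  multi-DOF landscape.
* **TSE frames and weights.** TSE membership is an overlay label; TSE
  frames keep their cluster membership so statistical weights always sum
  to 1.

## Problem sizes

The shipped validation runs use 0.2–3.2 million frame-DOF samples per
design — e.g. 5 × 40 000 frames × 15 DOFs for the hub design and
4 × 200 000 × 4 for the TSE design — which populate three to four decade
bands with comfortable counting statistics while a full validation pass
stays in the minutes range on a laptop.

## A worked miniature

```{r example}
spec <- ensemble_spec(
  n_trajectories = 2, frames_per_trajectory = 5000, frame_interval_ps = 100,
  dofs = list(
    telegraph_spec("phi24", exit_rates = 1 / 6,  state_centers = c(-60, 120),
                   dof_kind = "phi"),
    telegraph_spec("psi24", exit_rates = 1 / 60, state_centers = c(-90, 90),
                   dof_kind = "psi"),
    telegraph_spec("phi57", exit_rates = 1 / 300, state_centers = c(-70, 110),
                   dof_kind = "phi")
  ),
  seed = 11
)
ens <- simulate_ensemble(spec)
fit <- fit_torsion_states(ens)
glance(fit)

states <- assign_states(ens, fit)
ts <- dof_timescales(states, dofs = select_clustering_dofs(fit))
ts

hier <- cluster_hierarchy(states, ts)
glance(hier)

net <- build_network(hier, rev(hier$resolutions)[1])
hub_score(net)
```

## Known limitations

* Minima placement on small samples is accurate to a few degrees; with
  broad emission noise this inflates the counted transitions of very slow
  DOFs (boundary flicker), though rarely enough to change a decade band.
* The generator's slaves deviate by per-frame noise, so their observed
  transition counts include a fidelity-driven component that must be kept
  small when a slave is meant to share its master's band.
* The compact dPCA representation ($\cos\phi$, $\sin\psi$) cannot
  distinguish $\phi$ from $-\phi$; use `representation = "full_sincos"`
  when that matters.
* Hydrogen-bond donors/acceptors are inferred from elements and covalent
  H distances, not residue templates; unusual chemistry needs explicit
  atom tables.
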