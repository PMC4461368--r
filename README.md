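# torsionfel

Hierarchical conformational-substate analysis of protein free-energy
landscapes through backbone torsional degrees of freedom.

## The problem

A folded protein's free-energy landscape (FEL) is organized hierarchically:
at any moment the molecule occupies one *conformational substate* (CS) — a
particular combination of discrete torsional states of its backbone
dihedrals φ, ψ — and wanders between CSs on timescales from nanoseconds to
far beyond microseconds. Cartesian RMSD clustering and principal components
flatten this structure; analyzing the torsions directly keeps both the
combinatorial identity of each substate and its kinetics.

torsionfel is for computational biophysicists who have long
molecular-dynamics ensembles (or any per-frame dihedral table) and want the
landscape resolved *per timescale*:

* **Torsional states** — each dihedral's pooled angle distribution is
  histogrammed in 1° circular bins; effective local minima (merged when
  closer than 60°, the deeper one kept) split the circle into states.
  Dihedrals with two effective minima are two-state DOFs; χ rotamers with
  three states are supported.
* **Temporal bands** — each DOF's mean waiting time
  `t_w = total_time / N_trans` places it in a decade band, T4 (2–20 ns)
  through T0 (20–200 µs).
* **Bit-encoded clustering** — at resolution Tk, frames are keyed by the
  states of all DOFs in band Tk or coarser (one bit per two-state DOF, two
  for three-state) and grouped by radix sort; the fine partition refines
  the coarse one exactly.
* **Transition networks** — consecutive-frame key changes are counted
  edges; hub scores and weight-normalized connectivity (`N_conn/W`) expose
  hub-like coarse topology, network-like fine topology, and kinetic traps.
* **Transition-state ensembles** — arcs around the minima (fixed 5°, or
  grown by a flank-count jump rule on slow DOFs) plus a cluster-change
  coincidence rule label barrier-crossing snapshots and their lifetimes.
* **Structural properties** — radius of gyration, native contacts
  (Cα < 6.5 Å, non-sequential, ≥ 2/3 prevalence in a reference ensemble),
  hydrogen bonds (< 3.5 Å, > 130°), hydrophobic SASA (Shrake–Rupley,
  1.4 Å probe), pairwise backbone RMSD (Kabsch), and dihedral PCA with the
  compact `cos φ / sin ψ` representation.

A seeded telegraph-process generator (`simulate_ensemble()`) produces
torsional ensembles with known kinetics — including master–slave coupling
for hub topologies and barrier-transit emission for transition-state
lifetimes — so the whole pipeline is testable without MD data.

## A worked example

```r
library(torsionfel)

spec <- ensemble_spec(
  n_trajectories = 2, frames_per_trajectory = 5000, frame_interval_ps = 100,
  dofs = list(
    telegraph_spec("phi24", exit_rates = 1/6,   state_centers = c(-60, 120), dof_kind = "phi"),
    telegraph_spec("psi24", exit_rates = 1/60,  state_centers = c(-90, 90),  dof_kind = "psi"),
    telegraph_spec("phi57", exit_rates = 1/300, state_centers = c(-70, 110), dof_kind = "phi")
  ),
  seed = 11
)
ens    <- simulate_ensemble(spec)
fit    <- fit_torsion_states(ens)
states <- assign_states(ens, fit)
ts     <- dof_timescales(states, dofs = select_clustering_dofs(fit))
ts
#> # A tibble: 3 × 5
#>   dof_id n_trans total_time_us  t_w_us band
#>   <chr>    <int>         <dbl>   <dbl> <chr>
#> 1 phi24      185             1 0.00541 T4
#> 2 phi57        2             1 0.5     T2
#> 3 psi24       20             1 0.05    T3
```

The three dihedrals land in three decade bands: `phi24` flips every ~5 ns
(T4), `psi24` every 50 ns (T3), `phi57` every 0.5 µs (T2). Clustering at
each band and summarizing:

```r
hier <- cluster_hierarchy(states, ts)
glance(hier)
#> # A tibble: 3 × 5
#>   resolution n_clusters n_dofs top_W W_sum_top10
#>   <chr>           <int>  <int> <dbl>       <dbl>
#> 1 T2                  2      1 0.934           1
#> 2 T3                  3      2 0.537           1
#> 3 T4                  6      3 0.276           1

hub_score(build_network(hier, "T4"))
#> # A tibble: 1 × 4
#>   max_degree_share mean_degree degree_variance dominant_node_W
#>              <dbl>       <dbl>           <dbl>           <dbl>
#> 1              0.5           2             0.4           0.215
```

At the coarsest band the landscape is two substates dominated by one with
93% of the weight; refining to T4 splits it into six substates whose
transition network no longer has a dominant node. `derive_tse_regions()` /
`label_tse_events()` add transition-state lifetimes, `fit_dpca()` the
principal-component view, and `run_pipeline()` chains every stage from a
config (YAML or `pipeline_config()`), writing TSV/GraphML outputs.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and result
types have `autoplot()` methods.

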