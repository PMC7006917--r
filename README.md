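# aggsim

Agent-based simulation of molecular aggregation at the plasma membrane.

Membrane proteins cluster at the nanoscale, and super-resolution microscopy
shows those clusters changing with subtle perturbations of the cell. The many
competing processes proposed to drive this (lipid domains, protein affinity,
the actin picket fence, size exclusion) are hard to model together. `aggsim`
implements a deliberately abstract alternative for people who study membrane
organisation quantitatively: every molecule is an agent whose Brownian
mobility depends only on the local density around it — a single "desire for
clustering" rule — and the package asks how much of the observed clustering
phenomenology that one rule reproduces.

## The model

2000 agents diffuse on a toroidally wrapped 3 × 3 µm² patch, updated every
10 ms for 5 simulated minutes. The local density of agent *i* is the
localized linearised Ripley's L value

    L_{R,i} = sqrt( A k_i / (π (n − 1)) ),

with `k_i` the number of molecules within R = 100 nm ("encircled
molecules"), normalised so a completely spatially random (CSR) pattern has
⟨L_R⟩ = R (7 encircled molecules ↔ L₁₀₀ ≈ 100 nm at the standard density).
Each frame, an agent's step length is read off a displacement-versus-L
profile: in the Standard Condition it falls linearly from D_max = 3.5 nm/ms
at L = 0 to zero at a target L, so molecules at or above their target
density are immobile. Variants include a positive mobility floor, a tent
profile immobile only at exact equality, a quadratic decay, Gaussian instead
of fixed-length steps, and reflective actin-mesh barriers on a 250/500/1000
nm grid.

The package provides the compiled simulation engine with seeded replicate
ensembles, the L statistic (cell-list accelerated, with a brute-force
oracle), a density-based cluster caller with per-ROI descriptors (cluster
count, % clustered, molecules per cluster, cluster radius), and
convergence/regime/cut-off analytics for sweeps over the clustering target:
converged runs plateau above the CSR level, marginal ones are still rising
after 5 minutes, and beyond a sharp cut-off target the system never leaves
CSR — aggregation is digitized.

## Worked example

```r
library(aggsim)

cfg <- standard_condition(target_count = 45, seed = 1)  # L target ~254 nm
tr  <- run_simulation(cfg)
tr
#> <sim_trajectory> 30000 frames, <L> 98.2 -> 330.4 nm (seed 1)

rep <- analyse_clusters(tr$final_frame)
rep
#> <cluster_report> 6 clusters, 100.0% clustered, 333.3 molecules/cluster, radius 182.8 nm
```

The mean localized density ⟨L¹⁰⁰⟩ starts at the CSR level (~100 nm, i.e. ~7
neighbours within 100 nm), rises as nucleation sites appear and grow, and
plateaus well above the 254 nm target — converged runs systematically
overshoot, because molecules keep attaching to the rim of already-frozen
clusters. The final frame contains a handful of large dense clusters (six
here) holding essentially all molecules. Raising the target slightly changes the outcome
drastically (fewer, larger clusters), and past ~67 encircled molecules the
pattern simply stays CSR:

```r
sw <- sweep_targets(c(63, 65, 67, 69), standard_condition(record_every = 0L),
                    n_reps = 5)
sw$cutoff   # digitization threshold on this grid
```

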