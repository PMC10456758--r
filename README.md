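# swarmentropy

Quantifying spatial order in 2-D collective systems — boid simulations,
active colloids, robotic swarms — through the **entropy by neighbor
distance**.

## The problem and the measure

Collective systems self-organize into global patterns out of local rules.
The classic order parameter, the average velocity

    v_a = |Σᵢ vᵢ| / (N·V)  ∈ [0, 1],

measures heading alignment but is blind to *positional* order, and
point-group symmetry analysis does not transfer to configurations that
rearrange continuously. `swarmentropy` implements a complementary,
position-based measure: collect the distance from every agent to each of
its neighbors, bin the pooled distances into uniform intervals of width
`w`, and take the Shannon entropy of the resulting distribution,

    H_NDist = − Σᵢ pᵢ log₂ pᵢ,      pᵢ = Xᵢ / X,

together with a bin-width-corrected variant
`H_NDist,norm = (H_NDist + Σᵢ pᵢ log₂ wᵢ) / log₂ Σᵢ wᵢ` that is comparable
across bin sizes. Neighbors are defined either **topologically** (Voronoi
tessellation / Delaunay adjacency, open or periodic boundaries — the
default, and scale-free) or **metrically** (all agents within a radius R).
A perfect lattice scores exactly 0 bits; a structureless gas scores high.
The measure is sensitive to active phase transitions and discriminates
steady states that share the same alignment order.

The package also includes:

* a Vicsek-style **boid simulator** (cohesion / separation / alignment
  forces, unit-normalized and scaled by a steering factor `S`; constant
  speed; per-step uniform angular noise `η` in degrees; periodic box) with
  a compiled core that rebuilds the exact Voronoi neighbor graph at every
  step;
* **synthetic generators** of configurations with known order: hexagonal
  and square lattices, jittered lattices, uniform gas, Gaussian clusters,
  letter-masked packings (A–Z), and temporal stand-ins for gas-like vs
  aggregated steady states;
* experiment drivers (`noise_sweep()`, `bin_size_sweep()`,
  `letter_entropies()`, `order_series()`, `steady_state_stats()`), a
  trajectory CSV dialect for tracked coordinates, and a command-line
  interface (`inst/cli/swarmentropy.R`).

## Worked example

```r
library(swarmentropy)

# calibration: a hexagonal lattice has a single neighbor distance
lat <- hexagonal_lattice(12, 12, spacing = 10)
entropy_by_neighbor_distance(lat, bin_size = 1)
#> <entropy_result> H_NDist = 0.0000 bits, H_norm = 0.0000 (w = 1, 1 occupied bins, 864 distances)

# a uniform gas vs an aggregated (clustered) state, same N and box
gas <- uniform_gas(500, seed = 1)
entropy_by_neighbor_distance(gas, bin_size = 1)
#> <entropy_result> H_NDist = 6.5656 bits, H_norm = 0.9425 (w = 1, 121 occupied bins, 3000 distances)
cl <- gaussian_clusters(5, 100, sigma = 10, seed = 1)
entropy_by_neighbor_distance(cl, bin_size = 1)
#> <entropy_result> H_NDist = 3.8988 bits, H_norm = 0.4218 (w = 1, 90 occupied bins, 3000 distances)
```

The gas spreads its 3000 neighbor distances over 121 occupied 1-px bins
(6.57 bits, normalized 0.94 ≈ structureless); the clustered state
concentrates them (3.90 bits, normalized 0.42) — the measure separates two
states that the average velocity cannot tell apart. Letter-shaped swarm
configurations (circles on a square lattice masked by glyphs) show the
shape dependence through their edge profiles:

```r
letter_entropies(c("I", "K", "O", "S", "W"))
#>   letter n_sites h_ndist h_norm occupied_bins
#> 1      I     135   2.225 0.3000            22
#> 2      K     126   2.476 0.3236            21
#> 3      O     144   2.215 0.3327            15
#> 4      S     135   2.242 0.3241            16
#> 5      W     162   2.239 0.3055            22
```

A zero-noise boid run shows the two order parameters decoupling — the
heading field aligns (v_a → 1) hundreds of steps before the topological
structure, tracked by H_NDist, finishes reorganizing:

```r
p <- boid_params(n_boids = 100, steering = 0.1, noise = 0, seed = 1)
tr <- run_boids(p, n_steps = 30000, record_every = 100)
mean(tail(tr$va, 1000))
#> [1] 0.9998404
```

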