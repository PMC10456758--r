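#pragma once
#include <vector>
#include <utility>

// Delaunay adjacency of 2-D points, open boundary. Unique undirected pairs
// (i, j), 0-based, i < j. Coordinates are perturbed internally by a
// deterministic jitter (1e-9 of the bounding extent, fixed-seed generator) so
// that co-circular inputs (square lattices) are broken reproducibly; callers
// compute distances on the unperturbed coordinates.
std::vector<std::pair<int, int>> delaunay_pairs(const std::vector<double> &x,
                                                const std::vector<double> &y);

// Voronoi (Delaunay) adjacency on the torus [0,Lx) x [0,Ly) via a 3x3 ghost
// tiling. Pairs are canonical 0-based indices, i < j, self-pairs dropped.
std::vector<std::pair<int, int>> periodic_delaunay_pairs(
    const std::vector<double> &x, const std::vector<double> &y, double Lx,
    double Ly);
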