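#' Generate a periodic crystal layout of pseudo-protein chains
#'
#' Builds a `crystal_system`: a supercell of `n_cells` unit cells, each
#' holding `chains_per_cell` chains of `atoms_per_chain` C-alpha-like atoms.
#' Every chain is an identical copy of one compact self-avoiding
#' pseudo-chain (virtual-bond spacing 3.8 Angstrom, confined to a sphere
#' whose radius scales as a globular protein of that length), translated so
#' that chain centroids tile the unit cells. A crystal repeats the same
#' molecule in every cell, so identical copies are the faithful choice for
#' a model restricted to translational cell tiling (no space-group
#' rotations); it also makes single-chain rigid-body model curves directly
#' comparable to every chain of the lattice.
#'
#' @param cell_lengths numeric(3), unit-cell edge lengths a, b, c (Angstrom).
#' @param cell_angles numeric(3), unit-cell angles (degrees); only 90/90/90
#'   (orthorhombic-type metric) is supported.
#' @param n_cells integer(3), supercell replication along each axis.
#' @param chains_per_cell integer, chains in each unit cell.
#' @param atoms_per_chain integer (>= 2), atoms per chain.
#' @param seed integer seed; the layout is deterministic given the seed.
#' @param bond_length virtual C-alpha--C-alpha bond length (Angstrom).
#' @param confine_radius radius (Angstrom) of the sphere confining each
#'   chain; default `max(8, 3 * atoms_per_chain^(1/3))`, about 16 Angstrom
#'   for a 149-residue chain.
#'
#' @return An object of class `crystal_system`: list with elements
#'   `positions` (N x 3 reference coordinates, Angstrom), `chain_index`
#'   (integer per atom), `residue_index` (1..atoms_per_chain per chain),
#'   `chain_ids` (one label per chain), `cell_lengths`, `cell_angles`,
#'   `n_cells`, `chains_per_cell`, `atoms_per_chain`, `box` (supercell edge
#'   lengths).
#' @examples
#' sys <- crystal_layout(c(10, 10, 10), n_cells = c(1, 1, 1),
#'                       chains_per_cell = 1, atoms_per_chain = 5, seed = 1)
#' nrow(sys$positions)  # 5
#' @export
crystal_layout <- function(cell_lengths, cell_angles = c(90, 90, 90),
                           n_cells = c(1, 1, 1), chains_per_cell = 1,
                           atoms_per_chain = 2, seed = 1,
                           bond_length = 3.8, confine_radius = NULL) {
  cell_lengths <- as.numeric(cell_lengths)
  n_cells <- as.integer(n_cells)
  if (length(cell_lengths) != 3 || any(!is.finite(cell_lengths)) ||
      any(cell_lengths <= 0))
    stop_invalid("cell_lengths must be 3 positive numbers")
  if (any(abs(cell_angles - 90) > 1e-8))
    stop_invalid("only 90/90/90 cell angles are supported")
  if (length(n_cells) != 3 || any(n_cells < 1))
    stop_invalid("n_cells must be 3 positive integers")
  if (chains_per_cell < 1) stop_invalid("chains_per_cell must be >= 1")
  if (atoms_per_chain < 2) stop_invalid("atoms_per_chain must be >= 2")

  confine_radius <- confine_radius %||% max(8, 3 * atoms_per_chain^(1/3))

  chain <- withr::with_seed(seed,
    confined_walk(atoms_per_chain, bond_length, confine_radius))
  chain <- sweep(chain, 2, colMeans(chain))  # centroid at origin

  centroids <- chain_centroids(cell_lengths, n_cells, chains_per_cell)
  n_chain <- nrow(centroids)

  positions <- matrix(0, n_chain * atoms_per_chain, 3)
  for (c_i in seq_len(n_chain)) {
    idx <- ((c_i - 1L) * atoms_per_chain + 1L):(c_i * atoms_per_chain)
    positions[idx, ] <- sweep(chain, 2, centroids[c_i, ], "+")
  }

  ids <- c(LETTERS, letters, as.character(0:9))
  chain_ids <- if (n_chain <= length(ids)) ids[seq_len(n_chain)] else
    as.character(seq_len(n_chain))

  structure(list(
    positions = positions,
    chain_index = rep(seq_len(n_chain), each = atoms_per_chain),
    residue_index = rep(seq_len(atoms_per_chain), times = n_chain),
    chain_ids = chain_ids,
    cell_lengths = cell_lengths,
    cell_angles = as.numeric(cell_angles),
    n_cells = n_cells,
    chains_per_cell = as.integer(chains_per_cell),
    atoms_per_chain = as.integer(atoms_per_chain),
    box = cell_lengths * n_cells,
    seed = seed
  ), class = "crystal_system")
}

## compact self-avoiding random walk with fixed step, confined to a sphere
confined_walk <- function(n, step, radius, min_sep = 3.0, max_try = 200L) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    best <- NULL
    best_score <- -Inf
    for (k in seq_len(max_try)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1L, ] + step * u
      if (sqrt(sum(cand^2)) > radius) next
      score <- if (i > 2L) {
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        min(sqrt(rowSums(sweep(prev, 2, cand)^2)))
      } else Inf
      if (score >= min_sep) { best <- cand; break }
      if (score > best_score) { best_score <- score; best <- cand }
    }
    if (is.null(best)) {
      ## every candidate left the sphere: step back toward the center
      dir <- -xyz[i - 1L, ]
      dir <- dir / sqrt(sum(dir^2))
      best <- xyz[i - 1L, ] + step * dir
    }
    xyz[i, ] <- best
  }
  xyz
}

## fractional centroid positions tiling the cells; chains within a cell are
## spread over a parity-ordered sub-grid (tetrahedral-like for 4 per cell)
chain_centroids <- function(cell_lengths, n_cells, chains_per_cell) {
  k <- ceiling(chains_per_cell^(1/3))
  g <- expand.grid(i = 0:(k - 1), j = 0:(k - 1), l = 0:(k - 1))
  g <- g[order((g$i + g$j + g$l) %% 2, g$i, g$j, g$l), , drop = FALSE]
  frac <- as.matrix(g[seq_len(chains_per_cell), , drop = FALSE])
  frac <- (frac + 0.5) / k

  cells <- as.matrix(expand.grid(a = 0:(n_cells[1] - 1),
                                 b = 0:(n_cells[2] - 1),
                                 c = 0:(n_cells[3] - 1)))
  out <- matrix(0, nrow(cells) * chains_per_cell, 3)
  row <- 1L
  for (ci in seq_len(nrow(cells))) {
    for (pi in seq_len(chains_per_cell)) {
      out[row, ] <- (cells[ci, ] + frac[pi, ]) * cell_lengths
      row <- row + 1L
    }
  }
  out
}

#' @export
print.crystal_system <- function(x, ...) {
  cat(sprintf(
    "crystal_system: %d chains x %d atoms (%d total) in %dx%dx%d cells of %.2f x %.2f x %.2f A\n",
    length(x$chain_ids), x$atoms_per_chain, nrow(x$positions),
    x$n_cells[1], x$n_cells[2], x$n_cells[3],
    x$cell_lengths[1], x$cell_lengths[2], x$cell_lengths[3]))
  invisible(x)
}
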