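# shared fixtures, memoized so expensive ensembles are built once per run

.fixtures <- new.env(parent = emptyenv())

with_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), .fixtures)
  get(name, envir = .fixtures)
}

## 8 chains x 38 atoms = 304 atoms in a 48 A cubic supercell; the layout
## used for the liquid-like-motion recovery analyses
recovery_layout <- function() {
  with_fixture("recovery_layout",
    crystal_layout(c(24, 24, 24), n_cells = c(2, 2, 2), chains_per_cell = 1,
                   atoms_per_chain = 38, seed = 2))
}

## a compact random blob standing in for a single globular chain
blob_coords <- function(n = 40, sd = 7, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * 3, sd = sd), n, 3))
}

## brute-force traced covariance: explicit double loop over atoms/frames
brute_traced_covariance <- function(coords) {
  f <- dim(coords)[1]; n <- dim(coords)[2]
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (d in 1:3) {
      xi <- coords[, i, d]; xj <- coords[, j, d]
      acc <- acc + mean((xi - mean(xi)) * (xj - mean(xj)))
    }
    out[i, j] <- acc
  }
  out
}

## brute-force structure factor at one grid point
brute_sf <- function(coords, hkl, cell, f = 1) {
  s <- hkl / cell
  sum(f * exp(2i * pi * as.vector(coords %*% s)))
}

## fit a binned curve from an ensemble without any alignment, on given or
## data-derived edges; returns the exp_fit and the edges used
fit_llm_curve <- function(ens, dist_ref, edges = NULL) {
  tc <- traced_covariance(ens)
  b <- bin_covariance(tc, dist_ref, n_bins = 50, bin_edges = edges)
  list(fit = fit_exponential(b), edges = b$bin_edges, curve = b)
}

## frame-block standard errors of fitted (a, gamma): split the ensemble
## into n_blocks contiguous blocks, fit each, SD/sqrt(n_blocks)
block_fit_se <- function(ens, dist_ref, edges, n_blocks = 10) {
  f <- dim(ens$coords)[1]
  per <- f %/% n_blocks
  pa <- pg <- numeric(n_blocks)
  for (b_i in seq_len(n_blocks)) {
    sub <- ens
    sub$coords <- ens$coords[((b_i - 1) * per + 1):(b_i * per), , ,
                             drop = FALSE]
    fb <- fit_llm_curve(sub, dist_ref, edges)$fit
    pa[b_i] <- fb$a; pg[b_i] <- fb$gamma
  }
  c(a = sd(pa) / sqrt(n_blocks), gamma = sd(pg) / sqrt(n_blocks))
}

## per-bin frame-block means for honest bin-mean standard errors
block_bin_means <- function(ens, dist_ref, edges, n_blocks = 10) {
  f <- dim(ens$coords)[1]
  per <- f %/% n_blocks
  t(vapply(seq_len(n_blocks), function(b_i) {
    sub <- ens
    sub$coords <- ens$coords[((b_i - 1) * per + 1):(b_i * per), , ,
                             drop = FALSE]
    bin_covariance(traced_covariance(sub), dist_ref, bin_edges = edges)$mean
  }, numeric(length(edges) - 1)))
}
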