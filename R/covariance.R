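#' Remove global translations from an ensemble
#'
#' Per frame, a single rigid translation is removed so that the centroid of
#' the fit group matches its centroid in the reference frame. No rotation is
#' applied (the supercell as a whole has no rotational freedom in a
#' crystal).
#'
#' @param ens a `coord_ensemble`.
#' @param reference_frame index of the reference frame (default 1).
#' @param fit_atoms integer indices of the fit group (default: all atoms).
#' @return the translationally aligned `coord_ensemble`.
#' @export
align_translational <- function(ens, reference_frame = 1L, fit_atoms = NULL) {
  stopifnot(inherits(ens, "coord_ensemble"))
  f <- n_frames(ens)
  if (reference_frame < 1 || reference_frame > f)
    stop_invalid("reference_frame %d outside 1..%d", reference_frame, f)
  fit_atoms <- fit_atoms %||% seq_len(n_atoms(ens))
  if (length(fit_atoms) == 0) stop_invalid("empty fit group")

  ref_cen <- colMeans(ens$coords[reference_frame, fit_atoms, , drop = FALSE][1, , , drop = TRUE])
  for (k in seq_len(f)) {
    cen <- colMeans(ens$coords[k, fit_atoms, , drop = FALSE][1, , , drop = TRUE])
    shift <- ref_cen - cen
    for (d in 1:3) ens$coords[k, , d] <- ens$coords[k, , d] + shift[d]
  }
  ens$metadata$aligned <- list(reference_frame = reference_frame)
  ens
}

#' Trace-reduced displacement covariance matrix
#'
#' For every atom pair (i, j) computes the trace of the 3 x 3 Cartesian
#' displacement covariance block,
#' `C_ij = sum_d mean_f[(x_id - <x_id>)(x_jd - <x_jd>)]`,
#' with population normalization (divide by the number of frames). The
#' diagonal is each atom's mean squared deviation. The full `3N x 3N`
#' covariance matrix is never materialized; its dimension is reported in
#' the result for bookkeeping.
#'
#' @param ens a `coord_ensemble` with at least 2 frames.
#' @return object of class `traced_covariance`: list with `matrix`
#'   (N x N, Angstrom^2), `mean_coords` (N x 3 time averages), `n_frames`,
#'   `full_dim` (= 3N), `chain_index`, `residue_index`.
#' @export
traced_covariance <- function(ens) {
  stopifnot(inherits(ens, "coord_ensemble"))
  f <- n_frames(ens)
  if (f < 2) stop_invalid("need at least 2 frames, got %d", f)
  bad <- which(!is.finite(ens$coords), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_invalid("non-finite coordinate at frame %d, atom %d",
                 bad[1, 1], bad[1, 2])
  n <- n_atoms(ens)
  cmat <- matrix(0, n, n)
  mean_coords <- matrix(0, n, 3)
  for (d in 1:3) {
    x <- ens$coords[, , d, drop = FALSE]
    dim(x) <- c(f, n)
    mu <- colMeans(x)
    mean_coords[, d] <- mu
    xc <- sweep(x, 2, mu)
    cmat <- cmat + crossprod(xc) / f
  }
  structure(list(matrix = cmat, mean_coords = mean_coords,
                 n_frames = f, full_dim = 3L * n,
                 chain_index = ens$chain_index,
                 residue_index = ens$residue_index,
                 box = ens$box),
            class = "traced_covariance")
}

#' @export
print.traced_covariance <- function(x, ...) {
  n <- nrow(x$matrix)
  cat(sprintf(
    "traced_covariance: %d x %d (full covariance space %d x %d), %d frames\n",
    n, n, x$full_dim, x$full_dim, x$n_frames))
  cat(sprintf("  mean MSD (diagonal): %.4g A^2\n", mean(diag(x$matrix))))
  invisible(x)
}

#' Pairwise distances between time-averaged positions
#'
#' Euclidean distances; with a periodic `box`, the minimum-image convention
#' is used, bounding distances by half the box length per axis.
#'
#' @param mean_coords N x 3 coordinate matrix (Angstrom).
#' @param box numeric(3) periodic box lengths, or NULL for open boundaries.
#' @return N x N symmetric distance matrix (Angstrom).
#' @export
pairwise_distances <- function(mean_coords, box = NULL) {
  mean_coords <- as.matrix(mean_coords)
  if (any(!is.finite(mean_coords))) stop_invalid("non-finite coordinates")
  if (is.null(box)) {
    d2 <- as.matrix(stats::dist(mean_coords))^2
  } else {
    stopifnot(length(box) == 3L)
    d2 <- 0
    for (d in 1:3) {
      dd <- outer(mean_coords[, d], mean_coords[, d], "-")
      dd <- min_image(dd, box[d])
      d2 <- d2 + dd^2
    }
  }
  sqrt(d2)
}

#' Partition atom pairs into intraprotein and interprotein subsets
#'
#' Returns disjoint, exhaustive masks over unordered off-diagonal atom
#' pairs: `intra` selects pairs within one chain, `inter` pairs crossing a
#' chain boundary. An optional residue exclusion list (e.g. flexible
#' termini) removes atoms from both masks first.
#'
#' @param chain_index integer chain label per atom.
#' @param residue_index integer residue label per atom (needed when
#'   `exclude_residues` is given).
#' @param exclude_residues integer residue indices excluded from the
#'   analysis (applied per chain).
#' @param exclude_atoms integer atom indices excluded directly.
#' @return list with `intra`, `inter` (N x N logical, symmetric, diagonal
#'   FALSE) and `keep` (logical per atom).
#' @export
classify_pairs <- function(chain_index, residue_index = NULL,
                           exclude_residues = NULL, exclude_atoms = NULL) {
  chain_index <- as.integer(chain_index)
  n <- length(chain_index)
  keep <- rep(TRUE, n)
  if (!is.null(exclude_residues)) {
    if (is.null(residue_index))
      stop_invalid("residue_index needed to apply exclude_residues")
    keep <- keep & !(residue_index %in% exclude_residues)
  }
  if (!is.null(exclude_atoms)) keep[exclude_atoms] <- FALSE

  same <- outer(chain_index, chain_index, "==")
  kept <- outer(keep, keep, "&")
  offdiag <- !diag(TRUE, n)
  list(intra = same & kept & offdiag,
       inter = !same & kept,
       keep = keep)
}

#' Terminal-residue exclusion list
#'
#' Convenience builder for the default "stable core" selection: drop the
#' first `n_term` and last `c_term` residues of an `atoms_per_chain`-long
#' chain (defaults mirror a nuclease construct whose first five and last
#' eight residues are unresolved in the crystal).
#'
#' @param atoms_per_chain chain length.
#' @param n_term,c_term number of residues dropped at each end.
#' @return integer residue indices to exclude.
#' @export
terminal_exclusions <- function(atoms_per_chain, n_term = 5L, c_term = 8L) {
  stopifnot(n_term >= 0, c_term >= 0)
  idx <- c(seq_len(n_term),
           if (c_term > 0) (atoms_per_chain - c_term + 1L):atoms_per_chain)
  unique(idx[idx >= 1 & idx <= atoms_per_chain])
}

#' Bin pair covariances by inter-atomic distance
#'
#' Divides the distance range of the selected pairs into `n_bins` even bins
#' and reports, per bin, the mean covariance, its standard error
#' (sample SD / sqrt(count)) and the pair count. Empty bins are kept and
#' flagged, never silently dropped.
#'
#' @param cov a `traced_covariance` (or a plain symmetric matrix).
#' @param distances N x N distance matrix matching `cov`.
#' @param mask N x N logical selecting pairs (diagonal ignored); default:
#'   all off-diagonal pairs.
#' @param n_bins number of even bins (default 50).
#' @param bin_edges optional explicit edges (length `n_bins + 1`),
#'   overriding the `[min, max]` span of the selected distances.
#' @param subset_label label stored with the curve
#'   (`"all"`, `"intra"`, `"inter"`, ...).
#' @return object of class `binned_covariance`: list with `bin_edges`,
#'   `bin_center`, `mean`, `stderr`, `count`, `empty`, `subset_label`.
#' @export
bin_covariance <- function(cov, distances, mask = NULL, n_bins = 50L,
                           bin_edges = NULL, subset_label = "all") {
  cmat <- if (inherits(cov, "traced_covariance")) cov$matrix else cov
  stopifnot(is.matrix(cmat), all(dim(cmat) == dim(distances)))
  n <- nrow(cmat)
  sel <- upper.tri(cmat)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(cmat)))
    sel <- sel & mask
  }
  if (!any(sel)) stop_invalid("empty pair selection")

  d <- distances[sel]
  v <- cmat[sel]
  if (is.null(bin_edges)) {
    bin_edges <- seq(min(d), max(d), length.out = n_bins + 1L)
  } else {
    n_bins <- length(bin_edges) - 1L
  }
  idx <- findInterval(d, bin_edges, rightmost.closed = TRUE, all.inside = TRUE)
  idx[d < bin_edges[1] | d > bin_edges[n_bins + 1L]] <- NA_integer_
  ok <- !is.na(idx)
  fac <- factor(idx[ok], levels = seq_len(n_bins))
  count <- as.integer(table(fac))
  sums <- vapply(split(v[ok], fac), sum, numeric(1))
  mean_b <- ifelse(count > 0, sums / count, NA_real_)
  sd_b <- vapply(split(v[ok], fac), function(z)
    if (length(z) >= 2) sd(z) else NA_real_, numeric(1))
  stderr <- ifelse(count >= 2, sd_b / sqrt(count), NA_real_)

  structure(list(bin_edges = bin_edges,
                 bin_center = (bin_edges[-1] + bin_edges[-(n_bins + 1L)]) / 2,
                 mean = unname(mean_b), stderr = unname(stderr),
                 count = count, empty = count == 0L,
                 subset_label = subset_label),
            class = "binned_covariance")
}

#' @export
print.binned_covariance <- function(x, ...) {
  cat(sprintf(
    "binned_covariance [%s]: %d bins over %.2f-%.2f A, %d pairs (%d empty bins)\n",
    x$subset_label, length(x$bin_center),
    min(x$bin_edges), max(x$bin_edges), sum(x$count), sum(x$empty)))
  invisible(x)
}

#' @export
as.data.frame.binned_covariance <- function(x, ...) {
  data.frame(r_center = x$bin_center, mean = x$mean,
             stderr = x$stderr, count = x$count)
}

#' Subtract one binned curve from another
#'
#' Per-bin mean difference (e.g. trajectory curve minus rigid-body model
#' curve), with standard errors propagated in quadrature and counts taken
#' as the per-bin minimum. The two curves must share identical bin edges;
#' no silent rebinning is performed.
#'
#' @param md the minuend `binned_covariance` (e.g. trajectory analysis).
#' @param model the subtrahend `binned_covariance` (e.g. RBM model).
#' @return a `binned_covariance` labelled `"<md> - <model>"`.
#' @export
subtract_curves <- function(md, model) {
  stopifnot(inherits(md, "binned_covariance"),
            inherits(model, "binned_covariance"))
  if (length(md$bin_edges) != length(model$bin_edges) ||
      !isTRUE(all.equal(md$bin_edges, model$bin_edges, tolerance = 1e-10)))
    stop_invalid("bin edges differ; rebin the model curve on the data's edges")
  structure(list(bin_edges = md$bin_edges, bin_center = md$bin_center,
                 mean = md$mean - model$mean,
                 stderr = sqrt(md$stderr^2 + model$stderr^2),
                 count = pmin(md$count, model$count),
                 empty = md$empty | model$empty,
                 subset_label = paste(md$subset_label, "-", model$subset_label)),
            class = "binned_covariance")
}
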