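#' Rigid-body motion parameters
#'
#' @param sd_angle SD of each of the three sampled rotation angles (degrees).
#' @param sd_trans SD of each translation component (Angstrom).
#' @param n_frames number of frames (default 5000, the scale at which the
#'   model curve's standard errors become negligible against typical
#'   trajectory curves).
#' @param seed integer seed.
#' @return object of class `rbm_params`.
#' @export
rbm_params <- function(sd_angle, sd_trans, n_frames = 5000L, seed = 1L) {
  if (sd_angle < 0) stop_invalid("sd_angle must be >= 0")
  if (sd_trans < 0) stop_invalid("sd_trans must be >= 0")
  if (n_frames < 1) stop_invalid("n_frames must be >= 1")
  structure(list(sd_angle = sd_angle, sd_trans = sd_trans,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "rbm_params")
}

## rotation matrix from extrinsic X-Y-Z (Tait-Bryan) angles in radians:
## R = Rz(c) %*% Ry(b) %*% Rx(a). For small angles the rotation vector is
## (a, b, c), i.e. isotropic when the three angles share one SD - the
## property the small-angle covariance closed form 2*sigma^2*(r_i . r_j)
## relies on (Z-Y-Z conventions are anisotropic at the same order).
rotation_xyz <- function(ang) {
  ca <- cos(ang[1]); sa <- sin(ang[1])
  cb <- cos(ang[2]); sb <- sin(ang[2])
  cc <- cos(ang[3]); sc <- sin(ang[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Generate a rigid-body-motions ensemble of a single chain
#'
#' The chain is centered on its centroid, then each frame applies a random
#' rotation (three angles drawn independently from N(0, sd_angle), applied
#' about the centroid) followed by a random translation (components drawn
#' from N(0, sd_trans)). Rotation angles are extrinsic X-Y-Z (Tait-Bryan);
#' the convention is recorded in the metadata.
#'
#' @param coords N x 3 matrix of single-chain coordinates (Angstrom),
#'   N >= 2.
#' @param params an `rbm_params` object.
#' @param exclude optional integer atom indices to drop before generating
#'   (e.g. flexible termini that cannot be considered rigid).
#' @return a `coord_ensemble` of the (possibly reduced) chain.
#' @export
generate_rbm_ensemble <- function(coords, params, exclude = NULL) {
  stopifnot(inherits(params, "rbm_params"))
  coords <- as.matrix(coords)
  if (!is.null(exclude) && length(exclude))
    coords <- coords[-exclude, , drop = FALSE]
  if (nrow(coords) < 2)
    stop_invalid("at least 2 atoms are required (covariance undefined)")

  x0 <- sweep(coords, 2, colMeans(coords))  # centered on the origin
  n <- nrow(x0)
  f <- params$n_frames
  out <- array(0, c(f, n, 3L))
  withr::with_seed(params$seed, {
    for (k in seq_len(f)) {
      rot <- rotation_xyz(rnorm(3, 0, params$sd_angle) * pi / 180)
      tr <- rnorm(3, 0, params$sd_trans)
      out[k, , ] <- sweep(x0 %*% t(rot), 2, tr, "+")
    }
  })
  coord_ensemble(out, chain_index = rep(1L, n),
                 residue_index = seq_len(n),
                 metadata = list(generator = "rbm",
                                 sd_angle = params$sd_angle,
                                 sd_trans = params$sd_trans,
                                 euler_convention = "extrinsic XYZ (Tait-Bryan)",
                                 seed = params$seed))
}

#' Match rigid-body parameters to a target covariance curve
#'
#' Least-squares estimate of `(sd_angle, sd_trans)` from the long-range
#' part of a binned covariance curve (default `r > 20` Angstrom, where
#' rigid-body behavior dominates trajectory curves). Uses the small-angle
#' expectation of the rigid-body covariance,
#' `C_ij = 2*sigma_a^2*(r_i . r_j) + 3*sigma_t^2` with `sigma_a` in
#' radians, which is linear in the two squared amplitudes: the fit is an
#' exact two-basis linear regression of the target bin means on the
#' binned `2*(r_i . r_j)` curve and a constant, with negative solutions
#' clipped to zero. Accurate for angular SDs up to a couple of degrees,
#' and a reproducible replacement for matching the model to a trajectory
#' curve by eye.
#'
#' @param target a `binned_covariance` (e.g. an intraprotein trajectory
#'   curve).
#' @param coords N x 3 single-chain coordinates matching the target's
#'   geometry.
#' @param exclude optional atom indices dropped first.
#' @param r_min bins with centers above this enter the fit (Angstrom).
#' @return list with `sd_angle` (degrees), `sd_trans` (Angstrom),
#'   `rss`, and `n_bins_used`.
#' @export
fit_rbm_params <- function(target, coords, exclude = NULL, r_min = 20) {
  stopifnot(inherits(target, "binned_covariance"))
  coords <- as.matrix(coords)
  if (!is.null(exclude) && length(exclude))
    coords <- coords[-exclude, , drop = FALSE]
  x0 <- sweep(coords, 2, colMeans(coords))
  gram <- 2 * (x0 %*% t(x0))                 # basis for sigma_a^2
  d <- pairwise_distances(x0)
  basis <- bin_covariance(gram, d, bin_edges = target$bin_edges,
                          subset_label = "gram")
  use <- !target$empty & !basis$empty & target$bin_center > r_min &
    is.finite(target$mean)
  if (sum(use) < 2)
    stop_invalid("need at least 2 usable bins beyond r_min = %g", r_min)
  X <- cbind(gram = basis$mean[use], const = 3)
  fit <- stats::lm.fit(X, target$mean[use])
  beta <- pmax(coef(fit), 0)                 # squared amplitudes
  pred <- X %*% beta
  list(sd_angle = sqrt(beta[["gram"]]) * 180 / pi,
       sd_trans = sqrt(beta[["const"]]),
       rss = sum((target$mean[use] - pred)^2),
       n_bins_used = sum(use))
}

#' Covariance-versus-distance curve of a rigid-body-motions model
#'
#' Generates a rigid-body ensemble of the chain, computes its traced
#' displacement covariance (no translational re-alignment is applied: the
#' rigid motion itself is the signal), and bins the off-diagonal pair
#' covariances by the distance between time-averaged positions. Passing the
#' `bin_edges` of a trajectory analysis puts the model curve on the same
#' binning scheme so the two are subtractable with [subtract_curves()].
#'
#' @inheritParams generate_rbm_ensemble
#' @param bin_edges optional bin edges (Angstrom) to reuse; default spans
#'   the model's own distance range in `n_bins` even bins.
#' @param n_bins number of even bins when `bin_edges` is NULL.
#' @return a `binned_covariance` with subset label `"rbm"`.
#' @export
rbm_covariance_curve <- function(params, coords, exclude = NULL,
                                 bin_edges = NULL, n_bins = 50L) {
  ens <- generate_rbm_ensemble(coords, params, exclude = exclude)
  tc <- traced_covariance(ens)
  d <- pairwise_distances(tc$mean_coords)
  bin_covariance(tc, d, n_bins = n_bins, bin_edges = bin_edges,
                 subset_label = "rbm")
}
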