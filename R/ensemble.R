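#' Construct a coordinate ensemble
#'
#' Container for F frames of N atoms with chain/residue labels and an
#' optional periodic box. Frames are stored as an `F x N x 3` array in
#' Angstrom.
#'
#' @param coords numeric array `F x N x 3`, or an `N x 3` matrix for a
#'   single frame.
#' @param chain_index integer per atom.
#' @param residue_index integer per atom (defaults to 1..N).
#' @param box numeric(3) periodic box edge lengths (Angstrom), or NULL.
#' @param metadata list of provenance fields (generator parameters, seeds).
#' @return object of class `coord_ensemble`.
#' @export
coord_ensemble <- function(coords, chain_index, residue_index = NULL,
                           box = NULL, metadata = list()) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_atoms <- dim(coords)[2]
  chain_index <- as.integer(chain_index)
  if (length(chain_index) != n_atoms)
    stop_invalid("chain_index must have one entry per atom (%d)", n_atoms)
  residue_index <- as.integer(residue_index %||% seq_len(n_atoms))
  if (length(residue_index) != n_atoms)
    stop_invalid("residue_index must have one entry per atom (%d)", n_atoms)
  if (!is.null(box)) stopifnot(length(box) == 3L, all(box > 0))
  structure(list(coords = coords, chain_index = chain_index,
                 residue_index = residue_index, box = box,
                 metadata = metadata),
            class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("coord_ensemble: %d frames x %d atoms (%d chains)%s\n",
              d[1], d[2], length(unique(x$chain_index)),
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

n_frames <- function(ens) dim(ens$coords)[1]
n_atoms <- function(ens) dim(ens$coords)[2]

#' Liquid-like motion field parameters
#'
#' Parameters of an exponentially correlated Gaussian displacement field:
#' the traced displacement covariance between atoms at distance `r` is
#' `amplitude * exp(-r / gamma)`, so `amplitude` is the per-atom mean
#' squared displacement (Angstrom^2) and `gamma` the correlation length
#' (Angstrom).
#'
#' @param amplitude traced covariance at contact (Angstrom^2), >= 0.
#' @param gamma correlation length (Angstrom), > 0.
#' @param n_frames number of frames to generate.
#' @param seed integer seed.
#' @return object of class `llm_params`.
#' @export
llm_params <- function(amplitude, gamma, n_frames = 1000L, seed = 1L) {
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  if (gamma <= 0) stop_invalid("gamma must be > 0")
  if (n_frames < 1) stop_invalid("n_frames must be >= 1")
  structure(list(amplitude = amplitude, gamma = gamma,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "llm_params")
}

#' Generate a liquid-like-motion ensemble on a crystal layout
#'
#' Samples a Gaussian random displacement field whose per-coordinate
#' covariance between atoms i and j is `(amplitude/3) * exp(-r_ij/gamma)`,
#' so that the traced (x+y+z) covariance equals
#' `amplitude * exp(-r_ij/gamma)`. The x, y, z components are sampled
#' independently from the same kernel. Distances use the minimum-image
#' convention in the supercell box, making the field consistent with the
#' periodic boundary.
#'
#' The kernel is factorized by Cholesky decomposition after adding a
#' diagonal jitter; for correlation lengths approaching the half-box the
#' minimum-image kernel can be numerically non-positive-definite, in which
#' case an error is raised naming the jitter used.
#'
#' @param system a `crystal_system` from [crystal_layout()].
#' @param params an `llm_params` object.
#' @param jitter diagonal jitter (Angstrom^2) added before factorization.
#' @return a `coord_ensemble` with `params$n_frames` frames.
#' @export
generate_llm_ensemble <- function(system, params, jitter = 1e-8) {
  stopifnot(inherits(system, "crystal_system"), inherits(params, "llm_params"))
  ref <- system$positions
  n <- nrow(ref)
  f <- params$n_frames

  if (params$amplitude == 0) {
    coords <- array(0, c(f, n, 3L))
    for (k in seq_len(f)) coords[k, , ] <- ref
  } else {
    r <- pairwise_distances(ref, box = system$box)
    kern <- (params$amplitude / 3) * exp(-r / params$gamma)
    ch <- tryCatch(
      chol(kern + diag(jitter, n)),
      error = function(e) stop_invalid(
        "LLM kernel not positive definite after diagonal jitter %g A^2 (gamma = %g A may be too large for the box); %s",
        jitter, params$gamma, conditionMessage(e)))
    coords <- array(0, c(f, n, 3L))
    withr::with_seed(params$seed, {
      for (d in 1:3) {
        z <- matrix(rnorm(f * n), f, n)
        disp <- z %*% ch                      # rows ~ N(0, kern)
        coords[, , d] <- sweep(disp, 2, ref[, d], "+")
      }
    })
  }

  coord_ensemble(coords, system$chain_index, system$residue_index,
                 box = system$box,
                 metadata = list(generator = "llm",
                                 amplitude = params$amplitude,
                                 gamma = params$gamma,
                                 jitter = jitter, seed = params$seed))
}

#' Composite ensemble specification
#'
#' Combines an optional LLM field, optional per-chain rigid-body motions,
#' and optional uncorrelated white noise into one displacement model.
#'
#' @param llm an `llm_params` object or NULL.
#' @param rbm an `rbm_params` object (see [rbm_params()]) or NULL.
#' @param white_noise_sd per-coordinate SD of uncorrelated noise (Angstrom).
#' @param n_frames number of frames.
#' @param seed master seed; component seeds are derived from it.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(llm = NULL, rbm = NULL, white_noise_sd = 0,
                          n_frames = 1000L, seed = 1L) {
  if (!is.null(llm)) stopifnot(inherits(llm, "llm_params"))
  if (!is.null(rbm)) stopifnot(inherits(rbm, "rbm_params"))
  if (white_noise_sd < 0) stop_invalid("white_noise_sd must be >= 0")
  structure(list(llm = llm, rbm = rbm, white_noise_sd = white_noise_sd,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a composite ensemble: rigid motions + LLM field + noise
#'
#' Displacement of each frame is the independent superposition of (i) a
#' per-chain rigid rotation about the chain centroid followed by a rigid
#' translation, (ii) a liquid-like Gaussian displacement field, and (iii)
#' per-coordinate white noise. Component seeds are derived from
#' `spec$seed`; the generating parameters are recorded in the ensemble
#' metadata.
#'
#' @param system a `crystal_system`.
#' @param spec an `ensemble_spec`.
#' @return a `coord_ensemble`.
#' @export
generate_composite_ensemble <- function(system, spec) {
  stopifnot(inherits(system, "crystal_system"), inherits(spec, "ensemble_spec"))
  ref <- system$positions
  n <- nrow(ref)
  f <- spec$n_frames
  seeds <- derive_seeds(spec$seed, 3L)

  if (is.null(spec$llm) && is.null(spec$rbm) && spec$white_noise_sd == 0)
    warning("no displacement component given: ensemble is constant")

  coords <- array(0, c(f, n, 3L))
  for (k in seq_len(f)) coords[k, , ] <- ref

  if (!is.null(spec$rbm)) {
    p <- spec$rbm
    chains <- unique(system$chain_index)
    withr::with_seed(seeds[1], {
      for (c_i in chains) {
        idx <- which(system$chain_index == c_i)
        xc <- ref[idx, , drop = FALSE]
        cen <- colMeans(xc)
        x0 <- sweep(xc, 2, cen)
        for (k in seq_len(f)) {
          rot <- rotation_xyz(rnorm(3, 0, p$sd_angle) * pi / 180)
          tr <- rnorm(3, 0, p$sd_trans)
          moved <- x0 %*% t(rot)
          coords[k, idx, ] <- coords[k, idx, ] - xc +
            sweep(moved, 2, cen + tr, "+")
        }
      }
    })
  }

  if (!is.null(spec$llm)) {
    lp <- llm_params(spec$llm$amplitude, spec$llm$gamma,
                     n_frames = f, seed = seeds[2])
    llm_ens <- generate_llm_ensemble(system, lp)
    for (d in 1:3)
      coords[, , d] <- coords[, , d] +
        sweep(llm_ens$coords[, , d], 2, ref[, d])
  }

  if (spec$white_noise_sd > 0) {
    withr::with_seed(seeds[3],
      coords <- coords + array(rnorm(length(coords), 0, spec$white_noise_sd),
                               dim(coords)))
  }

  coord_ensemble(coords, system$chain_index, system$residue_index,
                 box = system$box,
                 metadata = list(
                   generator = "composite",
                   llm = spec$llm, rbm = spec$rbm,
                   white_noise_sd = spec$white_noise_sd,
                   euler_convention = "extrinsic XYZ (Tait-Bryan)",
                   seed = spec$seed))
}
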