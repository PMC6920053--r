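toy_lattice <- function(cell = c(10, 10, 10), d_min = 2, sf = 2)
  lattice_spec(cell, d_min, sf)

random_lattice <- function(seed = 1, ...) {
  lat <- toy_lattice(...)
  lat$I <- withr::with_seed(seed,
    array(runif(length(lat$I)), dim(lat$I)))
  lat
}

test_that("structure factors follow the phase conventions and the brute-force sum", {
  lat <- toy_lattice()
  ## single atom at the origin with unit form factor: F = 1 everywhere
  sf1 <- structure_factor_grid(matrix(c(0, 0, 0), 1, 3), lat)
  expect_equal(max(Mod(sf1$I - 1)), 0, tolerance = 1e-12)

  ## atom at fractional (0.5, 0, 0): F alternates with the parity of h
  sf2 <- structure_factor_grid(matrix(c(5, 0, 0), 1, 3), lat)
  hkl <- crystdyn:::lattice_hkl(lat)
  integer_h <- abs(hkl[, 1] - round(hkl[, 1])) < 1e-9
  expected <- exp(1i * pi * hkl[integer_h, 1])
  expect_equal(as.vector(sf2$I)[integer_h], expected, tolerance = 1e-10)

  ## random 10-atom frame equals the direct per-point summation
  coords <- withr::with_seed(2, matrix(runif(30, 0, 10), 10, 3))
  sf3 <- structure_factor_grid(coords, lat)
  for (m in c(1, 57, 1234, length(lat$I))) {
    fb <- brute_sf(coords, hkl[m, ], lat$cell)
    expect_lt(Mod(as.vector(sf3$I)[m] - fb) / Mod(fb), 1e-10)
  }
})

test_that("Guinier diffuse intensity matches the single-atom Gaussian closed form", {
  lat <- toy_lattice()
  sigma <- 0.3
  n_f <- 400
  coords <- array(0, c(n_f, 1, 3))
  coords[, 1, ] <- withr::with_seed(2, matrix(rnorm(3 * n_f, 5, sigma), n_f, 3))
  ens <- coord_ensemble(coords, 1L)
  id <- guinier_diffuse(ens, lat, "coherent")
  s2 <- crystdyn:::lattice_smag(lat)^2
  pred <- 1 - exp(-4 * pi^2 * s2 * sigma^2)
  ok <- lat$mask
  ## sampling error of a variance at 400 frames is ~ pred * sqrt(2/F)
  expect_lt(max(abs(id$I[ok] - pred[ok])), 5 * max(pred) * sqrt(2 / n_f))
})

test_that("single-frame ensembles give a zero lattice with a warning", {
  lat <- toy_lattice()
  ens <- coord_ensemble(matrix(1:6, 2, 3), c(1L, 1L))
  expect_warning(id <- guinier_diffuse(ens, lat), "single frame")
  expect_equal(max(id$I), 0)
})

test_that("coherent accumulation dominates incoherent pointwise", {
  lat <- toy_lattice(d_min = 2.5)
  set.seed(3)
  n_f <- 48
  ## drifting 4-atom ensemble so chunk means differ
  base <- matrix(runif(12, 2, 8), 4, 3)
  coords <- array(0, c(n_f, 4, 3))
  for (k in seq_len(n_f))
    coords[k, , ] <- base + 0.02 * k + matrix(rnorm(12, 0, 0.2), 4, 3)
  ens <- coord_ensemble(coords, rep(1L, 4))
  coh <- guinier_diffuse(ens, lat, "coherent")
  inc <- guinier_diffuse(ens, lat, "incoherent", n_chunks = 4)
  expect_true(all(coh$I - inc$I >= -1e-10 * max(coh$I)))
})

test_that("diffuse intensity decomposes the total intensity exactly", {
  ## mean(I_d + |<F>|^2) = mean(<|F|^2>): Guinier's variance identity
  lat <- toy_lattice(d_min = 2.5)
  set.seed(4)
  n_f <- 20
  coords <- array(runif(n_f * 5 * 3, 0, 10), c(n_f, 5, 3))
  ens <- coord_ensemble(coords, rep(1L, 5))
  id <- guinier_diffuse(ens, lat, "coherent")
  fmat <- vapply(seq_len(n_f), function(k)
    structure_factor_grid(coords[k, , ], lat)$I,
    complex(length(lat$I)))
  mean_f2 <- rowMeans(Mod(fmat)^2)
  f_mean2 <- Mod(rowMeans(fmat))^2
  expect_equal(mean(as.vector(id$I) + f_mean2), mean(mean_f2),
               tolerance = 1e-10)
})

test_that("Laue symmetrization is a projection onto group-invariant lattices", {
  lat <- random_lattice(5)
  s1 <- symmetrize_laue(lat, "P4")
  s2 <- symmetrize_laue(s1, "P4")
  expect_equal(s1$I, s2$I, tolerance = 1e-12)

  ## symmetric input is unchanged
  expect_equal(symmetrize_laue(s1, "P4")$I, s1$I, tolerance = 1e-12)

  ## orbit oracle: all present orbit members share one value afterwards
  hkl <- crystdyn:::lattice_hkl(lat)
  ops <- crystdyn:::laue_ops("P4")
  valid_idx <- which(as.vector(lat$mask))
  for (m in valid_idx[c(10, 333, 2000)]) {
    orbit <- unique(t(vapply(ops, function(o)
      as.vector(o %*% hkl[m, ]), numeric(3))))
    vals <- apply(orbit, 1, function(p) {
      i <- which(abs(hkl[, 1] - p[1]) < 1e-9 & abs(hkl[, 2] - p[2]) < 1e-9 &
                 abs(hkl[, 3] - p[3]) < 1e-9)
      if (length(i) == 1 && s1$mask[i]) as.vector(s1$I)[i] else NA_real_
    })
    vals <- vals[!is.na(vals)]
    expect_lt(diff(range(vals)), 1e-12)
  }

  ## Friedel symmetry holds after symmetrization (P1 too)
  p1 <- symmetrize_laue(random_lattice(6), "P1")
  arr <- p1$I
  rev_arr <- arr[rev(seq_len(dim(arr)[1])), rev(seq_len(dim(arr)[2])),
                 rev(seq_len(dim(arr)[3]))]
  ## masked points keep their input values; compare the valid region
  expect_equal(arr[p1$mask], rev_arr[p1$mask], tolerance = 1e-12)
})

test_that("anisotropic extraction removes every radial component", {
  lat <- random_lattice(7)
  sm <- crystdyn:::lattice_smag(lat)

  ## purely affine-radial input -> zero output
  lr <- lat; lr$I <- array(2 + 3 * sm, dim(lat$I))
  out <- anisotropic_component(lr)
  expect_lt(max(abs(out$I[out$mask])), 1e-10)

  ## adding an affine radial function leaves the output unchanged
  a1 <- anisotropic_component(lat)
  shifted <- lat; shifted$I <- lat$I + array(1.5 - 0.7 * sm, dim(lat$I))
  a2 <- anisotropic_component(shifted)
  expect_equal(a1$I[a1$mask], a2$I[a2$mask], tolerance = 1e-10)

  ## output shell means vanish
  valid <- as.vector(a1$mask)
  s <- as.vector(sm)[valid]
  v <- as.vector(a1$I)[valid]
  edges <- seq(min(s), max(s), length.out = 26)
  shell <- findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE)
  means <- tapply(v, shell, mean)
  expect_lt(max(abs(means)), 1e-6 * max(abs(as.vector(lat$I))))
})

test_that("Bragg and resolution culling matches direct enumeration", {
  lat <- random_lattice(8, cell = c(8, 8, 8), d_min = 2.5)
  culled <- cull_bragg_and_resolution(lat, bragg_radius = 0.25)
  hkl <- crystdyn:::lattice_hkl(lat)
  sm <- as.vector(crystdyn:::lattice_smag(lat))
  dbragg <- sqrt(rowSums((hkl - round(hkl))^2))
  expected <- as.vector(lat$mask) & sm <= 1 / 2.5 & dbragg > 0.25
  expect_equal(as.vector(culled$mask), expected)

  ## exact Bragg points excluded, half-integer points kept
  on_bragg <- which(dbragg < 1e-9 & sm <= 1 / 2.5)
  expect_false(any(as.vector(culled$mask)[on_bragg]))
  half <- which(abs(dbragg - 0.5) < 1e-9 & sm <= 1 / 2.5 - 0.1)
  expect_true(all(as.vector(culled$mask)[half]))

  ## downsampling to one point per Miller index averages surviving points
  coarse <- cull_bragg_and_resolution(lat, bragg_radius = 0.25,
                                      downsample = TRUE)
  expect_equal(coarse$sampling_factor, 1L)
  target <- round(hkl)
  pick <- expected & target[, 1] == 1 & target[, 2] == 0 & target[, 3] == 0
  i1 <- which(coarse$hs == 1); i0 <- which(coarse$ks == 0)
  expect_equal(coarse$I[i1, i0, i0], mean(as.vector(lat$I)[pick]),
               tolerance = 1e-12)
})

test_that("lattice Pearson correlation matches the direct formula", {
  a <- random_lattice(9); b <- random_lattice(10)
  expect_equal(diffuse_pearson(a, a), 1.0, tolerance = 1e-12)
  neg <- a; neg$I <- -a$I
  expect_equal(diffuse_pearson(a, neg), -1.0, tolerance = 1e-12)
  ok <- a$mask & b$mask
  x <- a$I[ok]; y <- b$I[ok]
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(diffuse_pearson(a, b), direct, tolerance = 1e-12)

  tiny <- a; tiny$mask <- array(FALSE, dim(a$I)); tiny$mask[1:2] <- TRUE
  expect_error(diffuse_pearson(tiny, tiny), "3 jointly valid")
})

test_that("LLM model intensity behaves across its parameter limits", {
  ref <- withr::with_seed(11, matrix(runif(15, 0, 10), 5, 3))
  lat <- toy_lattice()
  fsq <- sf_intensity(structure_factor_grid(ref, lat))

  expect_equal(max(llm_intensity(fsq, 6.5, 0)$I), 0)       # sigma = 0
  expect_error(llm_intensity(fsq, -1, 0.3), "gamma")

  ## strictly increasing in sigma at any fixed point off the origin
  i1 <- llm_intensity(fsq, 6.5, 0.2)$I
  i2 <- llm_intensity(fsq, 6.5, 0.4)$I
  sm <- crystdyn:::lattice_smag(lat)
  off_origin <- sm > 1e-9 & fsq$I > 1e-6
  expect_true(all(i2[off_origin] >= i1[off_origin]))

  ## gamma -> infinity: kernel collapses to the identity, equals RBT
  l_inf <- llm_intensity(fsq, 1e5, 0.3)
  r <- rbt_intensity(fsq, 0.3)
  expect_lt(max(abs(l_inf$I - r$I)) / max(r$I), 1e-10)

  ## growing gamma concentrates diffuse onto Bragg positions
  delta <- lat
  delta$I[] <- 0
  ih <- which(abs(lat$hs - 2) < 1e-9)
  i0 <- which(abs(lat$ks) < 1e-9)
  delta$I[ih, i0, i0] <- 1
  ratio <- vapply(c(3, 10, 30), function(g) {
    m <- llm_intensity(delta, g, 0.4)
    ih2 <- which(abs(lat$hs - 2.5) < 1e-9)
    m$I[ih, i0, i0] / m$I[ih2, i0, i0]
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("rigid-body-translation intensity has the analytic prefactor", {
  ref <- withr::with_seed(12, matrix(runif(15, 0, 10), 5, 3))
  lat <- toy_lattice()
  fsq <- sf_intensity(structure_factor_grid(ref, lat))
  expect_equal(max(rbt_intensity(fsq, 0)$I), 0)
  r <- rbt_intensity(fsq, 0.35)
  origin <- which(crystdyn:::lattice_smag(lat) < 1e-12)
  expect_equal(as.vector(r$I)[origin], 0)
  s2 <- crystdyn:::lattice_smag(lat)^2
  expect_equal(r$I, (1 - exp(-4 * pi^2 * s2 * 0.35^2)) * fsq$I,
               tolerance = 1e-12)
})

test_that("the FFT convolution agrees with direct summation on a tiny grid", {
  tiny <- lattice_spec(c(5, 5, 5), 2.5, 1)
  arr <- withr::with_seed(13, array(runif(length(tiny$I)), dim(tiny$I)))
  kern <- crystdyn:::llm_kernel(tiny, 3)
  expect_equal(crystdyn:::conv_fft(arr, kern),
               crystdyn:::conv_direct(arr, kern), tolerance = 1e-12)
})

test_that("a rigidly translating ensemble reproduces the RBT model lattice", {
  ## cross-module consistency: Guinier on shared Gaussian translations
  ref <- withr::with_seed(14, matrix(runif(18, 2, 8), 6, 3))
  lat <- toy_lattice(d_min = 2.5)
  sigma <- 0.3
  n_f <- 600
  shifts <- withr::with_seed(15, matrix(rnorm(n_f * 3, 0, sigma), n_f, 3))
  coords <- array(0, c(n_f, 6, 3))
  for (k in seq_len(n_f)) coords[k, , ] <- sweep(ref, 2, shifts[k, ], "+")
  ens <- coord_ensemble(coords, rep(1L, 6))
  emp <- suppressWarnings(guinier_diffuse(ens, lat, "coherent"))
  model <- rbt_intensity(sf_intensity(structure_factor_grid(ref, lat)), sigma)
  ok <- lat$mask & model$I > 0.05 * max(model$I)
  rel <- abs(emp$I[ok] - model$I[ok]) / model$I[ok]
  expect_lt(stats::median(rel), 4 * sqrt(2 / n_f))
  expect_gt(diffuse_pearson(emp, model), 0.97)
})

test_that("refinement reaches correlation 1 on a noiseless self-target", {
  ref <- withr::with_seed(16, matrix(runif(24, 2, 18), 8, 3))
  lat <- lattice_spec(c(20, 20, 20), 3, 1)
  fsq <- sf_intensity(structure_factor_grid(ref, lat))
  target <- llm_intensity(fsq, 6.5, 0.41)
  fit <- refine_llm(target, fsq, mode = "llm")
  expect_gt(fit$correlation, 0.9999)

  rbt_target <- rbt_intensity(fsq, 0.4)
  fit2 <- refine_llm(rbt_target, fsq, mode = "rbt")
  expect_gt(fit2$correlation, 0.9999)
  expect_equal(fit2$sigma, 0.4, tolerance = 0.02)
})

test_that("displacement MSD conversion is exact", {
  expect_equal(round(llm_msd(0.41), 2), 0.50)
  expect_equal(llm_msd(0), 0)
  expect_equal(llm_msd(1), 3)
  expect_error(llm_msd(-0.1), "sigma")
})

test_that("Cromer-Mann form factors reduce to electron counts at s = 0", {
  expect_equal(form_factor_cm("C", 0), 6, tolerance = 0.01)
  expect_equal(form_factor_cm("O", 0), 8, tolerance = 0.01)
  expect_true(all(diff(form_factor_cm("C", seq(0, 1, 0.1))) < 0))
  expect_error(form_factor_cm("Xx", 0), "no coefficients")
})
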