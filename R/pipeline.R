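#' Default run configuration
#'
#' Nested list of every pipeline parameter with its documented default:
#' a tetragonal-type 2 x 2 x 2 supercell of 48.5 x 48.5 x 63.43 Angstrom
#' cells holding 4 chains of 149 atoms each (32 chains, 4768 C-alpha
#' atoms); 50 even distance bins; exponential fit window 5-55.5 Angstrom;
#' rigid-body model curves from 5000 frames; terminal exclusions of 5
#' N-terminal and 8 C-terminal residues for the intra/interprotein
#' analyses; diffuse grids sampled 2 points per Miller index to a 1.6
#' Angstrom limit with quarter-Miller-index Bragg exclusion.
#'
#' Override any entry with `modifyList()` or pass a YAML file to
#' [run_pipeline()].
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    layout = list(cell_lengths = c(48.5, 48.5, 63.43),
                  cell_angles = c(90, 90, 90),
                  n_cells = c(2L, 2L, 2L),
                  chains_per_cell = 4L,
                  atoms_per_chain = 149L),
    ensemble = list(input = NULL,            # path; NULL = simulate
                    n_frames = 2000L,
                    llm = list(amplitude = 0.45, gamma = 5.7),
                    rbm = list(sd_angle = 1.0, sd_trans = 0.25),
                    white_noise_sd = 0.05),
    subsets = c("all", "intra", "inter"),
    exclude = list(n_term = 5L, c_term = 8L),
    binning = list(n_bins = 50L),
    fit = list(r_min = 5, r_max = 55.5, fix_b = FALSE),
    rbm_curve = list(n_frames = 5000L),
    diffuse = list(d_min = 1.6, sampling_factor = 2L, bragg_radius = 0.25)
  )
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the covariance analysis pipeline
#'
#' Orchestrates the full workflow: obtain an ensemble (simulate a composite
#' ensemble from the config, or read one from `config$ensemble$input`),
#' translationally align it to the first frame, compute the trace-reduced
#' covariance and minimum-image pair distances, bin the covariance for
#' each requested subset (`all`, `intra`, `inter`; terminal residues are
#' excluded from the intra/inter subsets), fit the exponential LLM form,
#' and — when rigid-body parameters are configured — compute the matched
#' RBM model curve on the intra bin edges, subtract it, and fit the
#' residual. Per-subset curves (CSV), fits (JSON) and a manifest naming
#' the configuration hash are written to `output_dir`. All randomness
#' flows from `config$seed`; identical configs give identical outputs.
#'
#' @param config nested list as from [default_config()], or a path to a
#'   YAML file with the same structure (missing entries take defaults).
#' @param output_dir directory for outputs (created if needed); NULL
#'   writes nothing.
#' @return list with the ensemble summary, per-subset `binned_covariance`
#'   and `exp_fit` objects, the RBM curve and residual fit (when
#'   configured), and the manifest.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  if (is.character(config))
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sys <- stage("layout", do.call(crystal_layout, c(
    config$layout[c("cell_lengths", "cell_angles", "n_cells",
                    "chains_per_cell", "atoms_per_chain")],
    list(seed = config$seed))))

  ens <- stage("ensemble", {
    ec <- config$ensemble
    if (!is.null(ec$input)) read_ensemble(ec$input)
    else {
      spec <- ensemble_spec(
        llm = if (!is.null(ec$llm))
          llm_params(ec$llm$amplitude, ec$llm$gamma, ec$n_frames),
        rbm = if (!is.null(ec$rbm))
          rbm_params(ec$rbm$sd_angle, ec$rbm$sd_trans, ec$n_frames),
        white_noise_sd = ec$white_noise_sd %||% 0,
        n_frames = ec$n_frames, seed = config$seed)
      generate_composite_ensemble(sys, spec)
    }
  })

  ens <- stage("align", align_translational(ens, 1L))
  tc <- stage("covariance", traced_covariance(ens))
  dmat <- stage("distances", pairwise_distances(tc$mean_coords, box = ens$box))

  excl <- NULL
  if (!is.null(config$exclude))
    excl <- terminal_exclusions(max(ens$residue_index),
                                config$exclude$n_term, config$exclude$c_term)
  masks <- stage("classify", classify_pairs(ens$chain_index,
                                            ens$residue_index,
                                            exclude_residues = excl))
  n_chain <- length(unique(ens$chain_index))

  subsets <- intersect(config$subsets, c("all", "intra", "inter"))
  if (n_chain < 2 && "inter" %in% subsets) {
    warning("single-chain system: interprotein analysis skipped")
    subsets <- setdiff(subsets, "inter")
  }

  curves <- list(); fits <- list()
  for (sb in subsets) {
    mask <- switch(sb, all = NULL, intra = masks$intra, inter = masks$inter)
    curves[[sb]] <- stage(paste0("bin_", sb),
      bin_covariance(tc, dmat, mask, n_bins = config$binning$n_bins,
                     subset_label = sb))
    fits[[sb]] <- stage(paste0("fit_", sb),
      fit_exponential(curves[[sb]], config$fit$r_min, config$fit$r_max,
                      fix_b = isTRUE(config$fit$fix_b)))
    message(sprintf(
      "stage %s: %d pairs in %d bins (%d occupied); a=%.3g gamma=%.3g b=%.3g",
      sb, sum(curves[[sb]]$count), length(curves[[sb]]$bin_center),
      sum(!curves[[sb]]$empty), fits[[sb]]$a, fits[[sb]]$gamma, fits[[sb]]$b))
  }

  rbm_curve <- residual <- residual_fit <- NULL
  if (!is.null(config$ensemble$rbm) && "intra" %in% names(curves)) {
    chain1 <- which(ens$chain_index == ens$chain_index[1])
    coords1 <- sys$positions[chain1, , drop = FALSE]
    excl_atoms <- if (!is.null(excl))
      which(ens$residue_index[chain1] %in% excl)
    p <- rbm_params(config$ensemble$rbm$sd_angle,
                    config$ensemble$rbm$sd_trans,
                    n_frames = config$rbm_curve$n_frames,
                    seed = derive_seeds(config$seed, 4L)[4])
    rbm_curve <- stage("rbm_curve",
      rbm_covariance_curve(p, coords1, exclude = excl_atoms,
                           bin_edges = curves$intra$bin_edges))
    residual <- stage("subtract", subtract_curves(curves$intra, rbm_curve))
    residual_fit <- stage("fit_residual",
      fit_exponential(residual, config$fit$r_min,
                      max(residual$bin_center[!residual$empty]),
                      fix_b = isTRUE(config$fit$fix_b)))
    message(sprintf("stage residual: gamma=%.3g +/- %.2g",
                    residual_fit$gamma, residual_fit$gamma_se))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("crystdyn")),
                   r_version = R.version.string,
                   config = config, config_hash = hash,
                   n_frames = n_frames(ens), n_atoms = n_atoms(ens),
                   n_chains = n_chain,
                   full_covariance_dim = tc$full_dim)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (sb in names(curves)) {
      write_binned_csv(curves[[sb]],
                       file.path(output_dir, paste0("covar_", sb, ".csv")),
                       hash = hash)
      write_fit_json(fits[[sb]],
                     file.path(output_dir, paste0("fit_", sb, ".json")),
                     hash = hash)
    }
    if (!is.null(rbm_curve)) {
      write_binned_csv(rbm_curve, file.path(output_dir, "covar_rbm.csv"),
                       hash = hash)
      write_binned_csv(residual, file.path(output_dir, "covar_residual.csv"),
                       hash = hash)
      write_fit_json(residual_fit, file.path(output_dir, "fit_residual.json"),
                     hash = hash)
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 6, null = "null",
                         force = TRUE)
  }

  invisible(list(system = sys, covariance = tc, curves = curves, fits = fits,
                 rbm_curve = rbm_curve, residual = residual,
                 residual_fit = residual_fit, manifest = manifest))
}
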