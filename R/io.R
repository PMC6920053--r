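#' Write a coordinate ensemble to disk
#'
#' Two formats, selected by extension: multi-model PDB (`.pdb`; one MODEL
#' per frame, C-alpha atoms only, chain IDs and residue numbers preserved,
#' box written as a CRYST1 record, coordinate precision 1e-3 Angstrom) or
#' the native array container (`.rds`; bit-exact round trip).
#'
#' @param ens a `coord_ensemble`.
#' @param path output file ending in `.pdb` or `.rds`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "coord_ensemble"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(ens, path)
    return(invisible(path))
  }
  if (ext != "pdb") stop_invalid("unsupported ensemble format '.%s'", ext)

  ids <- c(LETTERS, letters, as.character(0:9))
  chains <- ids[((ens$chain_index - 1L) %% length(ids)) + 1L]
  f <- n_frames(ens)
  n <- n_atoms(ens)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ens$box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      ens$box[1], ens$box[2], ens$box[3], 90, 90, 90), con)
  for (k in seq_len(f)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), chains, ens$residue_index,
      ens$coords[k, , 1], ens$coords[k, , 2], ens$coords[k, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a coordinate ensemble from disk
#'
#' Auto-detects the format from the extension (`.pdb` multi-model PDB via
#' bio3d, `.rds` native container). For PDB input, per-model atom counts
#' are validated first so an inconsistent model is reported by index.
#'
#' @param path input file.
#' @return a `coord_ensemble`.
#' @export
read_ensemble <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    ens <- readRDS(path)
    stopifnot(inherits(ens, "coord_ensemble"))
    return(ens)
  }
  if (ext != "pdb") stop_invalid("unsupported ensemble format '.%s'", ext)

  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    model_ends <- grep("^ENDMDL", lines)
    counts <- mapply(function(a, b) sum(grepl("^ATOM|^HETATM", lines[a:b])),
                     model_starts, model_ends)
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop_invalid("model %d has %d atoms, expected %d",
                   bad, counts[bad], counts[1])
    }
  }
  box <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) > 0)
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  n <- nrow(pdb$atom)
  f <- nrow(xyz)
  coords <- array(0, c(f, n, 3L))
  coords[, , 1] <- xyz[, seq(1, 3 * n, by = 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, 3 * n, by = 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, 3 * n, by = 3), drop = FALSE]
  chain <- as.integer(factor(pdb$atom$chain, levels = unique(pdb$atom$chain)))
  coord_ensemble(coords, chain, as.integer(pdb$atom$resno), box = box,
                 metadata = list(source = path))
}

#' Write a diffuse lattice as a plain-text HKL table
#'
#' Header comment lines carry the cell, sampling factor and resolution
#' limit; then one record per grid point, `h k l I valid`, with fractional
#' Miller indices.
#'
#' @param lat a `diffuse_lattice`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_hkl <- function(lat, path) {
  stopifnot(inherits(lat, "diffuse_lattice"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cell %.6g %.6g %.6g", lat$cell[1], lat$cell[2], lat$cell[3]),
    sprintf("# sampling_factor %d", lat$sampling_factor),
    sprintf("# d_min %.6g", lat$d_min),
    "# h k l I valid"), con)
  hkl <- lattice_hkl(lat)
  writeLines(sprintf("%.6g %.6g %.6g %.10g %d",
                     hkl[, 1], hkl[, 2], hkl[, 3],
                     as.vector(lat$I), as.integer(as.vector(lat$mask))), con)
  invisible(path)
}

#' Read a plain-text HKL lattice
#'
#' @param path file written by [write_hkl()].
#' @return a `diffuse_lattice`.
#' @export
read_hkl <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    l <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(l) == 0) stop_invalid("missing '%s' header", key)
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", l[1]), " ")[[1]])
  }
  cell <- getv("cell")
  sf <- as.integer(getv("sampling_factor"))
  d_min <- getv("d_min")
  lat <- lattice_spec(cell, d_min, sf)
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("h", "k", "l", "I", "valid"))
  if (nrow(dat) != length(lat$I))
    stop_invalid("expected %d records, found %d", length(lat$I), nrow(dat))
  ## records are written in grid order; verify and assign
  hkl <- lattice_hkl(lat)
  if (max(abs(dat$h - hkl[, 1]), abs(dat$k - hkl[, 2]),
          abs(dat$l - hkl[, 3])) > 1e-6)
    stop_invalid("HKL records are not in grid order")
  lat$I <- array(dat$I, dim(lat$I))
  lat$mask <- array(dat$valid > 0, dim(lat$I))
  lat
}

#' Write a binned covariance curve as CSV
#'
#' Columns `r_center, mean, stderr, count`; metadata (subset label,
#' optional config hash) go in `#` comment lines.
#'
#' @param binned a `binned_covariance`.
#' @param path output file.
#' @param hash optional configuration hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_binned_csv <- function(binned, path, hash = NULL) {
  stopifnot(inherits(binned, "binned_covariance"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subset %s", binned$subset_label), con)
  if (!is.null(hash)) writeLines(sprintf("# config %s", hash), con)
  df <- as.data.frame(binned)
  writeLines("r_center,mean,stderr,count", con)
  writeLines(sprintf("%.6g,%.6g,%.6g,%d",
                     df$r_center, df$mean, df$stderr, df$count), con)
  invisible(path)
}

#' Write an exponential fit result as JSON
#'
#' @param fit an `exp_fit`.
#' @param path output file.
#' @param hash optional configuration hash.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, hash = NULL) {
  stopifnot(inherits(fit, "exp_fit"))
  out <- unclass(fit)
  if (!is.null(hash)) out$config <- hash
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 6, null = "null")
  invisible(path)
}
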