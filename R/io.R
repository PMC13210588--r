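# Plain-text serialization: CSV for series/matrices, JSON sidecars for
# metadata, optional ASCII PGM images for quick matrix inspection.
# Numbers are written with 17 significant digits so write-then-read is exact.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
}

meta_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV has header `tau,z1,z2` and full-precision (17 significant digit)
#' values, so a round trip reproduces the numbers exactly. Metadata
#' (parameters, solver, tolerances, seed) goes to `<path-sans-ext>.json`.
#'
#' @param traj A [piezo_trajectory()].
#' @param path CSV file path.
#' @param meta Write/read the JSON sidecar (default TRUE).
#' @return `write_trajectory()`: the path, invisibly. `read_trajectory()`: a
#'   [piezo_trajectory()]. A malformed CSV (wrong column count) fails with the
#'   offending line number.
#' @export
write_trajectory <- function(traj, path, meta = TRUE) {
  stopifnot(inherits(traj, "piezo_trajectory"))
  lines <- c("tau,z1,z2",
             paste(fmt_num(traj$tau), fmt_num(traj$z1), fmt_num(traj$z2),
                   sep = ","))
  writeLines(lines, path)
  if (meta) {
    m <- trajectory_meta(traj)
    if (length(m)) write_json_file(m, meta_path(path))
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, meta = TRUE) {
  nf <- utils::count.fields(path, sep = ",", quote = "")
  bad <- which(nf != 3L)
  if (length(bad))
    stop("malformed trajectory CSV '", path, "': line ", bad[1],
         " has ", nf[bad[1]], " fields (expected 3)")
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("tau", "z1", "z2")))
    stop("malformed trajectory CSV '", path, "': header must be tau,z1,z2")
  m <- list()
  mp <- meta_path(path)
  if (meta && file.exists(mp))
    m <- jsonlite::read_json(mp, simplifyVector = TRUE)
  piezo_trajectory(df$tau, df$z1, df$z2, meta = m)
}

#' Write / read a basin grid (CSV matrix plus JSON bounds)
#'
#' `basin.csv` holds the `final_z1` matrix (rows indexed by `z1_grid`);
#' the sidecar JSON records grid bounds, resolution, horizon, step, label
#' tolerance and blow-up count. Labels are recomputed on read.
#'
#' @param basin A [basin_map()] result.
#' @param path CSV file path.
#' @return The path (write) or a `basin_grid` (read).
#' @export
write_basin <- function(basin, path) {
  stopifnot(inherits(basin, "basin_grid"))
  lines <- apply(basin$final_z1, 1, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(lines, path)
  write_json_file(list(z1_range = range(basin$z1_grid),
                       z2_range = range(basin$z2_grid),
                       N = length(basin$z1_grid),
                       T_end = basin$T_end, dt = basin$dt,
                       label_tol = basin$label_tol,
                       n_blown = basin$n_blown),
                  meta_path(path))
  invisible(path)
}

#' @rdname write_basin
#' @export
read_basin <- function(path) {
  m <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  fz <- as.matrix(utils::read.csv(path, header = FALSE,
                                  colClasses = "numeric"))
  dimnames(fz) <- NULL
  if (!all(dim(fz) == m$N))
    stop("basin CSV dimensions ", paste(dim(fz), collapse = "x"),
         " do not match the declared N = ", m$N)
  labels <- sign(fz)
  labels[abs(fz) <= m$label_tol] <- 0
  structure(list(z1_grid = seq(m$z1_range[1], m$z1_range[2], length.out = m$N),
                 z2_grid = seq(m$z2_range[1], m$z2_range[2], length.out = m$N),
                 final_z1 = fz, labels = labels,
                 n_blown = m$n_blown, T_end = m$T_end, dt = m$dt,
                 label_tol = m$label_tol),
            class = "basin_grid")
}

#' Write / read a stochastic ensemble directory
#'
#' One full-precision CSV per member (`member_<seed>.csv`) plus a
#' `manifest.json` recording seeds, noise intensity, parameters and initial
#' condition; the manifest and the seeds suffice to regenerate the ensemble
#' bit-identically with [run_ensemble()].
#'
#' @param run A [run_ensemble()] result.
#' @param dir Output directory (created if needed).
#' @return The directory (write) or a `piezo_ensemble` (read). A manifest
#'   whose member file is missing fails with the offending seed listed.
#' @export
write_ensemble <- function(run, dir) {
  stopifnot(inherits(run, "piezo_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("member_%d.csv", run$seeds)
  for (i in seq_along(run$seeds)) {
    write_trajectory(ensemble_member(run, i), file.path(dir, files[i]),
                     meta = FALSE)
  }
  write_json_file(list(seeds = run$seeds, files = files,
                       sigma1 = run$sigma1, params = run$params,
                       ic = run$ic, n_real = length(run$seeds)),
                  file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  missing <- !file.exists(file.path(dir, man$files))
  if (any(missing))
    stop("ensemble manifest lists missing member file(s) for seed(s): ",
         paste(man$seeds[missing], collapse = ", "))
  trs <- lapply(file.path(dir, man$files), read_trajectory, meta = FALSE)
  tau <- trs[[1]]$tau
  structure(list(tau = tau,
                 z1 = vapply(trs, function(t) t$z1, numeric(length(tau))),
                 z2 = vapply(trs, function(t) t$z2, numeric(length(tau))),
                 seeds = as.integer(man$seeds), sigma1 = man$sigma1,
                 params = man$params, ic = man$ic,
                 dt = mean(diff(tau))),
            class = "piezo_ensemble")
}

#' Write a matrix as an ASCII (P2) PGM image
#'
#' Portable grayscale dump for quick visual inspection of recurrence matrices
#' and basin label maps; values are linearly rescaled to 0..255.
#'
#' @param mat Numeric or logical matrix.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_pgm <- function(mat, path) {
  mat <- matrix(as.numeric(mat), nrow(mat), ncol(mat))
  rng <- range(mat)
  g <- if (diff(rng) == 0) matrix(0L, nrow(mat), ncol(mat))
       else matrix(as.integer(round(255 * (mat - rng[1]) / diff(rng))),
                   nrow(mat), ncol(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  writeLines(apply(g, 1, paste, collapse = " "), con)
  invisible(path)
}
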