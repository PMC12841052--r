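## Chemical-space embedding (FCFP4 + UMAP) and kernel-density occupancy.

#' Fit a chemical-space embedding on a reference population
#'
#' Computes FCFP-style functional circular fingerprints (radius 2, 1024
#' bits) for the reference compounds and fits a 2-D UMAP on them
#' (n_neighbors = 50, Jaccard metric by default, fixed seed). Libraries and
#' other query sets are then projected through the fitted model with
#' [project()]; the reference is never refit.
#'
#' @param smiles Character vector of reference SMILES, or a pre-computed
#'   0/1 fingerprint matrix.
#' @param n_neighbors UMAP neighbourhood size (default 50).
#' @param metric UMAP metric (default `"jaccard"`).
#' @param seed Integer random seed (default 42). With a fixed seed,
#'   refitting on the same input reproduces identical coordinates.
#' @param model_path Where to persist the fitted model (default: a
#'   session temp file).
#' @return List of class `cddap_embedding`: `model_path`, `params`, `n`,
#'   and `coords` (n x 2 matrix of the training coordinates).
#' @export
fit_embedding <- function(smiles, n_neighbors = 50L, metric = "jaccard",
                          seed = 42L,
                          model_path = tempfile(fileext = ".pkl")) {
  fps <- if (is.matrix(smiles)) smiles else fcfp_fp(smiles)
  if (nrow(fps) == 0) stop("fit_embedding(): empty reference set")
  if (nrow(fps) < n_neighbors) {
    stop("fit_embedding(): n_neighbors (", n_neighbors,
         ") exceeds the number of reference compounds (", nrow(fps),
         "); lower n_neighbors")
  }
  fps_path <- tempfile(fileext = ".fps")
  coords_path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fps_path, coords_path)), add = TRUE)
  write_fp_file(fps, fps_path)
  py_worker("umap_fit",
            list(fps = fps_path, model = model_path, coords = coords_path,
                 n_neighbors = as.integer(n_neighbors), metric = metric,
                 seed = as.integer(seed)))
  coords <- as.matrix(utils::read.csv(coords_path))
  out <- list(model_path = model_path,
              params = list(n_neighbors = as.integer(n_neighbors),
                            metric = metric, seed = as.integer(seed),
                            nbits = ncol(fps), radius = 2L),
              n = nrow(fps), coords = coords)
  class(out) <- "cddap_embedding"
  out
}

#' Project compounds through a fitted embedding
#'
#' @param model A `cddap_embedding` from [fit_embedding()].
#' @param smiles Character vector of SMILES, or a 0/1 fingerprint matrix
#'   with the model's bit size. Unsanitizable SMILES are skipped (their
#'   rows are dropped; see `attr(, "skipped")`).
#' @return n x 2 matrix of coordinates, input order preserved.
#' @export
project <- function(model, smiles) {
  stopifnot(inherits(model, "cddap_embedding"))
  if (length(smiles) == 0) return(matrix(numeric(), 0, 2,
                                         dimnames = list(NULL, c("x", "y"))))
  fps <- if (is.matrix(smiles)) smiles else fcfp_fp(smiles, nbits = model$params$nbits)
  skipped <- which(is.na(fps[, 1L]))
  if (length(skipped)) fps <- fps[-skipped, , drop = FALSE]
  if (nrow(fps) == 0) {
    out <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("x", "y")))
    attr(out, "skipped") <- skipped
    return(out)
  }
  fps_path <- tempfile(fileext = ".fps")
  coords_path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fps_path, coords_path)), add = TRUE)
  write_fp_file(fps, fps_path)
  py_worker("umap_transform",
            list(model = model$model_path, fps = fps_path,
                 coords = coords_path))
  out <- as.matrix(utils::read.csv(coords_path))
  attr(out, "skipped") <- skipped
  out
}

#' Fit on a reference and project several sets in one pass
#'
#' Equivalent to [fit_embedding()] followed by [project()] on each query
#' set, but runs in a single worker process (the embedding runtime is
#' dominated by interpreter start-up and JIT compilation, so batch this
#' when projecting the four libraries plus an approved subset).
#'
#' @param reference Reference SMILES or fingerprint matrix.
#' @param queries Named list of SMILES vectors or fingerprint matrices.
#' @inheritParams fit_embedding
#' @return List: `model` (a `cddap_embedding`), `reference` (coordinates),
#'   and `queries` (named list of coordinate matrices).
#' @export
embed_sets <- function(reference, queries = list(), n_neighbors = 50L,
                       metric = "jaccard", seed = 42L) {
  ref_fps <- if (is.matrix(reference)) reference else fcfp_fp(reference)
  if (nrow(ref_fps) < n_neighbors) {
    stop("embed_sets(): n_neighbors (", n_neighbors,
         ") exceeds the number of reference compounds (", nrow(ref_fps),
         "); lower n_neighbors")
  }
  model_path <- tempfile(fileext = ".pkl")
  ref_path <- tempfile(fileext = ".fps")
  ref_coords <- tempfile(fileext = ".csv")
  write_fp_file(ref_fps, ref_path)
  q_paths <- character(0)
  q_coords <- character(0)
  for (q in queries) {
    fps <- if (is.matrix(q)) q else fcfp_fp(q)
    p <- tempfile(fileext = ".fps")
    write_fp_file(fps, p)
    q_paths <- c(q_paths, p)
    q_coords <- c(q_coords, tempfile(fileext = ".csv"))
  }
  on.exit(unlink(c(ref_path, ref_coords, q_paths, q_coords)), add = TRUE)
  py_worker("umap_batch",
            list(fps = ref_path, model = model_path, coords = ref_coords,
                 query_fps = as.list(q_paths),
                 query_coords = as.list(q_coords),
                 n_neighbors = as.integer(n_neighbors), metric = metric,
                 seed = as.integer(seed)))
  ref_xy <- as.matrix(utils::read.csv(ref_coords))
  model <- list(model_path = model_path,
                params = list(n_neighbors = as.integer(n_neighbors),
                              metric = metric, seed = as.integer(seed),
                              nbits = ncol(ref_fps), radius = 2L),
                n = nrow(ref_fps), coords = ref_xy)
  class(model) <- "cddap_embedding"
  qs <- lapply(q_coords, function(p) as.matrix(utils::read.csv(p)))
  names(qs) <- names(queries)
  list(model = model, reference = ref_xy, queries = qs)
}

#' Build a shared evaluation lattice over one or more coordinate sets
#'
#' One global rectangular grid spanning the union bounding box of all sets,
#' padded 5% per side, default resolution 512 x 512. Density maps compared
#' by [occupancy()] must be built on the same grid.
#'
#' @param coord_sets A coordinate matrix or list of coordinate matrices.
#' @param resolution Cells per axis (default 512).
#' @param pad Fractional padding per side (default 0.05).
#' @return List of class `cddap_grid`: `gx`, `gy` (cell-centre vectors) and
#'   `cell_area`.
#' @export
build_grid <- function(coord_sets, resolution = 512L, pad = 0.05) {
  if (is.matrix(coord_sets)) coord_sets <- list(coord_sets)
  all_xy <- do.call(rbind, lapply(coord_sets, function(m) m[, 1:2]))
  rx <- range(all_xy[, 1L])
  ry <- range(all_xy[, 2L])
  px <- max(diff(rx), .Machine$double.eps) * pad
  py <- max(diff(ry), .Machine$double.eps) * pad
  gx <- seq(rx[1L] - px, rx[2L] + px, length.out = resolution)
  gy <- seq(ry[1L] - py, ry[2L] + py, length.out = resolution)
  out <- list(gx = gx, gy = gy,
              cell_area = (gx[2L] - gx[1L]) * (gy[2L] - gy[1L]))
  class(out) <- "cddap_grid"
  out
}

#' Gridded Gaussian kernel density map with occupancy threshold
#'
#' Gaussian KDE with full data covariance and Scott's-rule bandwidth
#' (factor n^(-1/6) in two dimensions, matching `scipy.stats.gaussian_kde`),
#' evaluated on a shared lattice. Cells whose raw normalised density
#' exceeds `threshold` form the occupied region; its area is the occupied
#' cell count times the cell area.
#'
#' @param coords n x 2 coordinate matrix (n >= 3, non-collinear).
#' @param grid A `cddap_grid` from [build_grid()] (defaults to a grid over
#'   `coords` alone).
#' @param threshold Density threshold (default 0.01, applied to the raw
#'   density that integrates to 1).
#' @param bw_factor Bandwidth factor multiplying the data covariance
#'   (standard-deviation scale). `NULL` (default) uses Scott's rule,
#'   n^(-1/6) in two dimensions. Note that under Scott's rule the
#'   bandwidth depends on n, so point duplication changes the map
#'   slightly; pass a fixed factor for size-invariant comparisons.
#' @return List of class `cddap_density`: `grid`, `density` (matrix),
#'   `threshold`, `occupied` (logical matrix), `area`, `n`.
#' @export
kde_map <- function(coords, grid = build_grid(coords), threshold = 0.01,
                    bw_factor = NULL) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(coords)
  if (n < 3) stop("kde_map(): need at least 3 points")
  if (is.null(bw_factor)) {
    S <- stats::cov(coords)         # unbiased, as in gaussian_kde
    bw_factor <- n^(-1 / 6)         # Scott's rule, d = 2
  } else {
    # explicit factor: population covariance, so the kernel (hence the
    # whole map) is exactly invariant under duplication of the point set
    S <- stats::cov(coords) * (n - 1) / n
  }
  if (det(S) <= 0) {
    stop("kde_map(): singular covariance (collinear points); ",
         "jitter the coordinates")
  }
  C <- S * bw_factor^2
  dens <- kde_grid_eval(coords[, 1L], coords[, 2L], grid$gx, grid$gy,
                        C[1L, 1L], C[1L, 2L], C[2L, 2L])
  occ <- dens > threshold
  out <- list(grid = grid, density = dens, threshold = threshold,
              occupied = occ, area = sum(occ) * grid$cell_area, n = n)
  class(out) <- "cddap_density"
  out
}

#' Occupancy of a reference density region by a library
#'
#' The occupancy rate is the fraction of the reference set's occupied cells
#' (density above threshold) that are also occupied by the library. Both
#' maps must share the same lattice.
#'
#' @param library_map,reference_map `cddap_density` maps built on the same
#'   grid.
#' @param name Library label carried into the report.
#' @param mean_qed Optional mean QED of the library, carried into the
#'   report for downstream correlation.
#' @return List of class `cddap_occupancy`: `name`, `kde_area`,
#'   `occupancy_rate` in \[0, 1\], `mean_qed`.
#' @export
occupancy <- function(library_map, reference_map, name = "library",
                      mean_qed = NA_real_) {
  stopifnot(inherits(library_map, "cddap_density"),
            inherits(reference_map, "cddap_density"))
  if (!isTRUE(all.equal(library_map$grid$gx, reference_map$grid$gx)) ||
      !isTRUE(all.equal(library_map$grid$gy, reference_map$grid$gy))) {
    stop("occupancy(): maps are on different lattices; ",
         "build both with a shared build_grid()")
  }
  ref_cells <- sum(reference_map$occupied)
  if (ref_cells == 0) stop("occupancy(): reference occupied region is empty")
  rate <- sum(library_map$occupied & reference_map$occupied) / ref_cells
  out <- list(name = name, kde_area = library_map$area,
              occupancy_rate = rate, mean_qed = mean_qed)
  class(out) <- "cddap_occupancy"
  out
}

#' @export
print.cddap_occupancy <- function(x, ...) {
  cat(sprintf("%s: KDE area %.3f, occupancy rate %.1f%%, mean QED %.3f\n",
              x$name, x$kde_area, 100 * x$occupancy_rate, x$mean_qed))
  invisible(x)
}
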