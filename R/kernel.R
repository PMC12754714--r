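#' Matern covariance kernel specification
#'
#' Constructs the stationary Matern correlation kernel used for all
#' Gaussian-process priors in the model.  The correlation between two
#' locations at Euclidean distance \eqn{d} is
#' \deqn{K(d) = \frac{2^{1-\nu}}{\Gamma(\nu)} u^\nu K_\nu(u), \qquad
#'       u = \sqrt{2\nu}\, d / \rho,}
#' with unit variance, length scale \eqn{\rho} (`length_scale`) and
#' smoothness \eqn{\nu} (`smoothness`).  Closed forms are used for
#' \eqn{\nu \in \{1/2, 3/2, 5/2\}}; other values fall back to the Bessel
#' representation.  Coordinates are normalized to the unit cube before
#' kernel evaluation (see [spatial_domain()]), so `length_scale` is
#' unit-free; `0.3` is a typical choice for slice-level simulated data and
#' `0.1` for dense whole-brain grids.
#'
#' @param length_scale positive correlation length \eqn{\rho} in normalized
#'   coordinate units.
#' @param smoothness positive smoothness \eqn{\nu}; `3/2` (once mean-square
#'   differentiable fields) is the default.
#' @param jitter nonnegative value added to Gram-matrix diagonals before
#'   Cholesky factorization; escalated automatically on failure.
#' @return An object of class `"bsir_kernel"`.
#' @examples
#' k <- matern_kernel(0.3)
#' matern_cor(c(0, 0.3, 1), k)
#' @export
matern_kernel <- function(length_scale = 0.3, smoothness = 1.5, jitter = 1e-8) {
  if (!is.numeric(length_scale) || length(length_scale) != 1L || length_scale <= 0)
    stop("'length_scale' must be a single positive number")
  if (!is.numeric(smoothness) || length(smoothness) != 1L || smoothness <= 0)
    stop("'smoothness' must be a single positive number")
  if (!is.numeric(jitter) || length(jitter) != 1L || jitter < 0)
    stop("'jitter' must be a single nonnegative number")
  structure(list(family = "matern", length_scale = length_scale,
                 smoothness = smoothness, jitter = jitter),
            class = "bsir_kernel")
}

#' @export
print.bsir_kernel <- function(x, ...) {
  cat(sprintf("Matern kernel: length scale %.4g, smoothness %.4g, jitter %.1e\n",
              x$length_scale, x$smoothness, x$jitter))
  invisible(x)
}

#' Matern correlation at given distances
#'
#' @param dist vector of nonnegative Euclidean distances.
#' @param kernel a [matern_kernel()] object.
#' @return Correlations in `(0, 1]`; exactly 1 at zero distance.
#' @export
matern_cor <- function(dist, kernel) {
  stopifnot(inherits(kernel, "bsir_kernel"))
  if (any(dist < 0)) stop("distances must be nonnegative")
  nu <- kernel$smoothness
  u <- sqrt(2 * nu) * dist / kernel$length_scale
  out <-
    if (nu == 0.5) {
      exp(-u)
    } else if (nu == 1.5) {
      (1 + u) * exp(-u)
    } else if (nu == 2.5) {
      (1 + u + u^2 / 3) * exp(-u)
    } else {
      # general form; besselK underflows for large u, where the limit is 0
      r <- 2^(1 - nu) / gamma(nu) * u^nu * besselK(u, nu)
      r[!is.finite(r)] <- 0
      r
    }
  out[dist == 0] <- 1
  out
}

#' Gram matrix of the kernel between two coordinate sets
#'
#' @param rows,cols numeric matrices with one location per row and matching
#'   column dimension; `cols = NULL` takes `cols = rows` (symmetric case).
#' @param kernel a [matern_kernel()] object.
#' @param jitter logical; add `kernel$jitter` to the diagonal (square,
#'   symmetric case only).
#' @return `nrow(rows)` by `nrow(cols)` correlation matrix.
#' @export
gram_matrix <- function(rows, cols = NULL, kernel, jitter = FALSE) {
  rows <- as.matrix(rows)
  symmetric <- is.null(cols)
  cols <- if (symmetric) rows else as.matrix(cols)
  if (ncol(rows) != ncol(cols)) stop("coordinate sets differ in dimension")
  d2 <- outer(rowSums(rows^2), rep(1, nrow(cols))) +
    outer(rep(1, nrow(rows)), rowSums(cols^2)) -
    2 * tcrossprod(rows, cols)
  d2[d2 < 0] <- 0
  G <- matern_cor(sqrt(d2), kernel)
  dim(G) <- c(nrow(rows), nrow(cols))
  if (symmetric) {
    G <- (G + t(G)) / 2
    if (jitter) diag(G) <- diag(G) + kernel$jitter
  }
  G
}

#' Spatial domain of masked image locations
#'
#' Holds the coordinates of the `V` analyzed voxels (or surface vertices)
#' and, optionally, the grid geometry needed to write maps back to image
#' files.  Coordinates are affinely mapped into the unit cube, dividing all
#' axes by the largest axis extent so the aspect ratio is preserved; kernel
#' length scales then live on a unit-free scale.
#'
#' @param coords numeric `V` by `d` matrix of locations (`d` = 2 or 3).
#' @param voxel_ids integer labels linking locations back to the source
#'   grid or mesh; defaults to `1:V`, must be unique.
#' @param normalize logical; map coordinates into `[0,1]^d` (default).
#' @param grid optional list describing the source geometry
#'   (`dim`, `mask_idx`, and optionally `affine`), used by [write_maps()].
#' @return An object of class `"bsir_domain"` with elements `coords`
#'   (normalized), `coords_raw`, `voxel_ids`, `d`, `V`, `grid`.
#' @export
spatial_domain <- function(coords, voxel_ids = NULL, normalize = TRUE,
                           grid = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 2L) stop("need at least two locations")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(voxel_ids)) voxel_ids <- seq_len(nrow(coords))
  if (anyDuplicated(voxel_ids)) stop("voxel_ids must be unique")
  raw <- coords
  if (normalize) {
    mins <- apply(coords, 2, min)
    coords <- sweep(coords, 2, mins)
    ext <- max(apply(coords, 2, max))
    if (ext <= 0) stop("degenerate coordinates: zero extent")
    coords <- coords / ext
  }
  structure(list(coords = coords, coords_raw = raw,
                 voxel_ids = as.integer(voxel_ids),
                 d = ncol(coords), V = nrow(coords), grid = grid),
            class = "bsir_domain")
}

#' @export
print.bsir_domain <- function(x, ...) {
  cat(sprintf("Spatial domain: %d locations in %d-D (normalized to [0,1]^%d)\n",
              x$V, x$d, x$d))
  invisible(x)
}

#' Empirical length-scale estimate from pairwise spatial correlations
#'
#' Subsamples pairs of locations, computes the across-participant
#' correlation of group-mean-removed images at each pair, and finds the
#' Matern length scale whose correlation-versus-distance curve best fits
#' the points in least squares.
#'
#' @param Y `N` by `V` response matrix (two or more participants).
#' @param domain a [spatial_domain()].
#' @param n_pairs number of location pairs to subsample.
#' @param seed integer seed controlling the subsample.
#' @param smoothness Matern smoothness held fixed during the fit.
#' @param bounds search interval for the length scale.
#' @return Estimated length scale (scalar).  Estimates pinned at a bound
#'   emit a warning.
#' @export
estimate_length_scale <- function(Y, domain, n_pairs = 2000L, seed = 1L,
                                  smoothness = 1.5, bounds = c(0.01, 1)) {
  stopifnot(inherits(domain, "bsir_domain"))
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least two participants")
  if (ncol(Y) != domain$V) stop("Y and domain disagree on V")
  R <- sweep(Y, 2, colMeans(Y))              # remove the group-mean image
  sds <- sqrt(colSums(R^2))
  ok <- sds > 0
  if (sum(ok) < 4L) stop("images are (near-)constant across participants; cannot estimate a length scale")
  set.seed(as.integer(seed))
  idx <- which(ok)
  a <- sample(idx, n_pairs, replace = TRUE)
  b <- sample(idx, n_pairs, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  d <- sqrt(rowSums((domain$coords[a, , drop = FALSE] -
                     domain$coords[b, , drop = FALSE])^2))
  rho_ab <- colSums(R[, a, drop = FALSE] * R[, b, drop = FALSE]) / (sds[a] * sds[b])
  if (stats::sd(rho_ab) < 1e-10 && mean(rho_ab) > 0.99)
    stop("pairwise correlations are all ~1; images are degenerate")
  obj <- function(ls)
    mean((rho_ab - matern_cor(d, matern_kernel(ls, smoothness)))^2)
  opt <- stats::optimize(obj, interval = bounds)
  est <- opt$minimum
  tol <- 1e-3 * diff(bounds)
  if (est - bounds[1] < tol) {
    warning("length-scale estimate pinned at the lower bound (no detectable spatial correlation)")
    est <- bounds[1]
  } else if (bounds[2] - est < tol) {
    warning("length-scale estimate pinned at the upper bound")
    est <- bounds[2]
  }
  est
}
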