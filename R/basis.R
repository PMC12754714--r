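#' Select approximately space-filling inducing points
#'
#' Default method runs k-means on the normalized coordinates and snaps each
#' centroid to the nearest masked location; duplicate snaps are replaced by
#' greedy farthest-point substitution, so the result is always `L` distinct
#' indices.  A uniform-random alternative is provided.
#'
#' @param domain a [spatial_domain()].
#' @param L number of inducing points, `1 <= L <= V`.
#' @param method `"kmeans"` (space-filling, default) or `"random"`.
#' @param seed integer seed; the selection is deterministic given the seed.
#' @return Integer vector of `L` distinct location indices.
#' @export
select_inducing <- function(domain, L, method = c("kmeans", "random"), seed = 1L) {
  stopifnot(inherits(domain, "bsir_domain"))
  method <- match.arg(method)
  V <- domain$V
  if (L < 1L || L > V) stop("L must be between 1 and V = ", V)
  if (L == V) return(seq_len(V))
  set.seed(as.integer(seed))
  if (method == "random") return(sort(sample.int(V, L)))
  km <- suppressWarnings(
    stats::kmeans(domain$coords, centers = L, iter.max = 50L, nstart = 1L))
  idx <- integer(L)
  for (k in seq_len(L)) {
    dd <- colSums((t(domain$coords) - km$centers[k, ])^2)
    idx[k] <- which.min(dd)
  }
  idx <- unique(idx)
  # farthest-point substitution for centroids that snapped to the same voxel
  while (length(idx) < L) {
    cand <- setdiff(seq_len(V), idx)
    dmin <- rep(Inf, length(cand))
    for (j in idx) {
      dj <- rowSums((domain$coords[cand, , drop = FALSE] -
                     matrix(domain$coords[j, ], length(cand), domain$d, byrow = TRUE))^2)
      dmin <- pmin(dmin, dj)
    }
    idx <- c(idx, cand[which.max(dmin)])
  }
  sort(idx)
}

# Nystrom spectral decomposition of the kernel restricted to `inducing`.
# Returns orthonormal Psi (V x L') and positive eigenvalues, with the
# numerically zero tail trimmed (lambda < tol_rel * lambda_1).
nystrom_decompose <- function(domain, kernel, inducing, tol_rel = 1e-10) {
  stopifnot(inherits(domain, "bsir_domain"), inherits(kernel, "bsir_kernel"))
  inducing <- as.integer(inducing)
  if (anyDuplicated(inducing) || any(inducing < 1L) || any(inducing > domain$V))
    stop("inducing indices must be distinct members of the domain")
  S <- domain$coords
  SL <- S[inducing, , drop = FALSE]
  KL <- gram_matrix(SL, kernel = kernel)
  KVL <- gram_matrix(S, SL, kernel = kernel)
  # Cholesky with escalating jitter
  jit <- max(kernel$jitter, 1e-8)
  U <- NULL
  repeat {
    U <- tryCatch(chol(KL + diag(jit, nrow(KL))), error = function(e) NULL)
    if (!is.null(U)) break
    jit <- jit * 10
    if (jit > 1e-4)
      stop(sprintf(
        "Cholesky of the inducing-point Gram matrix failed up to jitter 1e-4 (rcond ~ %.2e)",
        rcond(KL)))
  }
  # K_L = R R^T with R lower triangular = t(U); Ktilde = K_VL R^{-T}
  Ktilde <- t(forwardsolve(t(U), t(KVL)))
  sv <- svd(Ktilde, nv = 0)
  lambda <- sv$d^2
  keep <- lambda > tol_rel * lambda[1]
  list(Psi = sv$u[, keep, drop = FALSE], lambda = lambda[keep],
       inducing = inducing, jitter_used = jit)
}

#' Low-rank Gaussian-process basis via the Nystrom method
#'
#' Builds the rank-`L` spectral approximation \eqn{K_V \approx \Psi \Lambda
#' \Psi^\top} of the kernel Gram matrix from `L` inducing points
#' (Cholesky of the inducing Gram matrix, whitening of the cross Gram
#' matrix, then SVD), plus a separate, smaller rank-`L_eta` basis
#' \eqn{\tilde\Psi \tilde\Lambda \tilde\Psi^\top} for participant-level
#' deviations, and the projection operators used by the reparameterized
#' regression model:
#' \deqn{\Phi = \Psi \Lambda^{-1/2}, \qquad
#'       \Phi_\eta = \tilde\Lambda^{1/2} \tilde\Psi^\top \Psi \Lambda^{-1/2}.}
#'
#' @param domain a [spatial_domain()].
#' @param kernel a [matern_kernel()].
#' @param L number of basis functions; trailing numerically zero
#'   eigenvalues are trimmed, which may reduce the effective `L`.
#' @param L_eta basis size for participant deviations; default
#'   `ceiling(0.1 * L)`, a fraction that is typically sufficient for
#'   individual variation while limiting overfitting.
#' @param method,seed inducing-point selection, see [select_inducing()].
#' @return Object of class `"bsir_basis"`: `Psi`, `lambda`, `Psi_eta`,
#'   `lambda_eta`, `Phi` (\eqn{V\times L}), `B` (\eqn{\Psi\Lambda^{1/2}},
#'   the reconstruction operator), `B_eta`, `Phi_eta`, `h` (projection of
#'   the all-ones image, \eqn{1^\top\Phi}), `g` (\eqn{1^\top\Psi\Lambda^{1/2}}),
#'   inducing index sets, and the domain/kernel used.
#' @examples
#' dom <- spatial_domain(as.matrix(expand.grid(1:10, 1:10)))
#' b <- lowrank_basis(dom, matern_kernel(0.3), L = 20, seed = 1)
#' max(abs(crossprod(b$Psi) - diag(ncol(b$Psi))))  # orthonormal columns
#' @export
lowrank_basis <- function(domain, kernel, L, L_eta = NULL,
                          method = c("kmeans", "random"), seed = 1L) {
  method <- match.arg(method)
  if (is.null(L_eta)) L_eta <- max(1L, ceiling(0.1 * L))
  if (L_eta > L) stop("L_eta must not exceed L")
  ind <- select_inducing(domain, L, method, seed = seed)
  dec <- nystrom_decompose(domain, kernel, ind)
  if (ncol(dec$Psi) < L)
    message(sprintf("trimmed %d numerically zero eigenvalues; effective L = %d",
                    L - ncol(dec$Psi), ncol(dec$Psi)))
  ind_eta <- select_inducing(domain, L_eta, method, seed = seed + 1L)
  dec_eta <- nystrom_decompose(domain, kernel, ind_eta)
  build_basis(domain, kernel, dec, dec_eta)
}

# Assemble a bsir_basis from two spectral decompositions.
build_basis <- function(domain, kernel, dec, dec_eta) {
  Psi <- dec$Psi; lambda <- dec$lambda
  Psi_e <- dec_eta$Psi; lambda_e <- dec_eta$lambda
  if (any(lambda <= 0) || any(lambda_e <= 0))
    stop("nonpositive eigenvalue; should have been trimmed upstream")
  Phi <- sweep(Psi, 2, sqrt(lambda), "/")
  B <- sweep(Psi, 2, sqrt(lambda), "*")
  B_eta <- sweep(Psi_e, 2, sqrt(lambda_e), "*")
  Phi_eta <- crossprod(B_eta, Phi)           # L_eta x L
  structure(list(
    domain = domain, kernel = kernel,
    L = length(lambda), L_eta = length(lambda_e),
    inducing = dec$inducing, inducing_eta = dec_eta$inducing,
    Psi = Psi, lambda = lambda, Psi_eta = Psi_e, lambda_eta = lambda_e,
    Phi = Phi, B = B, B_eta = B_eta, Phi_eta = Phi_eta,
    h = colSums(Phi), g = colSums(B)),
    class = "bsir_basis")
}

#' @export
print.bsir_basis <- function(x, ...) {
  cat(sprintf("Low-rank GP basis: V = %d, L = %d, L_eta = %d\n",
              x$domain$V, x$L, x$L_eta))
  cat(sprintf("  leading eigenvalues: %s ...\n",
              paste(signif(utils::head(x$lambda, 4), 3), collapse = ", ")))
  invisible(x)
}
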