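#' Squared-exponential Gram matrix
#'
#' `k(x, x') = exp(-||x - x'||^2 / (2 l^2))`, the input kernel of the
#' stage-2 multi-output GP.
#'
#' @param points matrix of input locations (rows).
#' @param ell positive lengthscale.
#' @return Symmetric PSD matrix with unit diagonal.
#' @export
squared_exponential_gram <- function(points, ell) {
  if (!is.numeric(ell) || length(ell) != 1L || ell <= 0) {
    stop("lengthscale must be a positive scalar")
  }
  D2 <- as.matrix(dist(points))^2
  exp(-D2 / (2 * ell^2))
}

#' Matern 3/2 Gram matrix
#'
#' Input kernel used for the stage-1 per-experiment interaction GP; rougher
#' than the squared exponential, so the latent surface can track rapid
#' changes in the interaction.
#'
#' @param points matrix of input locations (rows).
#' @param ell positive lengthscale.
#' @param amp2 marginal variance (amplitude squared).
#' @return Symmetric PSD matrix.
#' @export
matern32_gram <- function(points, ell, amp2 = 1) {
  stopifnot(ell > 0, amp2 >= 0)
  D <- as.matrix(dist(points))
  r <- sqrt(3) * D / ell
  amp2 * (1 + r) * exp(-r)
}

#' Low-rank free-form covariance
#'
#' `K = L L^T + diag(v)` -- the "free-form" output covariance used for both
#' the drug-combination and the cell-line kernels, with every entry of `L`
#' and `v` learned from data.
#'
#' @param L factor matrix `q x r`.
#' @param v positive vector of length `q`.
#' @return Symmetric positive-definite `q x q` matrix.
#' @export
lowrank_gram <- function(L, v) {
  L <- as.matrix(L)
  stopifnot(length(v) == nrow(L), all(v > 0))
  tcrossprod(L) + diag(v, nrow(L))
}

#' Permutation matrices encoding the pair swap
#'
#' `P` (size `2 N_d`) swaps the canonical and reversed pair blocks;
#' `P_tilde` (size `k^2`) realises the grid reflection
#' `(x1, x2) -> (x2, x1)`. Both are symmetric involutions.
#'
#' @param N_d number of canonical drug pairs.
#' @param grid a [common_grid()].
#' @return A list with `P`, `P_tilde`, and the underlying index
#'   permutations `perm_pairs`, `perm_grid`.
#' @export
build_permutations <- function(N_d, grid) {
  stopifnot(N_d >= 1L, inherits(grid, "common_grid"))
  perm_grid <- grid_reflection(grid)
  # sanity: involution and actual reflection of coordinates
  if (!identical(perm_grid[perm_grid], seq_along(perm_grid)) ||
      max(abs(grid$points[perm_grid, , drop = FALSE] -
              grid$points[, c(2, 1), drop = FALSE])) > 0) {
    stop("grid is not closed under coordinate reflection")
  }
  perm_pairs <- c(N_d + seq_len(N_d), seq_len(N_d))
  P <- diag(2 * N_d)[perm_pairs, , drop = FALSE]
  P_tilde <- diag(length(perm_grid))[perm_grid, , drop = FALSE]
  list(P = P, P_tilde = P_tilde, perm_pairs = perm_pairs, perm_grid = perm_grid)
}

#' Stage-2 kernel hyperparameters
#'
#' Container for everything trained by marginal likelihood: the input
#' lengthscale, the low-rank factors of the drug-combination and cell-line
#' covariances, and the shared observation noise.
#'
#' @param ell input-kernel lengthscale (> 0).
#' @param Lc,vc cell-line covariance factors (`N_c x r_c`, positive `N_c`).
#' @param Ld,vd drug-combination covariance factors (`2 N_d x r_d`,
#'   positive `2 N_d`).
#' @param sigma2 shared observation noise variance (> 0); this global term
#'   couples the outputs and avoids the autokrigability degeneracy of
#'   noiseless multi-output GPs.
#' @return A `kernel_hyperparams` object.
#' @export
kernel_hyperparams <- function(ell, Lc, vc, Ld, vd, sigma2) {
  Lc <- as.matrix(Lc); Ld <- as.matrix(Ld)
  stopifnot(ell > 0, sigma2 > 0, all(vc > 0), all(vd > 0),
            length(vc) == nrow(Lc), length(vd) == nrow(Ld),
            nrow(Ld) %% 2L == 0L)
  structure(list(ell = ell, Lc = Lc, vc = as.numeric(vc),
                 Ld = Ld, vd = as.numeric(vd), sigma2 = sigma2),
            class = "kernel_hyperparams")
}

#' @export
print.kernel_hyperparams <- function(x, ...) {
  cat(sprintf(paste0("<kernel_hyperparams> ell = %.4g, sigma2 = %.4g, ",
                     "K_c: %d x %d (rank %d), K_d: %d x %d (rank %d)\n"),
              x$ell, x$sigma2, nrow(x$Lc), nrow(x$Lc), ncol(x$Lc),
              nrow(x$Ld), nrow(x$Ld), ncol(x$Ld)))
  invisible(x)
}

#' Assemble the full stage-2 covariance operator
#'
#' The permutation-invariant covariance is
#' `K = K_c ox [(K_d + P K_d P) ox K_x + (P K_d + K_d P) ox Pt K_x]`,
#' exposed as a linear operator whose matrix-vector product is a sum of two
#' triple-Kronecker products; memory is `O(N_c^2 + (2 N_d)^2 + n^2)`. The
#' `non_invariant` ablation is the plain Kronecker product
#' `K = K_c ox K_d ox K_x`.
#'
#' @param h a [kernel_hyperparams()].
#' @param grid a [common_grid()].
#' @param variant `"invariant"` (default) or `"non_invariant"`.
#' @return A `piicm_kernel` operator object with `$matvec(w)`, sizes, and
#'   the factor matrices.
#' @export
assemble_full_covariance <- function(h, grid, variant = c("invariant", "non_invariant")) {
  variant <- match.arg(variant)
  stopifnot(inherits(h, "kernel_hyperparams"), inherits(grid, "common_grid"))
  Kc <- lowrank_gram(h$Lc, h$vc)
  Kd <- lowrank_gram(h$Ld, h$vd)
  Kx <- squared_exponential_gram(grid$points, h$ell)
  N_d <- nrow(Kd) / 2L
  perms <- build_permutations(N_d, grid)
  n <- grid$k^2
  N <- nrow(Kc) * nrow(Kd) * n
  pg <- perms$perm_grid; pp <- perms$perm_pairs
  PKx <- Kx[pg, , drop = FALSE]                  # Pt %*% Kx (symmetric here)
  PKdP <- Kd[pp, pp, drop = FALSE]
  A1 <- Kd + PKdP                                # pairs with aligned ordering
  A2 <- Kd[pp, , drop = FALSE] + Kd[, pp, drop = FALSE]  # P Kd + Kd P
  op <- list(variant = variant, Kc = Kc, Kd = Kd, Kx = Kx,
             A1 = A1, A2 = A2, PKx = PKx, perms = perms,
             n = n, N_d = N_d, N_c = nrow(Kc), N = N, grid = grid)
  op$matvec <- if (variant == "invariant") {
    function(w) {
      if (length(w) != N) stop("length mismatch: expected ", N, ", got ", length(w))
      kron3_matvec(Kc, A1, Kx, w) + kron3_matvec(Kc, A2, PKx, w)
    }
  } else {
    function(w) {
      if (length(w) != N) stop("length mismatch: expected ", N, ", got ", length(w))
      kron3_matvec(Kc, Kd, Kx, w)
    }
  }
  structure(op, class = "piicm_kernel")
}

#' Structured matrix-vector product
#'
#' @param K a `piicm_kernel` operator.
#' @param w vector of length `N`.
#' @return `K %*% w` computed without materializing `K`.
#' @export
structured_matvec <- function(K, w) {
  stopifnot(inherits(K, "piicm_kernel"))
  K$matvec(w)
}

#' Dense materialization of the covariance (testing / small instances)
#'
#' @param K a `piicm_kernel` operator.
#' @param cap refuse to materialize above this `N` (default 5000).
#' @return Dense `N x N` matrix.
#' @export
dense_covariance <- function(K, cap = 5000L) {
  stopifnot(inherits(K, "piicm_kernel"))
  if (K$N > cap) stop("refusing to materialize N = ", K$N, " > cap = ", cap)
  if (K$variant == "invariant") {
    K$Kc %x% (K$A1 %x% K$Kx + K$A2 %x% K$PKx)
  } else {
    K$Kc %x% K$Kd %x% K$Kx
  }
}

#' Eigenvalues of the assembled covariance
#'
#' For the invariant kernel, uses the identity that the positive spectrum of
#' `K` is twice the positive spectrum of the Kronecker factor
#' `K_c ox (P K_d + K_d P) ox Pt K_x`, computed as cross-products of the
#' factor spectra; all remaining eigenvalues are zero. For the
#' `non_invariant` variant the spectrum is the plain Kronecker
#' cross-product. Eigenvalues with `|lambda| <= tol * max` are treated as
#' zero.
#'
#' @param K a `piicm_kernel` operator.
#' @param tol relative cutoff for the positive-part operation
#'   (default 1e-10).
#' @return Numeric vector of `N` eigenvalues, sorted decreasing.
#' @export
proposition1_eigenvalues <- function(K, tol = 1e-10) {
  stopifnot(inherits(K, "piicm_kernel"))
  check_psd <- function(A, name) {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-12)) {
      stop("factor ", name, " is not PSD (min eigenvalue ", min(ev), ")")
    }
    ev
  }
  if (K$variant == "non_invariant") {
    ec <- check_psd(K$Kc, "K_c")
    ed <- check_psd(K$Kd, "K_d")
    ex <- check_psd(K$Kx, "K_x")
    lam <- as.vector(outer(as.vector(outer(ex, ed)), ec))
    return(sort(pmax(lam, 0), decreasing = TRUE))
  }
  check_psd(K$Kd, "K_d")
  ec <- check_psd(K$Kc, "K_c")
  # A2 = P Kd + Kd P and Pt Kx are both symmetric (the grid kernel is
  # reflection-invariant), but indefinite; only their positive cross-products
  # survive in the spectrum of K, doubled.
  e2 <- eigen((K$A2 + t(K$A2)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sP <- (K$PKx + t(K$PKx)) / 2
  ex <- eigen(sP, symmetric = TRUE, only.values = TRUE)$values
  lam <- as.vector(outer(as.vector(outer(ex, e2)), ec))
  cutoff <- tol * max(abs(lam), 1e-300)
  pos <- 2 * lam[lam > cutoff]
  out <- c(sort(pos, decreasing = TRUE), rep(0, K$N - length(pos)))
  out
}
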