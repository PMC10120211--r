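#' Training configuration for the stage-2 multi-output GP
#'
#' @param learning_rate Adam learning rate (default 0.1).
#' @param cg_tol_factor CG tolerance is `cg_tol_factor * M / N` relative to
#'   the preconditioned right-hand side norm (default 0.1); an absolute
#'   override is available via `cg_tol`.
#' @param cg_tol optional absolute relative tolerance for CG, overriding the
#'   `M/N`-scaled default (used by oracle tests).
#' @param cg_maxit maximum CG iterations (default 1000).
#' @param max_steps maximum optimizer steps (default 300).
#' @param patience stop after this many steps without relative improvement
#'   `rel_tol` in the best marginal likelihood (default 50).
#' @param rel_tol relative improvement threshold (default 1e-5).
#' @param r_c,r_d ranks of the cell-line and drug-combination covariances.
#' @param variant `"invariant"` or the `"non_invariant"` ablation.
#' @param use_measurement_error if `FALSE`, stage-1 variances of observed
#'   entries are set to zero (equal weighting ablation); masked dummy
#'   entries keep their large noise.
#' @param fd_step central finite-difference step for gradients of the
#'   marginal likelihood (default 1e-3; kept well above the tightened CG
#'   tolerance used during training).
#' @param seed integer seed for initialization.
#' @return A `piicm_config` list.
#' @export
piicm_config <- function(learning_rate = 0.1, cg_tol_factor = 0.1,
                         cg_tol = NULL, cg_maxit = 1000L,
                         max_steps = 300L, patience = 50L, rel_tol = 1e-5,
                         r_c = 1L, r_d = 1L,
                         variant = c("invariant", "non_invariant"),
                         use_measurement_error = TRUE,
                         fd_step = 1e-3, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(learning_rate > 0, cg_tol_factor > 0, r_c >= 1L, r_d >= 1L)
  structure(list(learning_rate = learning_rate, cg_tol_factor = cg_tol_factor,
                 cg_tol = cg_tol, cg_maxit = cg_maxit, max_steps = max_steps,
                 patience = patience, rel_tol = rel_tol,
                 r_c = as.integer(r_c), r_d = as.integer(r_d),
                 variant = variant,
                 use_measurement_error = use_measurement_error,
                 fd_step = fd_step, seed = as.integer(seed)),
            class = "piicm_config")
}

#' Initialize stage-2 hyperparameters
#'
#' Lengthscale and noise start at `softplus(0) = log 2`; the diagonal
#' inflations `v` are softplus transforms of standard-normal draws; the
#' low-rank factor entries are `N(0, 0.1^2)`, so both output covariances
#' start near-diagonal.
#'
#' @param N_c,N_d numbers of cell lines and canonical drug pairs.
#' @param r_c,r_d covariance ranks.
#' @param seed integer seed; the same seed reproduces the initialization
#'   bit-exactly.
#' @return A [kernel_hyperparams()].
#' @export
initialize_parameters <- function(N_c, N_d, r_c, r_d, seed = 1L) {
  stopifnot(r_c >= 1L, r_d >= 1L, N_c >= 1L, N_d >= 1L)
  set.seed(as.integer(seed))
  ell <- softplus(0)
  sigma <- softplus(0)
  Lc <- matrix(rnorm(N_c * r_c, sd = 0.1), N_c, r_c)
  vc <- softplus(rnorm(N_c))
  Ld <- matrix(rnorm(2 * N_d * r_d, sd = 0.1), 2 * N_d, r_d)
  vd <- softplus(rnorm(2 * N_d))
  kernel_hyperparams(ell = ell, Lc = Lc, vc = vc, Ld = Ld, vd = vd,
                     sigma2 = sigma^2)
}

#' Observation-noise model for the masked system
#'
#' `Sigma = diag(vec(S) + sigma2)`; masked dummy entries carry the dominant
#' `1/epsilon` noise so that preconditioned CG reproduces the reduced
#' observed-data system.
#'
#' @param screen a `screen_matrices` object.
#' @param sigma2 shared noise variance.
#' @param use_measurement_error if `FALSE`, observed `S` entries are
#'   ignored (set to zero).
#' @return A list with `Sigma_diag` (length `N`) and `observed` (logical).
#' @export
noise_model <- function(screen, sigma2, use_measurement_error = TRUE) {
  stopifnot(inherits(screen, "screen_matrices"), sigma2 > 0)
  S <- as.vector(screen$S)
  obs <- as.vector(screen$mask)
  if (!use_measurement_error) S[obs] <- 0
  list(Sigma_diag = S + sigma2, observed = obs)
}

#' Masked preconditioned conjugate-gradient solve
#'
#' Solves `(K + Sigma) alpha = rhs` through the preconditioned system
#' `C (K + Sigma) C q = C rhs` with `C = Sigma^{-1/2}`, `alpha = C q`. With
#' dummy-masked entries the restriction of `alpha` to observed indices
#' matches the dense solve of the reduced system `(K_M + Sigma_M) q = z`.
#'
#' @param K a `piicm_kernel` operator (or any function `w -> K w`).
#' @param noise a [noise_model()] list.
#' @param rhs right-hand side, length `N`.
#' @param tol relative tolerance on the preconditioned residual.
#' @param maxit maximum iterations.
#' @return List with `solution` (alpha), `iterations`, `residual`.
#' @export
preconditioned_cg_solve <- function(K, noise, rhs, tol = 1e-10, maxit = 1000L) {
  mv <- if (is.function(K)) K else K$matvec
  d <- noise$Sigma_diag
  stopifnot(all(d > 0), length(rhs) == length(d))
  Cd <- 1 / sqrt(d)
  if (all(rhs == 0)) {
    return(list(solution = rhs, iterations = 0L, residual = 0))
  }
  Amv <- function(q) Cd * (mv(Cd * q)) + q       # C K C + I
  b <- Cd * rhs
  bnorm <- sqrt(sum(b^2))
  q <- numeric(length(b))
  r <- b
  p <- r
  rs <- sum(r^2)
  it <- 0L
  while (sqrt(rs) / bnorm > tol && it < maxit) {
    Ap <- Amv(p)
    a <- rs / sum(p * Ap)
    q <- q + a * p
    r <- r - a * Ap
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  res <- sqrt(rs) / bnorm
  if (res > tol) {
    stop(sprintf("CG failed to converge in %d iterations (relative residual %.3e > %.3e)",
                 it, res, tol))
  }
  list(solution = Cd * q, iterations = it, residual = res)
}

# eigenvalue-based approximation of log|K_M + Sigma_M|: the spectrum of K
# (exact, via the Kronecker identity) is scaled by M/N, its top-M values are
# paired with the sorted observed noise entries (largest eigenvalue with
# smallest noise), and the pairing is exact in the fully observed
# homoskedastic case.
approx_logdet <- function(K, noise, tol = 1e-10) {
  obs <- noise$observed
  M <- sum(obs)
  if (M == 0L) return(0)
  lam <- proposition1_eigenvalues(K, tol = tol)     # sorted decreasing
  lam_top <- lam[seq_len(M)] * (M / K$N)
  s_obs <- sort(noise$Sigma_diag[obs])              # increasing
  sum(log(lam_top + s_obs))
}

#' Marginal log-likelihood of the stage-2 model
#'
#' Up to an additive constant:
#' `- [ vec(Z)^T (K + Sigma)^{-1} vec(Z) + log |K + Sigma| ]`, with the
#' quadratic form computed by masked preconditioned CG over the observed
#' entries and the log-determinant by the scaled-eigenvalue approximation
#' (exact when fully observed with isotropic noise).
#'
#' @param h a [kernel_hyperparams()].
#' @param screen a `screen_matrices` object.
#' @param config a [piicm_config()].
#' @return Scalar marginal log-likelihood (up to a constant).
#' @export
log_marginal_likelihood <- function(h, screen, config = piicm_config()) {
  K <- assemble_full_covariance(h, screen$grid, variant = config$variant)
  noise <- noise_model(screen, h$sigma2, config$use_measurement_error)
  obs <- noise$observed
  if (!any(obs)) return(0)
  z <- as.vector(screen$Z)
  tol <- config$cg_tol %||% (config$cg_tol_factor * screen$M / screen$N)
  sol <- preconditioned_cg_solve(K, noise, z, tol = tol, maxit = config$cg_maxit)
  quad <- sum(z[obs] * sol$solution[obs])
  ld <- approx_logdet(K, noise)
  val <- -(quad + ld)
  if (!is.finite(val)) {
    stop("non-finite marginal likelihood (quad = ", quad, ", logdet = ", ld, ")")
  }
  val
}

# pack/unpack hyperparameters to an unconstrained vector (softplus for all
# positive quantities; sigma is parameterized on the standard-deviation
# scale as in the softplus(0) initialization)
pack_hyperparams <- function(h) {
  c(inv_softplus(h$ell), inv_softplus(sqrt(h$sigma2)),
    as.vector(h$Lc), inv_softplus(h$vc),
    as.vector(h$Ld), inv_softplus(h$vd))
}

unpack_hyperparams <- function(theta, N_c, N_d, r_c, r_d) {
  i <- 2L
  ell <- softplus(theta[1L]); sigma <- softplus(theta[2L])
  Lc <- matrix(theta[i + seq_len(N_c * r_c)], N_c, r_c); i <- i + N_c * r_c
  vc <- softplus(theta[i + seq_len(N_c)]); i <- i + N_c
  Ld <- matrix(theta[i + seq_len(2 * N_d * r_d)], 2 * N_d, r_d); i <- i + 2 * N_d * r_d
  vd <- softplus(theta[i + seq_len(2 * N_d)])
  kernel_hyperparams(ell, Lc, vc, Ld, vd, sigma^2)
}

#' Train the stage-2 multi-output GP by marginal likelihood
#'
#' Gradient ascent with Adam on the (approximate) marginal log-likelihood;
#' gradients are central finite differences on the unconstrained
#' (softplus-reparameterized) parameter vector. Training stops when the
#' best-seen likelihood has not improved by `rel_tol` (relatively) for
#' `patience` consecutive steps.
#'
#' @param screen a `screen_matrices` object.
#' @param config a [piicm_config()].
#' @param init optional [kernel_hyperparams()] overriding the seeded
#'   initialization.
#' @return A `piicm_model`: best-seen `hyperparams`, the likelihood `trace`,
#'   a `converged` flag, and the `config`.
#' @export
piicm_train <- function(screen, config = piicm_config(), init = NULL) {
  N_c <- length(screen$cell_lines)
  N_d <- nrow(screen$extended_pairs) / 2L
  if (N_c < 1L || N_d < 1L) stop("degenerate screen: need >= 1 cell line and pair")
  h0 <- init %||% initialize_parameters(N_c, N_d, config$r_c, config$r_d,
                                        seed = config$seed)
  theta <- pack_hyperparams(h0)
  # finite-difference gradients need CG residuals far below the FD step;
  # the M/N-scaled tolerance is only appropriate when differentiating
  # through the solver itself, so tighten it here
  fd_config <- config
  fd_config$cg_tol <- config$cg_tol %||%
    min(1e-6, config$cg_tol_factor * screen$M / max(screen$N, 1L))
  fd_config$cg_maxit <- max(config$cg_maxit, 5000L)
  z <- as.vector(screen$Z)
  obs <- as.vector(screen$mask)
  unpack <- function(th) unpack_hyperparams(th, N_c, N_d, config$r_c,
                                            config$r_d)
  # one evaluation returns the objective and the CG solution alpha, which
  # the gradient below reuses so each optimizer step needs a single solve
  evaluate <- function(th) {
    h <- unpack(th)
    if (!any(obs)) return(list(val = 0, alpha = numeric(screen$N), h = h))
    K <- assemble_full_covariance(h, screen$grid, variant = config$variant)
    noise <- noise_model(screen, h$sigma2, config$use_measurement_error)
    tol <- fd_config$cg_tol
    sol <- preconditioned_cg_solve(K, noise, z, tol = tol,
                                   maxit = fd_config$cg_maxit)
    quad <- sum(z[obs] * sol$solution[obs])
    ld <- approx_logdet(K, noise)
    val <- -(quad + ld)
    if (!is.finite(val)) stop("non-finite marginal likelihood during training")
    list(val = val, alpha = sol$solution, h = h)
  }
  # d/dtheta [z^T A^-1 z] = -alpha^T (dA/dtheta) alpha with alpha = A^-1 z,
  # so the quadratic-form gradient needs only operator differences; the
  # log-determinant term involves no solve and is finite-differenced whole
  gradient <- function(th, alpha, eps = config$fd_step) {
    if (!any(obs)) return(numeric(length(th)))
    g <- numeric(length(th))
    for (j in seq_along(th)) {
      tp <- th; tp[j] <- tp[j] + eps
      tm <- th; tm[j] <- tm[j] - eps
      hp <- unpack(tp); hm <- unpack(tm)
      Kp <- assemble_full_covariance(hp, screen$grid, variant = config$variant)
      Km <- assemble_full_covariance(hm, screen$grid, variant = config$variant)
      dK_alpha <- (Kp$matvec(alpha) - Km$matvec(alpha)) / (2 * eps)
      dSigma <- (hp$sigma2 - hm$sigma2) / (2 * eps)
      dquad <- -(sum(alpha * dK_alpha) + dSigma * sum(alpha^2))
      dld <- (approx_logdet(Kp, noise_model(screen, hp$sigma2,
                                            config$use_measurement_error)) -
              approx_logdet(Km, noise_model(screen, hm$sigma2,
                                            config$use_measurement_error))) /
        (2 * eps)
      g[j] <- -(dquad + dld)
    }
    g
  }
  # Adam, ascent
  lr <- config$learning_rate
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  trace <- numeric(0)
  best <- -Inf; best_theta <- theta; stall <- 0L
  nonfinite <- 0L
  for (step in seq_len(config$max_steps)) {
    ev <- tryCatch(evaluate(theta), error = function(e) NULL)
    if (is.null(ev) || !is.finite(ev$val)) {
      nonfinite <- nonfinite + 1L
      if (nonfinite >= 5L) stop("optimizer diverged: repeated non-finite likelihood")
      theta <- best_theta + rnorm(length(theta), sd = 1e-3)
      next
    }
    val <- ev$val
    trace <- c(trace, val)
    improved <- !is.finite(best) || val > best + config$rel_tol * max(1, abs(best))
    if (improved) {
      best <- val; best_theta <- theta; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    g <- gradient(theta, ev$alpha)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^step)
    vhat <- v / (1 - b2^step)
    theta <- theta + lr * mhat / (sqrt(vhat) + eps_adam)
  }
  structure(list(hyperparams = unpack_hyperparams(best_theta, N_c, N_d,
                                                  config$r_c, config$r_d),
                 trace = trace, converged = stall >= config$patience,
                 best = best, config = config,
                 layout = list(N_c = N_c, N_d = N_d,
                               cell_lines = screen$cell_lines,
                               extended_pairs = screen$extended_pairs,
                               grid = screen$grid)),
            class = "piicm_model")
}

#' @export
print.piicm_model <- function(x, ...) {
  cat(sprintf("<piicm_model> %s variant, %d optimizer steps, best logL = %.4f\n",
              x$config$variant, length(x$trace), x$best))
  print(x$hyperparams)
  invisible(x)
}

#' Predictive posterior of the latent multi-output GP
#'
#' Predicts the latent field of every output simultaneously by GP
#' imputation: `Zhat = K (K + Sigma)^{-1} vec(Z)` (a single CG solve reused
#' across all targets). Predictive variances, when requested, use one extra
#' CG solve per target grid point:
#' `V = k** - k*^T (K + Sigma)^{-1} k*`.
#'
#' @param model a `piicm_model` (or a [kernel_hyperparams()] if `layout`
#'   information is supplied through `screen`).
#' @param screen the training `screen_matrices`.
#' @param targets optional data.frame with `cell_line`, `drug_a`, `drug_b`;
#'   by default predictions for all columns are returned. Targets may use
#'   either drug ordering; reversed orderings address the reflected column.
#' @param want_variance compute per-point predictive variances for the
#'   targets (opt-in; `n` extra CG solves per target).
#' @return A list with `Zhat` (full `n x (N_c 2N_d)` matrix of predictive
#'   means) and, for each target, `zeta_mean` (and `zeta_var`).
#' @export
predictive_posterior <- function(model, screen, targets = NULL,
                                 want_variance = FALSE) {
  h <- if (inherits(model, "piicm_model")) model$hyperparams else model
  config <- if (inherits(model, "piicm_model")) model$config else piicm_config()
  K <- assemble_full_covariance(h, screen$grid, variant = config$variant)
  noise <- noise_model(screen, h$sigma2, config$use_measurement_error)
  z <- as.vector(screen$Z)
  tol <- config$cg_tol %||% min(1e-8, config$cg_tol_factor * screen$M / screen$N)
  sol <- preconditioned_cg_solve(K, noise, z, tol = tol,
                                 maxit = max(config$cg_maxit, 5000L))
  alpha <- sol$solution
  Zhat <- matrix(K$matvec(alpha), nrow = screen$grid$k^2)
  out <- list(Zhat = Zhat)
  if (!is.null(targets)) {
    n <- screen$grid$k^2
    preds <- vector("list", nrow(targets))
    for (i in seq_len(nrow(targets))) {
      cl <- targets$cell_line[i]
      if (!cl %in% screen$cell_lines) {
        stop("cold-start error: unknown cell line '", cl,
             "' (the free-form kernels carry no covariates)")
      }
      j <- tryCatch(
        screen_column(screen, cl, targets$drug_a[i], targets$drug_b[i]),
        error = function(e) stop("cold-start error: unknown drug pair (",
                                 targets$drug_a[i], ", ", targets$drug_b[i], ")"))
      pred <- list(cell_line = cl, drug_a = targets$drug_a[i],
                   drug_b = targets$drug_b[i],
                   zeta_mean = Zhat[, j])
      if (want_variance) {
        vv <- numeric(n)
        for (g in seq_len(n)) {
          t_idx <- (j - 1L) * n + g
          kstar <- K$matvec(as.numeric(seq_len(K$N) == t_idx))
          ssol <- preconditioned_cg_solve(K, noise, kstar, tol = tol,
                                          maxit = max(config$cg_maxit, 5000L))
          vv[g] <- kstar[t_idx] - sum(kstar * ssol$solution)
        }
        pred$zeta_var <- pmax(vv, 0)
      }
      preds[[i]] <- pred
    }
    out$targets <- preds
  }
  out
}
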