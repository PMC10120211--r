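#' Priors for the stage-1 dose-response model
#'
#' Weakly-informative defaults respecting the structural constraints: the
#' lower asymptote gets a mild push towards full kill, slopes and transform
#' parameters are log-normal, GP amplitude is half-normal on the scale of
#' the bounded surface, and the heteroskedastic noise parameters keep
#' residual standard deviations in the few-percent range typical of
#' normalized viability assays. All values are adjustable; the model code
#' touches them only through this object.
#'
#' @param l_shape1,l_shape2 Beta prior on the lower asymptote.
#' @param s_meanlog,s_sdlog log-normal prior on the slope.
#' @param m_mean,m_sd normal prior on the EC50 (unit-box scale).
#' @param b_meanlog,b_sdlog log-normal prior on the transform shapes.
#' @param amp_sd half-normal prior sd on the GP amplitude.
#' @param ls_meanlog,ls_sdlog log-normal prior on the GP lengthscale.
#' @param sigma0_sd,c0_sd half-normal prior sds of the noise scale and
#'   offset in `sigma_i^2 = sigma0^2 (c0 + f(x_i))`.
#' @return A `stage1_priors` list.
#' @export
stage1_priors <- function(l_shape1 = 1, l_shape2 = 1.25,
                          s_meanlog = 0, s_sdlog = 1,
                          m_mean = 0.5, m_sd = 1,
                          b_meanlog = 0, b_sdlog = 0.5,
                          amp_sd = 1, ls_meanlog = 0, ls_sdlog = 0.5,
                          sigma0_sd = 0.1, c0_sd = 0.1) {
  structure(as.list(environment()), class = "stage1_priors")
}

#' Sampler settings for stage-1 fits
#'
#' Defaults give 4 chains of 1000 post-warmup
#' draws each (4000 total). Tests scale these down.
#'
#' @param chains number of chains.
#' @param warmup warmup iterations per chain (adaptation happens here).
#' @param draws retained post-warmup draws per chain.
#' @param seed global seed; the per-experiment seed is derived from it and
#'   the experiment key, so fits are reproducible and independent.
#' @param min_draws minimum total draws required by
#'   [latent_summary_on_grid()].
#' @param rhat_max convergence gate on split-Rhat.
#' @param priors a [stage1_priors()] object.
#' @return A `stage1_config` list.
#' @export
stage1_config <- function(chains = 4L, warmup = 1000L, draws = 1000L,
                          seed = 1L, min_draws = 100L, rhat_max = 1.05,
                          priors = stage1_priors()) {
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 min_draws = as.integer(min_draws), rhat_max = rhat_max,
                 priors = priors),
            class = "stage1_config")
}

# half-normal log-density plus the log-jacobian of the log transform
lp_halfnormal_log <- function(x, sd) dnorm(x, 0, sd, log = TRUE) + log(2) + log(x)

#' Fit one combination experiment with the Bayesian dose-response model
#'
#' Fits the model `y_i ~ N(f(x_i), sigma0^2 (c0 + f(x_i)))` with
#' `f = p0 + Delta`: log-logistic monotherapies (upper asymptote 1), Bliss
#' product `p0`, and interaction `Delta = g(z)` with a Matern-3/2 latent GP
#' `z` pushed through the bounding transform. Sampling combines elliptical
#' slice updates of the whitened latent field with adaptive random-walk
#' Metropolis on the remaining parameters.
#'
#' In `monotherapy_only` mode combination rows are ignored and only the
#' monotherapy parameters and noise are sampled, yielding draws of the
#' Bliss surface `p0*` on the common grid -- the quantity available for a
#' held-out experiment.
#'
#' @param records data.frame of viability records of one experiment
#'   (combination rows plus the two drugs' monotherapy rows).
#' @param k common grid size per axis (default 10).
#' @param mode `"full"` or `"monotherapy_only"`.
#' @param config a [stage1_config()].
#' @return A `stage1_fit` with parameter draws, latent/grid draws, and
#'   split-Rhat / effective-sample-size diagnostics (non-convergence is
#'   flagged, never silent).
#' @export
fit_single_experiment <- function(records, k = 10L,
                                  mode = c("full", "monotherapy_only"),
                                  config = stage1_config()) {
  mode <- match.arg(mode)
  pr <- config$priors
  records <- as.data.frame(records)
  mono <- records[is.na(records$drug_b), , drop = FALSE]
  comb <- records[!is.na(records$drug_b), , drop = FALSE]
  if (nrow(comb)) {
    d1 <- comb$drug_a[1L]; d2 <- comb$drug_b[1L]; cl <- comb$cell_line[1L]
  } else {
    ds <- sort(unique(mono$drug_a))
    if (length(ds) != 2L) stop("cannot determine drug pair from monotherapy rows")
    d1 <- ds[1L]; d2 <- ds[2L]; cl <- mono$cell_line[1L]
  }
  if (!all(c(d1, d2) %in% mono$drug_a)) {
    stop("monotherapy data required for both drugs (missing for ",
         paste(setdiff(c(d1, d2), mono$drug_a), collapse = ", "), ")")
  }
  if (mode == "full" && !nrow(comb)) stop("full mode requires combination data")
  scaling <- scale_to_common_grid(records, k)
  sc1 <- scaling$scalers[[d1]]; sc2 <- scaling$scalers[[d2]]
  grid <- scaling$grid
  m1 <- mono[mono$drug_a == d1, ]; m2 <- mono[mono$drug_a == d2, ]
  x_m1 <- sc1$scale(m1$conc_a); y_m1 <- m1$viability
  x_m2 <- sc2$scale(m2$conc_a); y_m2 <- m2$viability

  use_combo <- mode == "full"
  if (use_combo) {
    xc1 <- sc1$scale(comb$conc_a); xc2 <- sc2$scale(comb$conc_b)
    yc <- comb$viability
    loc_key <- paste(signif(xc1, 12), signif(xc2, 12))
    uloc <- !duplicated(loc_key)
    Xu <- cbind(xc1[uloc], xc2[uloc])
    loc_of_row <- match(loc_key, loc_key[uloc])
    nu <- nrow(Xu)
    Du <- as.matrix(dist(Xu))
    Dgu <- sqrt(outer(grid$points[, 1], Xu[, 1], "-")^2 +
                outer(grid$points[, 2], Xu[, 2], "-")^2)
    Dgg <- as.matrix(dist(grid$points))
  }

  par_names <- c("l1", "s1", "m1", "l2", "s2", "m2")
  if (use_combo) par_names <- c(par_names, "b1", "b2", "amp", "ls")
  par_names <- c(par_names, "sigma0", "c0")
  np <- length(par_names)

  to_constrained <- function(th) {
    p <- list(l1 = plogis(th[1L]), s1 = exp(th[2L]), m1 = th[3L],
              l2 = plogis(th[4L]), s2 = exp(th[5L]), m2 = th[6L])
    if (use_combo) {
      p$b1 <- exp(th[7L]); p$b2 <- exp(th[8L])
      p$amp <- exp(th[9L]); p$ls <- exp(th[10L])
    }
    p$sigma0 <- exp(th[np - 1L]); p$c0 <- exp(th[np])
    p
  }

  log_prior <- function(th, p) {
    lp <- dbeta(p$l1, pr$l_shape1, pr$l_shape2, log = TRUE) +
      log(p$l1) + log1p(-p$l1) +
      dbeta(p$l2, pr$l_shape1, pr$l_shape2, log = TRUE) +
      log(p$l2) + log1p(-p$l2) +
      dnorm(th[2L], pr$s_meanlog, pr$s_sdlog, log = TRUE) +
      dnorm(th[5L], pr$s_meanlog, pr$s_sdlog, log = TRUE) +
      dnorm(p$m1, pr$m_mean, pr$m_sd, log = TRUE) +
      dnorm(p$m2, pr$m_mean, pr$m_sd, log = TRUE) +
      lp_halfnormal_log(p$sigma0, pr$sigma0_sd) +
      lp_halfnormal_log(p$c0, pr$c0_sd)
    if (use_combo) {
      lp <- lp + dnorm(th[7L], pr$b_meanlog, pr$b_sdlog, log = TRUE) +
        dnorm(th[8L], pr$b_meanlog, pr$b_sdlog, log = TRUE) +
        lp_halfnormal_log(p$amp, pr$amp_sd) +
        dnorm(th[10L], pr$ls_meanlog, pr$ls_sdlog, log = TRUE)
    }
    lp
  }

  loglik_mono <- function(p) {
    f1 <- log_logistic_response(x_m1, p$l1, p$s1, p$m1)
    f2 <- log_logistic_response(x_m2, p$l2, p$s2, p$m2)
    v1 <- p$sigma0^2 * (p$c0 + f1); v2 <- p$sigma0^2 * (p$c0 + f2)
    sum(dnorm(y_m1, f1, sqrt(v1), log = TRUE)) +
      sum(dnorm(y_m2, f2, sqrt(v2), log = TRUE))
  }

  combo_surface <- function(p, z_rows) {
    p0 <- bliss_noninteraction(xc1, xc2, list(l = p$l1, s = p$s1, m = p$m1),
                               list(l = p$l2, s = p$s2, m = p$m2))
    p0 <- pmin(pmax(p0, 1e-12), 1 - 1e-12)
    p0 + interaction_transform(z_rows, p0, p$b1, p$b2)
  }

  loglik_combo <- function(p, z_u) {
    f <- combo_surface(p, z_u[loc_of_row])
    v <- p$sigma0^2 * (p$c0 + pmax(f, 0))
    sum(dnorm(yc, f, sqrt(v), log = TRUE))
  }

  chol_latent <- function(p) {
    r <- sqrt(3) * Du / p$ls
    Ku <- p$amp^2 * (1 + r) * exp(-r) + diag(1e-8, nu)
    t(chol(Ku))
  }

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    th <- c(qlogis(0.3), 0, 0.5, qlogis(0.3), 0, 0.5)
    if (use_combo) th <- c(th, 0, 0, log(0.5), log(0.5))
    th <- c(th, log(0.05), log(0.2))
    th <- th + rnorm(np, sd = 0.1)
    u <- if (use_combo) rnorm(nu) else NULL
    p <- to_constrained(th)
    L <- if (use_combo) chol_latent(p) else NULL
    z_u <- if (use_combo) as.vector(L %*% u) else NULL
    lp_cur <- log_prior(th, p) + loglik_mono(p) +
      if (use_combo) loglik_combo(p, z_u) else 0
    step <- rep(0.2, np)
    acc <- rep(0L, np); tries <- rep(0L, np)
    total <- config$warmup + config$draws
    keep_th <- matrix(NA_real_, config$draws, np,
                      dimnames = list(NULL, par_names))
    keep_z <- if (use_combo) matrix(NA_real_, config$draws, nu) else NULL
    for (it in seq_len(total)) {
      # adaptive random-walk Metropolis, one coordinate at a time
      for (j in seq_len(np)) {
        th_p <- th; th_p[j] <- th_p[j] + rnorm(1, sd = step[j])
        p_p <- to_constrained(th_p)
        L_p <- L; z_p <- z_u
        if (use_combo && j %in% c(9L, 10L)) {
          L_p <- chol_latent(p_p); z_p <- as.vector(L_p %*% u)
        }
        lp_p <- log_prior(th_p, p_p) + loglik_mono(p_p) +
          if (use_combo) loglik_combo(p_p, z_p) else 0
        tries[j] <- tries[j] + 1L
        if (is.finite(lp_p) && log(runif(1)) < lp_p - lp_cur) {
          th <- th_p; p <- p_p; L <- L_p; z_u <- z_p; lp_cur <- lp_p
          acc[j] <- acc[j] + 1L
        }
      }
      if (it <= config$warmup && it %% 50L == 0L) {
        rate <- acc / pmax(tries, 1L)
        step <- step * exp(pmin(0.5, pmax(-0.5, rate - 0.35)))
        acc[] <- 0L; tries[] <- 0L
      }
      # elliptical slice update of the whitened latent field
      if (use_combo) {
        nu_vec <- rnorm(nu)
        ll_u <- function(uu) loglik_combo(p, as.vector(L %*% uu))
        ll_cur <- loglik_combo(p, z_u)
        logy <- ll_cur + log(runif(1))
        ang <- runif(1, 0, 2 * pi)
        lo <- ang - 2 * pi; hi <- ang
        repeat {
          u_p <- u * cos(ang) + nu_vec * sin(ang)
          if (ll_u(u_p) > logy) break
          if (ang < 0) lo <- ang else hi <- ang
          ang <- runif(1, lo, hi)
          if (hi - lo < 1e-10) { u_p <- u; break }
        }
        u <- u_p
        z_u <- as.vector(L %*% u)
        lp_cur <- log_prior(th, p) + loglik_mono(p) + loglik_combo(p, z_u)
      }
      if (it > config$warmup) {
        d <- it - config$warmup
        keep_th[d, ] <- th
        if (use_combo) keep_z[d, ] <- z_u
      }
    }
    list(theta = keep_th, z = keep_z)
  }

  key <- list(cell_line = cl, drug_a = d1, drug_b = d2)
  chains <- lapply(seq_len(config$chains), function(ch) {
    run_chain(seed_from_key(c(unlist(key), ch), config$seed))
  })
  theta_draws <- do.call(rbind, lapply(chains, `[[`, "theta"))
  # constrained-scale draws for reporting
  cons <- t(apply(theta_draws, 1L, function(th) unlist(to_constrained(unname(th)))))
  rhat <- vapply(seq_len(np), function(j) {
    split_rhat(lapply(chains, function(c) c$theta[, j]))
  }, numeric(1))
  names(rhat) <- par_names
  ess <- vapply(seq_len(np), function(j) {
    ess_basic(lapply(chains, function(c) c$theta[, j]))
  }, numeric(1))
  names(ess) <- par_names

  fit <- list(mode = mode, key = key, grid = grid, scaling = scaling,
              par_names = par_names, draws = cons, draws_unconstrained = theta_draws,
              diagnostics = list(rhat = rhat, ess = ess,
                                 converged = all(is.finite(rhat)) &&
                                   max(rhat) < config$rhat_max),
              config = config)

  # posterior predictive of the latent GP and dose-response on the grid
  gx1 <- grid$points[, 1]; gx2 <- grid$points[, 2]
  ndr <- nrow(cons)
  p0_grid <- matrix(NA_real_, ndr, grid$k^2)
  for (i in seq_len(ndr)) {
    p0_grid[i, ] <- bliss_noninteraction(
      gx1, gx2,
      list(l = cons[i, "l1"], s = cons[i, "s1"], m = cons[i, "m1"]),
      list(l = cons[i, "l2"], s = cons[i, "s2"], m = cons[i, "m2"]))
  }
  fit$p0_grid_draws <- p0_grid
  if (use_combo) {
    z_draws <- do.call(rbind, lapply(chains, `[[`, "z"))
    fit$z_obs_draws <- z_draws
    ng <- grid$k^2
    z_grid <- matrix(NA_real_, ndr, ng)
    f_grid <- matrix(NA_real_, ndr, ng)
    for (i in seq_len(ndr)) {
      amp <- cons[i, "amp"]; ls <- cons[i, "ls"]
      ru <- sqrt(3) * Du / ls
      Ku <- amp^2 * (1 + ru) * exp(-ru) + diag(1e-8, nu)
      rgu <- sqrt(3) * Dgu / ls
      Kgu <- amp^2 * (1 + rgu) * exp(-rgu)
      rgg <- sqrt(3) * Dgg / ls
      Kgg <- amp^2 * (1 + rgg) * exp(-rgg)
      W <- Kgu %*% solve(Ku)
      mu <- as.vector(W %*% z_draws[i, ])
      Cv <- Kgg - W %*% t(Kgu)
      Cv <- (Cv + t(Cv)) / 2 + diag(1e-8, ng)
      z_grid[i, ] <- mu + as.vector(t(chol(Cv)) %*% rnorm(ng))
      p0c <- pmin(pmax(p0_grid[i, ], 1e-12), 1 - 1e-12)
      f_grid[i, ] <- p0c + interaction_transform(z_grid[i, ], p0c,
                                                 cons[i, "b1"], cons[i, "b2"])
    }
    fit$z_grid_draws <- z_grid
    fit$f_grid_draws <- f_grid
  } else {
    fit$f_grid_draws <- p0_grid
  }
  class(fit) <- "stage1_fit"
  fit
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("<stage1_fit> (%s, %s, %s) mode = %s, %d draws, max Rhat = %.3f%s\n",
              x$key$cell_line, x$key$drug_a, x$key$drug_b, x$mode,
              nrow(x$draws), max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Summarise a stage-1 fit on the common grid
#'
#' Empirical posterior means and variances of the latent GP (and of the
#' dose-response surface) over the retained draws, the per-experiment
#' quantities consumed by stage 2. Variances are floored at `1e-6` so the
#' stage-2 noise matrix stays strictly positive (required by the
#' `Sigma^{-1/2}` preconditioner).
#'
#' @param fit a `stage1_fit` in `"full"` mode.
#' @param grid the [common_grid()] (defaults to the fit's own grid).
#' @param var_floor variance floor (default 1e-6).
#' @return A [latent_summary()].
#' @export
latent_summary_on_grid <- function(fit, grid = NULL, var_floor = 1e-6) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (fit$mode != "full") stop("latent summaries require a full-mode fit")
  grid <- grid %||% fit$grid
  if (grid$k != fit$grid$k) stop("shape error: fit grid has k = ", fit$grid$k)
  if (nrow(fit$draws) < fit$config$min_draws) {
    stop("too few draws: ", nrow(fit$draws), " < ", fit$config$min_draws)
  }
  z_mean <- colMeans(fit$z_grid_draws)
  z_var <- pmax(apply(fit$z_grid_draws, 2L, var), var_floor)
  f_mean <- colMeans(fit$f_grid_draws)
  f_var <- pmax(apply(fit$f_grid_draws, 2L, var), var_floor)
  latent_summary(fit$key$cell_line, fit$key$drug_a, fit$key$drug_b,
                 z_mean, z_var, f_mean, f_var, grid = grid)
}

# split-Rhat over a list of per-chain draw vectors
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars); B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from lag-autocorrelations (initial positive
# sequence), summed over chains
ess_basic <- function(chains) {
  sum(vapply(chains, function(x) {
    n <- length(x)
    if (var(x) == 0) return(n)
    ac <- acf(x, lag.max = min(n - 1L, 100L), plot = FALSE)$acf[-1L]
    pos <- which(ac < 0.05)
    s <- if (length(pos)) sum(ac[seq_len(pos[1L] - 1L)]) else sum(ac)
    n / (1 + 2 * max(s, 0))
  }, numeric(1)))
}

#' Posterior summary of stage-1 parameters
#'
#' @param object a `stage1_fit`.
#' @param ... unused.
#' @return data.frame with posterior mean, sd and split-Rhat per parameter.
#' @export
summary.stage1_fit <- function(object, ...) {
  data.frame(parameter = colnames(object$draws),
             mean = colMeans(object$draws),
             sd = apply(object$draws, 2L, sd),
             rhat = object$diagnostics$rhat[colnames(object$draws)],
             row.names = NULL)
}
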