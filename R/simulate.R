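#' Simulate a stage-2 latent dataset from the multi-output GP
#'
#' Draws the latent field of every (cell line, drug pair, ordering)
#' experiment directly from the generative model: a zero-mean GP with
#' covariance `K_c ox K_d ox K_x` is sampled densely, symmetrized by adding
#' its pair-swapped, grid-reflected copy (so the swap identity holds to
#' machine precision), and observed with heteroskedastic noise
#' `S + sigma2`. Reversed orderings are always masked; an additional random
#' fraction of experiments is held out. Per-experiment Bliss surfaces and
#' true dose-response surfaces are generated alongside so that
#' dose-response reconstruction can be evaluated against ground truth.
#'
#' @param N_c,N_d,k numbers of cell lines, canonical drug pairs, and grid
#'   points per axis (defaults 3, 4, 4: the desk-scale test world).
#' @param r_c,r_d true covariance ranks (defaults 2, 2).
#' @param ell true input lengthscale (default 0.3 on the unit box).
#' @param sigma2 true shared noise variance (default 0.01).
#' @param noise_meanlog,noise_sdlog log-normal parameters of the per-entry
#'   stage-1 variances stored in `S` (defaults give a median variance of
#'   0.05 with moderate spread, emulating heterogeneous experimental
#'   quality).
#' @param mask_fraction fraction of canonical experiments held out
#'   (default 0.2).
#' @param interaction `"independent"` (generic low-rank structure),
#'   `"synergy_in_block"` (a block of pairs shares a strong common latent
#'   factor, across all cell lines), or `"none"` (near-zero latent field).
#' @param b1,b2 transform parameters used for the true dose-response
#'   surfaces (default 1, 1).
#' @param seed integer seed.
#' @param cap refuse dense sampling above this total size (default 5000).
#' @return A list with `screen` (the assembled `screen_matrices`, held-out
#'   and reversed columns masked), `truth` (true hyperparameters, the full
#'   latent vector `zeta`, per-column `p0`, `f_true`, `F_obs`, `S_F`), and
#'   the `observed`/`heldout` experiment key tables.
#' @export
simulate_stage2_dataset <- function(N_c = 3L, N_d = 4L, k = 4L,
                                    r_c = 2L, r_d = 2L, ell = 0.3,
                                    sigma2 = 0.01,
                                    noise_meanlog = log(0.05),
                                    noise_sdlog = 0.5,
                                    mask_fraction = 0.2,
                                    interaction = c("independent",
                                                    "synergy_in_block",
                                                    "none"),
                                    b1 = 1, b2 = 1,
                                    seed = 1L, cap = 5000L) {
  interaction <- match.arg(interaction)
  set.seed(as.integer(seed))
  grid <- common_grid(k)
  n <- k^2
  N <- N_c * 2L * N_d * n
  if (N > cap) stop("size over cap: N = ", N, " > ", cap)
  cells <- sprintf("CL%02d", seq_len(N_c))
  n_drugs <- ceiling((1 + sqrt(1 + 8 * N_d)) / 2)
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  all_pairs <- t(utils::combn(drugs, 2L))
  pairs <- data.frame(drug_a = all_pairs[seq_len(N_d), 1L],
                      drug_b = all_pairs[seq_len(N_d), 2L])
  epairs <- extended_pairs(pairs)

  Lc <- matrix(rnorm(N_c * r_c, sd = 0.4), N_c, r_c)
  vc <- runif(N_c, 0.1, 0.3)
  if (interaction == "none") {
    Ld <- matrix(0, 2 * N_d, r_d)
    vd <- rep(1e-6, 2 * N_d)
  } else if (interaction == "synergy_in_block") {
    Ld <- matrix(rnorm(2 * N_d * r_d, sd = 0.15), 2 * N_d, r_d)
    block <- seq_len(max(2L, N_d %/% 2L + 1L))          # canonical indices
    in_block <- c(block, N_d + block)                   # both orderings
    Ld[in_block, 1L] <- 1.2
    vd <- runif(2 * N_d, 0.02, 0.08)
  } else {
    Ld <- matrix(rnorm(2 * N_d * r_d, sd = 0.5), 2 * N_d, r_d)
    vd <- runif(2 * N_d, 0.05, 0.2)
  }
  h_true <- kernel_hyperparams(ell, Lc, vc, Ld, vd, sigma2)

  # sample the pre-symmetrization field from the plain Kronecker covariance
  Kc <- lowrank_gram(Lc, vc); Kd <- lowrank_gram(Ld, vd)
  Kx <- squared_exponential_gram(grid$points, ell)
  K0 <- Kc %x% Kd %x% Kx
  zeta_tilde <- as.vector(t(chol(K0 + diag(1e-10, N))) %*% rnorm(N))
  perms <- build_permutations(N_d, grid)
  swap <- swap_index(N_c, N_d, n, perms)
  zeta <- zeta_tilde + zeta_tilde[swap]

  S_entry <- matrix(exp(rnorm(n * N_c * 2 * N_d, noise_meanlog, noise_sdlog)),
                    n, N_c * 2L * N_d)
  zbar <- matrix(zeta, n) + matrix(rnorm(N, sd = sqrt(S_entry + sigma2)), n)

  # monotherapy parameters per (cell line, drug) -> Bliss surface per column
  mono <- list()
  for (cl in cells) for (d in drugs) {
    mono[[paste(cl, d)]] <- list(l = runif(1, 0, 0.6), s = runif(1, 0.5, 3),
                                 m = runif(1, 0.2, 0.8))
  }
  n_cols <- N_c * 2L * N_d
  p0 <- matrix(NA_real_, n, n_cols)
  for (ci in seq_len(N_c)) for (pi in seq_len(2L * N_d)) {
    j <- (ci - 1L) * 2L * N_d + pi
    pA <- mono[[paste(cells[ci], epairs$drug_a[pi])]]
    pB <- mono[[paste(cells[ci], epairs$drug_b[pi])]]
    p0[, j] <- bliss_noninteraction(grid$points[, 1], grid$points[, 2], pA, pB)
  }
  p0c <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  zeta_m <- matrix(zeta, n)
  f_true <- p0c + vapply(seq_len(n_cols), function(j) {
    interaction_transform(zeta_m[, j], p0c[, j], b1, b2)
  }, numeric(n))
  # surfaces as stage 1 would report them: noisy latent pushed through the
  # transform, with delta-method variances
  F_obs <- p0c + vapply(seq_len(n_cols), function(j) {
    interaction_transform(zbar[, j], p0c[, j], b1, b2)
  }, numeric(n))
  gprime <- vapply(seq_len(n_cols), function(j) {
    q <- logit(p0c[, j]); z <- zbar[, j]
    s1 <- plogis(-(b1 * z + q)); s2 <- plogis(b2 * z + q)
    p0c[, j] * b1 * s1 * (1 - s1) + (1 - p0c[, j]) * b2 * s2 * (1 - s2)
  }, numeric(n))
  S_F <- pmax(S_entry * gprime^2, 1e-8)

  canonical <- expand.grid(pi = seq_len(N_d), ci = seq_len(N_c))
  keys <- data.frame(cell_line = cells[canonical$ci],
                     drug_a = epairs$drug_a[canonical$pi],
                     drug_b = epairs$drug_b[canonical$pi],
                     stringsAsFactors = FALSE)
  n_hold <- floor(mask_fraction * nrow(keys))
  hold_idx <- if (n_hold > 0) sample.int(nrow(keys), n_hold) else integer(0)
  observed <- keys[setdiff(seq_len(nrow(keys)), hold_idx), , drop = FALSE]
  heldout <- keys[hold_idx, , drop = FALSE]

  summaries <- lapply(seq_len(nrow(observed)), function(i) {
    j <- matrix_column(cells, epairs, n_cols, observed$cell_line[i],
                       observed$drug_a[i], observed$drug_b[i])
    latent_summary(observed$cell_line[i], observed$drug_a[i],
                   observed$drug_b[i],
                   z_mean = zbar[, j], z_var = S_entry[, j],
                   f_mean = F_obs[, j], f_var = S_F[, j], grid = grid)
  })
  screen <- assemble_matrices(summaries, cells, pairs, grid)
  list(screen = screen,
       truth = list(hyperparams = h_true, zeta = zeta,
                    zeta_tilde = zeta_tilde, swap = swap,
                    p0 = p0c, f_true = f_true, F_obs = F_obs, S_F = S_F,
                    S = S_entry, zbar = zbar, b1 = b1, b2 = b2,
                    mono = mono, seed = seed),
       observed = observed, heldout = heldout)
}

# global index permutation realising (c, A, B, x) -> (c, B, A, x~)
swap_index <- function(N_c, N_d, n, perms) {
  idx <- integer(N_c * 2L * N_d * n)
  for (ci in seq_len(N_c)) for (pi in seq_len(2L * N_d)) {
    j <- (ci - 1L) * 2L * N_d + pi
    js <- (ci - 1L) * 2L * N_d + perms$perm_pairs[pi]
    idx[(j - 1L) * n + seq_len(n)] <- (js - 1L) * n + perms$perm_grid
  }
  idx
}

#' Simulate a raw viability screen
#'
#' Generates replicate-level viability measurements from the full stage-1
#' generative chain: log-logistic monotherapies, Bliss product, a latent
#' interaction field pushed through the bounding transform, and
#' heteroskedastic Gaussian noise whose variance grows with viability
#' (`sd = sigma0 sqrt(c0 + f)`), emulating the higher variance of
#' negative-control-like wells. The default design matches a typical
#' published combination screen: a 4 x 4 combination grid in 4 replicates
#' plus 8-point monotherapy curves.
#'
#' @param N_c,N_d numbers of cell lines and drug pairs (defaults 3, 4).
#' @param combo_k combination grid size per axis (default 4).
#' @param combo_reps combination replicates (default 4).
#' @param mono_points,mono_reps monotherapy design (defaults 8, 4).
#' @param interaction `"synergy_in_block"` (a block of pairs shares a
#'   synergistic latent pattern), `"none"` (pure Bliss surfaces), or
#'   `"independent"` (per-experiment latent fields).
#' @param sigma0,c0 noise scale and offset (defaults 0.08, 0.3: residual sd
#'   about 0.05 at full kill and 0.09 at full viability).
#' @param amp,ls latent-field amplitude and lengthscale on the unit box.
#' @param b1,b2 transform parameters (default 1, 1).
#' @param seed integer seed.
#' @param path optional CSV output path (written with [write_screen()]).
#' @return A list with `screen` (records, a `screen` object) and `truth`
#'   (monotherapy parameters, latent fields and true surfaces per
#'   experiment on the scaled combination grid).
#' @export
simulate_viability_screen <- function(N_c = 3L, N_d = 4L, combo_k = 4L,
                                      combo_reps = 4L, mono_points = 8L,
                                      mono_reps = 4L,
                                      interaction = c("synergy_in_block",
                                                      "none", "independent"),
                                      sigma0 = 0.08, c0 = 0.3,
                                      amp = 0.8, ls = 0.4,
                                      b1 = 1, b2 = 1,
                                      seed = 1L, path = NULL) {
  interaction <- match.arg(interaction)
  set.seed(as.integer(seed))
  cells <- sprintf("CL%02d", seq_len(N_c))
  n_drugs <- ceiling((1 + sqrt(1 + 8 * N_d)) / 2)
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  all_pairs <- t(utils::combn(drugs, 2L))
  pairs <- data.frame(drug_a = all_pairs[seq_len(N_d), 1L],
                      drug_b = all_pairs[seq_len(N_d), 2L])
  # concentration design per drug (log10 molar, realistic micromolar ranges)
  ranges <- lapply(drugs, function(d) {
    lo <- runif(1, -9, -7); c(lo = lo, hi = lo + runif(1, 2, 4))
  })
  names(ranges) <- drugs
  mono_pars <- list()
  for (cl in cells) for (d in drugs) {
    rg <- ranges[[d]]
    mono_pars[[paste(cl, d)]] <- list(
      l = runif(1, 0, 0.6), s = runif(1, 0.5, 3),
      m = runif(1, rg["lo"] + 0.2 * diff(rg), rg["hi"] - 0.2 * diff(rg)))
  }
  # scaled combination grid locations (shared design across experiments)
  ug <- seq(0, 1, length.out = combo_k)
  gridpts <- cbind(rep(ug, each = combo_k), rep(ug, times = combo_k))
  Kz <- matern32_gram(gridpts, ls, amp^2) + diag(1e-8, combo_k^2)
  Lz <- t(chol(Kz))
  # shared synergistic pattern: effect deepens with both concentrations
  shared <- -1.5 * (gridpts[, 1] * gridpts[, 2])^0.8 +
    as.vector(t(chol(matern32_gram(gridpts, ls, 0.2^2) +
                     diag(1e-8, combo_k^2))) %*% rnorm(combo_k^2))
  block <- seq_len(max(2L, N_d %/% 2L + 1L))

  records <- list(); truth <- list()
  for (ci in seq_along(cells)) {
    cl <- cells[ci]
    for (d in drugs) {
      rg <- ranges[[d]]
      x <- seq(rg["lo"], rg["hi"], length.out = mono_points)
      pp <- mono_pars[[paste(cl, d)]]
      h <- log_logistic_response(x, pp$l, pp$s, pp$m)
      for (r in seq_len(mono_reps)) {
        y <- h + rnorm(length(x), sd = sigma0 * sqrt(c0 + h))
        records[[length(records) + 1L]] <- data.frame(
          cell_line = cl, drug_a = d, drug_b = NA_character_,
          conc_a = x, conc_b = NA_real_, replicate = r, viability = y)
      }
    }
    for (pi in seq_len(N_d)) {
      dA <- pairs$drug_a[pi]; dB <- pairs$drug_b[pi]
      rgA <- ranges[[dA]]; rgB <- ranges[[dB]]
      xA <- rgA["lo"] + gridpts[, 1] * diff(rgA)
      xB <- rgB["lo"] + gridpts[, 2] * diff(rgB)
      pA <- mono_pars[[paste(cl, dA)]]; pB <- mono_pars[[paste(cl, dB)]]
      p0 <- bliss_noninteraction(xA, xB, pA, pB)
      p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
      z <- if (interaction == "none") {
        rep(0, combo_k^2)
      } else if (interaction == "synergy_in_block" && pi %in% block) {
        runif(1, 0.7, 1.3) * shared + 0.15 * as.vector(Lz %*% rnorm(combo_k^2))
      } else {
        as.vector(Lz %*% rnorm(combo_k^2))
      }
      f <- p0 + interaction_transform(z, p0, b1, b2)
      for (r in seq_len(combo_reps)) {
        y <- f + rnorm(length(f), sd = sigma0 * sqrt(c0 + f))
        records[[length(records) + 1L]] <- data.frame(
          cell_line = cl, drug_a = dA, drug_b = dB,
          conc_a = xA, conc_b = xB, replicate = r, viability = y)
      }
      truth[[paste(cl, dA, dB)]] <- list(
        cell_line = cl, drug_a = dA, drug_b = dB,
        locations = gridpts, z = z, p0 = p0, f = f)
    }
  }
  screen <- as_screen(do.call(rbind, records))
  if (!is.null(path)) write_screen(screen, path)
  list(screen = screen,
       truth = list(experiments = truth, mono_pars = mono_pars,
                    ranges = ranges, pairs = pairs,
                    noise = list(sigma0 = sigma0, c0 = c0),
                    b1 = b1, b2 = b2, seed = seed))
}
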