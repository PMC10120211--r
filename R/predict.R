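#' Reconstruct a dose-response surface from predicted latent values
#'
#' Pushes the predicted latent mean through the bounding transform and adds
#' the monotherapy-only Bliss surface:
#' `Delta_hat = g(zeta_hat)`, `f_hat = p0_hat + Delta_hat`.
#'
#' @param zeta_mean predicted latent values on the grid.
#' @param p0_hat monotherapy-only Bliss surface on the same grid; values at
#'   0 or 1 are clamped to `[1e-6, 1 - 1e-6]` with a warning (the transform
#'   uses log-odds of `p0`).
#' @param b1,b2 positive transform parameters, aggregated from training
#'   experiments (see [aggregate_transform_params()]).
#' @return A `predicted_surface` list with `delta_hat`, `f_hat`,
#'   `zeta_mean`, `p0_hat`.
#' @export
reconstruct_dose_response <- function(zeta_mean, p0_hat, b1, b2) {
  stopifnot(length(zeta_mean) == length(p0_hat), b1 > 0, b2 > 0)
  if (any(p0_hat <= 0 | p0_hat >= 1)) {
    warning("p0_hat at the boundary; clamping to [1e-6, 1 - 1e-6]")
    p0_hat <- pmin(pmax(p0_hat, 1e-6), 1 - 1e-6)
  }
  delta_hat <- interaction_transform(zeta_mean, p0_hat, b1, b2)
  structure(list(zeta_mean = zeta_mean, p0_hat = p0_hat,
                 delta_hat = delta_hat, f_hat = p0_hat + delta_hat),
            class = "predicted_surface")
}

#' Aggregate stage-1 transform parameters for prediction
#'
#' The transform parameters `(b1, b2)` of a held-out experiment cannot be
#' estimated without its combination data; predictions use the unweighted
#' mean of the per-experiment posterior means across training fits (a
#' per-pair aggregation is available via `by_pair`).
#'
#' @param fits list of `stage1_fit` objects (full mode) from the training
#'   data.
#' @param by_pair if `TRUE`, return a per-drug-pair table instead of the
#'   global mean.
#' @return A list `b1`, `b2` (or a data.frame when `by_pair`).
#' @export
aggregate_transform_params <- function(fits, by_pair = FALSE) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(drug_a = f$key$drug_a, drug_b = f$key$drug_b,
               b1 = mean(f$draws[, "b1"]), b2 = mean(f$draws[, "b2"]))
  }))
  if (by_pair) {
    agg <- stats::aggregate(cbind(b1, b2) ~ drug_a + drug_b, tab, mean)
    return(agg)
  }
  list(b1 = mean(tab$b1), b2 = mean(tab$b2))
}

#' Inverse-variance weighted prediction metrics
#'
#' `wRMSE = sqrt(sum_i w_i (pred_i - obs_i)^2)` with normalized
#' inverse-variance weights `w_i = (1/var_i) / sum_j (1/var_j)`; Pearson
#' correlation (unweighted) is the secondary metric.
#'
#' @param predicted,observed equal-length numeric vectors.
#' @param observed_var positive per-observation variances (uniform variances
#'   reduce wRMSE to the plain RMSE).
#' @return An `evaluation_report` list with `wrmse`, `pearson_r`, `n`.
#' @export
evaluation_metrics <- function(predicted, observed, observed_var) {
  n <- length(observed)
  if (n == 0L) stop("empty test set")
  stopifnot(length(predicted) == n, length(observed_var) == n,
            all(observed_var > 0))
  w <- (1 / observed_var) / sum(1 / observed_var)
  wrmse <- sqrt(sum(w * (predicted - observed)^2))
  r <- if (sd(predicted) > 0 && sd(observed) > 0) {
    cor(predicted, observed)
  } else if (wrmse == 0) 1 else NA_real_
  structure(list(wrmse = wrmse, pearson_r = r, n = n, weights = w),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> wRMSE = %.4f, Pearson r = %.4f (n = %d)\n",
              x$wrmse, x$pearson_r, x$n))
  invisible(x)
}

#' Seeded train/test split of experiments
#'
#' @param experiments data.frame of experiment keys (one row each).
#' @param test_fraction fraction of experiments held out, in (0, 1); test
#'   size is `floor(fraction * count)`.
#' @param seed integer seed (bit-exact reproducibility).
#' @return A list with `train` and `test` data.frames (disjoint,
#'   exhaustive).
#' @export
train_test_split <- function(experiments, test_fraction = 0.2, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  m <- nrow(experiments)
  n_test <- floor(test_fraction * m)
  set.seed(as.integer(seed))
  idx <- sample.int(m, n_test)
  list(train = experiments[setdiff(seq_len(m), idx), , drop = FALSE],
       test = experiments[idx, , drop = FALSE])
}

#' Cross-validate the covariance ranks
#'
#' K-fold cross-validation over experiments (the sampling unit is an
#' experiment, not a grid point): for each `(r_c, r_d)` candidate, each
#' fold's experiments are masked out of the assembled matrices, the model
#' is retrained, the held-out latent values are predicted, and the
#' latent-space wRMSE is averaged over folds. Ties break toward the
#' smaller `r_d`, then `r_c`.
#'
#' @param screen an assembled `screen_matrices` with all candidate training
#'   experiments observed.
#' @param experiments data.frame of observed experiment keys.
#' @param r_c_grid,r_d_grid candidate ranks.
#' @param folds number of folds (default 5).
#' @param config a [piicm_config()]; its `r_c`/`r_d` are overridden.
#' @param seed seed controlling fold assignment.
#' @return A list with the selected `r_c`, `r_d` and the full CV `table`.
#' @export
cross_validate_ranks <- function(screen, experiments, r_c_grid, r_d_grid,
                                 folds = 5L, config = piicm_config(),
                                 seed = 1L) {
  stopifnot(folds >= 2L)
  N_c <- length(screen$cell_lines)
  N_d <- nrow(screen$extended_pairs) / 2L
  if (any(r_c_grid > N_c)) stop("r_c exceeds the number of cell lines")
  if (any(r_d_grid > 2L * N_d)) stop("r_d exceeds the drug-pair dimension")
  m <- nrow(experiments)
  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = m))
  grid_tab <- expand.grid(r_c = r_c_grid, r_d = r_d_grid)
  grid_tab$wrmse <- NA_real_
  for (g in seq_len(nrow(grid_tab))) {
    cfg <- config
    cfg$r_c <- grid_tab$r_c[g]; cfg$r_d <- grid_tab$r_d[g]
    scores <- numeric(folds)
    for (f in seq_len(folds)) {
      hold <- experiments[fold_id == f, , drop = FALSE]
      sm <- mask_experiments(screen, hold)
      model <- piicm_train(sm, cfg)
      pp <- predictive_posterior(model, sm)
      pred <- obs <- vv <- numeric(0)
      for (i in seq_len(nrow(hold))) {
        j <- screen_column(screen, hold$cell_line[i], hold$drug_a[i],
                           hold$drug_b[i])
        pred <- c(pred, pp$Zhat[, j])
        obs <- c(obs, screen$Z[, j])
        vv <- c(vv, screen$S[, j])
      }
      scores[f] <- evaluation_metrics(pred, obs, vv)$wrmse
    }
    grid_tab$wrmse[g] <- mean(scores)
  }
  ord <- order(grid_tab$wrmse, grid_tab$r_d, grid_tab$r_c)
  best <- grid_tab[ord[1L], ]
  list(r_c = best$r_c, r_d = best$r_d, table = grid_tab)
}

#' Bliss baseline surfaces
#'
#' The non-interaction baseline predicts `f_hat = p0_hat` exactly
#' (equivalently, [reconstruct_dose_response()] at `zeta = 0`).
#'
#' @param p0_hats named list of monotherapy-only Bliss surfaces, one per
#'   target experiment.
#' @return Named list of `predicted_surface` objects with `delta_hat = 0`.
#' @export
bliss_baseline <- function(p0_hats) {
  if (!length(p0_hats)) stop("no monotherapy surfaces supplied")
  lapply(p0_hats, function(p0) {
    if (is.null(p0)) stop("missing monotherapy surface for a target")
    structure(list(zeta_mean = rep(0, length(p0)), p0_hat = p0,
                   delta_hat = rep(0, length(p0)), f_hat = p0),
              class = "predicted_surface")
  })
}
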