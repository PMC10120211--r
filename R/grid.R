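#' Common concentration grid on the unit box
#'
#' All experiments are rescaled to the `[0,1] x [0,1]` unit box and
#' summarised on a shared equispaced k x k Cartesian grid. Points are stored
#' row-major over (axis-1 concentration, axis-2 concentration): index
#' `i = (i1 - 1) * k + i2`, so the second axis varies fastest. The grid is
#' closed under the coordinate reflection `(x1, x2) -> (x2, x1)`, which is
#' what makes the reflected input kernel a row permutation of the grid Gram
#' matrix.
#'
#' @param k integer, points per axis (default 10).
#' @return An object of class `common_grid`: a list with elements `k`, `x`
#'   (the axis values), `points` (an `n x 2` matrix, `n = k^2`), and
#'   `reflection` (the index permutation realising the coordinate swap).
#' @examples
#' g <- common_grid(10)
#' nrow(g$points) # 100
#' @export
common_grid <- function(k = 10L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  x <- seq(0, 1, length.out = k)
  points <- cbind(x1 = rep(x, each = k), x2 = rep(x, times = k))
  i1 <- rep(seq_len(k), each = k)
  i2 <- rep(seq_len(k), times = k)
  reflection <- (i2 - 1L) * k + i1
  structure(list(k = k, x = x, points = points, reflection = reflection),
            class = "common_grid")
}

#' @export
print.common_grid <- function(x, ...) {
  cat(sprintf("<common_grid> %d x %d equispaced points on [0,1]^2\n", x$k, x$k))
  invisible(x)
}

#' Grid reflection permutation
#'
#' Returns the involutive index permutation `p` with
#' `points[p[i], ] == points[i, c(2, 1)]`.
#'
#' @param grid a [common_grid()].
#' @return Integer vector of length `k^2`.
#' @export
grid_reflection <- function(grid) {
  stopifnot(inherits(grid, "common_grid"))
  grid$reflection
}

#' Rescale an experiment's concentrations to the unit box
#'
#' Each experiment is scaled independently: per drug, the affine map sends
#' the minimum observed log10 concentration to 0 and the maximum to 1. The
#' inverse map is retained so that predictions on the common grid can be
#' reported on the original concentration scale.
#'
#' @param records a `data.frame` of viability records for one experiment
#'   (columns `drug_a`, `drug_b`, `conc_a`, `conc_b`; monotherapy rows have
#'   `drug_b` missing and carry their concentration in `conc_a`).
#' @param k common grid size per axis.
#' @return A list with the per-drug `conc_scaler` maps (`scaler_a`,
#'   `scaler_b` when a second drug is present) and the [common_grid()] in
#'   element `grid`.
#' @export
scale_to_common_grid <- function(records, k = 10L) {
  drugs <- sort(unique(stats::na.omit(c(records$drug_a, records$drug_b))))
  scalers <- lapply(drugs, function(d) {
    xa <- records$conc_a[!is.na(records$drug_a) & records$drug_a == d]
    xb <- if (!is.null(records$conc_b))
      records$conc_b[!is.na(records$drug_b) & records$drug_b == d] else numeric()
    conc_scaler(c(xa, xb), drug = d)
  })
  names(scalers) <- drugs
  out <- list(grid = common_grid(k), scalers = scalers)
  if (length(drugs) >= 1L) out$scaler_a <- scalers[[1L]]
  if (length(drugs) >= 2L) out$scaler_b <- scalers[[2L]]
  out
}

#' Affine concentration map for one drug
#'
#' @param log_conc numeric vector of observed log10 concentrations.
#' @param drug optional identifier carried along for reporting.
#' @return A `conc_scaler` object with `$scale()` and `$unscale()` closures.
#' @export
conc_scaler <- function(log_conc, drug = NULL) {
  log_conc <- log_conc[is.finite(log_conc)]
  lo <- min(log_conc); hi <- max(log_conc)
  if (!(hi > lo)) {
    stop("degenerate concentration range for drug ",
         drug %||% "<unnamed>", ": need >= 2 distinct concentrations")
  }
  structure(list(drug = drug, lo = lo, hi = hi,
                 scale = function(x) (x - lo) / (hi - lo),
                 unscale = function(u) lo + u * (hi - lo)),
            class = "conc_scaler")
}

#' @export
print.conc_scaler <- function(x, ...) {
  cat(sprintf("<conc_scaler> %s: log10 conc [%.4g, %.4g] -> [0, 1]\n",
              x$drug %||% "?", x$lo, x$hi))
  invisible(x)
}
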