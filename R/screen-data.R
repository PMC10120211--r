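#' @title Screen tables and stage-2 matrix assembly
#' @description Readers/writers for long-format combination screen tables
#'   and the assembly of the stage-2 response/noise matrices `Z` and `S`
#'   with the fixed column ordering and dummy-masking conventions.
#' @name screen_data
NULL

SCREEN_COLUMNS <- c("cell_line", "drug_a", "drug_b",
                    "conc_a", "conc_b", "replicate", "viability")

#' Canonical ordering of a drug pair
#'
#' The canonical ordering of a pair is lexicographic on the drug
#' identifiers; the reversed ordering exists in the model only as a masked
#' column block.
#'
#' @param a,b drug identifiers.
#' @return A list with `drug_a`, `drug_b` (sorted) and `swapped` (logical).
#' @export
canonical_pair <- function(a, b) {
  sw <- as.character(b) < as.character(a)
  list(drug_a = ifelse(sw, b, a), drug_b = ifelse(sw, a, b), swapped = sw)
}

#' Load a long-format screen table
#'
#' Expects a CSV with header columns `cell_line, drug_a, drug_b, conc_a,
#' conc_b, replicate, viability`. A blank `drug_b` denotes a monotherapy
#' row. Concentrations are log10 by default; raw molar values can be
#' converted with `conc_scale = "molar"`. Combination rows are re-ordered to
#' the canonical (lexicographic) drug ordering, swapping the concentrations
#' alongside the drugs.
#'
#' @param path CSV file path.
#' @param conc_scale `"log10"` (stored as-is) or `"molar"` (log10-ed on
#'   load).
#' @return A `screen` object: a `data.table` of validated records with
#'   canonical drug ordering, plus an `experiments` attribute listing
#'   distinct combination experiment keys.
#' @export
load_screen <- function(path, conc_scale = c("log10", "molar")) {
  conc_scale <- match.arg(conc_scale)
  if (!file.exists(path)) stop("screen file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = c("cell_line", "drug_a", "drug_b")),
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(SCREEN_COLUMNS, names(dt))
  if (length(missing_cols)) {
    stop("screen format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  as_screen(as.data.frame(dt), conc_scale = conc_scale)
}

#' Build a screen object from a records data frame
#'
#' @param records data.frame with the screen columns.
#' @param conc_scale see [load_screen()].
#' @return A `screen` object.
#' @export
as_screen <- function(records, conc_scale = c("log10", "molar")) {
  conc_scale <- match.arg(conc_scale)
  records <- as.data.frame(records)[, SCREEN_COLUMNS]
  for (col in c("conc_a", "conc_b", "viability")) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric '%s' at row %d: '%s'",
                     col, bad[1L], v[bad[1L]]))
      }
      records[[col]] <- vn
    }
  }
  if (conc_scale == "molar") {
    records$conc_a <- log10(records$conc_a)
    records$conc_b <- log10(records$conc_b)
  }
  mono <- is.na(records$drug_b)
  if (any(mono & is.na(records$conc_a))) {
    stop("format error: monotherapy row without conc_a at row ",
         which(mono & is.na(records$conc_a))[1L])
  }
  if (any(mono & !is.na(records$conc_b))) {
    stop("format error: monotherapy row carries conc_b at row ",
         which(mono & !is.na(records$conc_b))[1L])
  }
  if (any(!mono & (is.na(records$conc_a) | is.na(records$conc_b)))) {
    stop("format error: combination row with missing concentration")
  }
  if (any(records$replicate < 1 | records$replicate != round(records$replicate))) {
    stop("format error: replicate must be a positive integer")
  }
  # canonicalize combination rows: lexicographic drug order, concentrations
  # swapped alongside
  comb <- which(!mono)
  if (length(comb)) {
    cp <- canonical_pair(records$drug_a[comb], records$drug_b[comb])
    sw <- cp$swapped
    swap_rows <- comb[sw]
    if (length(swap_rows)) {
      tmp_d <- records$drug_a[swap_rows]
      records$drug_a[swap_rows] <- records$drug_b[swap_rows]
      records$drug_b[swap_rows] <- tmp_d
      tmp_c <- records$conc_a[swap_rows]
      records$conc_a[swap_rows] <- records$conc_b[swap_rows]
      records$conc_b[swap_rows] <- tmp_c
    }
  }
  keys <- unique(records[!mono, c("cell_line", "drug_a", "drug_b")])
  keys <- keys[order(keys$cell_line, keys$drug_a, keys$drug_b), , drop = FALSE]
  rownames(keys) <- NULL
  structure(records, experiments = keys, class = c("screen", "data.frame"))
}

#' Write a screen table
#'
#' Round-trips exactly with [load_screen()] on identifiers and values.
#'
#' @param screen a `screen` object or compatible data.frame.
#' @param path output CSV path.
#' @export
write_screen <- function(screen, path) {
  df <- as.data.frame(screen)[, SCREEN_COLUMNS]
  # 17 significant digits so doubles survive the round trip bit-exactly
  for (col in c("conc_a", "conc_b", "viability")) {
    v <- sprintf("%.17g", df[[col]])
    v[is.na(df[[col]])] <- ""
    df[[col]] <- v
  }
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}

#' Experiment keys present in a screen
#'
#' @param screen a `screen` object.
#' @return data.frame with columns `cell_line`, `drug_a`, `drug_b`
#'   (canonical ordering).
#' @export
experiment_keys <- function(screen) attr(screen, "experiments")

#' Records of a single experiment
#'
#' Returns the combination rows of the requested (cell line, drug pair)
#' experiment together with the monotherapy rows of its two component drugs
#' on the same cell line. The pair may be given in either order.
#'
#' @param screen a `screen` object.
#' @param cell_line,drug_a,drug_b experiment identity.
#' @return data.frame of records.
#' @export
get_experiment <- function(screen, cell_line, drug_a, drug_b) {
  cp <- canonical_pair(drug_a, drug_b)
  df <- as.data.frame(screen)
  comb <- !is.na(df$drug_b) & df$cell_line == cell_line &
    df$drug_a == cp$drug_a & df$drug_b == cp$drug_b
  mono <- is.na(df$drug_b) & df$cell_line == cell_line &
    df$drug_a %in% c(cp$drug_a, cp$drug_b)
  out <- df[comb | mono, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extended drug-pair ordering
#'
#' Canonical pairs first in alphabetical order, then the same sequence with
#' every pair reversed element-wise, so that entry `i` of the canonical
#' block and entry `N_d + i` of the reversed block are the two orderings of
#' the same pair. This mirrored layout is what makes the block-swap
#' permutation `P = [[0, I], [I, 0]]`.
#'
#' @param pairs a data.frame or 2-column matrix of canonical drug pairs.
#' @return data.frame with columns `drug_a`, `drug_b` and `2 * N_d` rows.
#' @export
extended_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("drug_a", "drug_b")
  if (any(pairs$drug_b <= pairs$drug_a)) {
    stop("pairs must be canonically ordered (drug_a < drug_b) and distinct")
  }
  pairs <- pairs[order(pairs$drug_a, pairs$drug_b), , drop = FALSE]
  rev <- data.frame(drug_a = pairs$drug_b, drug_b = pairs$drug_a)
  out <- rbind(pairs, rev)
  rownames(out) <- NULL
  out
}

#' Per-experiment latent summary
#'
#' Posterior mean and variance of the latent interaction GP (and of the
#' dose-response surface) of one experiment, evaluated on the common grid.
#' These are the stage-1 outputs consumed by stage 2.
#'
#' @param cell_line,drug_a,drug_b experiment identity (canonical order).
#' @param z_mean,z_var latent GP posterior mean / variance on the grid.
#' @param f_mean,f_var dose-response posterior mean / variance on the grid.
#' @param grid the [common_grid()] the summaries live on.
#' @return A `latent_summary` object.
#' @export
latent_summary <- function(cell_line, drug_a, drug_b, z_mean, z_var,
                           f_mean = NULL, f_var = NULL, grid = NULL) {
  n <- length(z_mean)
  stopifnot(length(z_var) == n, all(z_var > 0))
  if (!is.null(grid) && grid$k^2 != n) {
    stop("shape error: summary length ", n, " does not match grid size ", grid$k^2)
  }
  structure(list(cell_line = as.character(cell_line),
                 drug_a = as.character(drug_a), drug_b = as.character(drug_b),
                 z_mean = as.numeric(z_mean), z_var = as.numeric(z_var),
                 f_mean = f_mean, f_var = f_var, grid = grid),
            class = "latent_summary")
}

summary_key <- function(s) paste(s$cell_line, s$drug_a, s$drug_b, sep = "\r")

#' Assemble the stage-2 response and noise matrices
#'
#' Builds the `n x (N_c * 2 N_d)` matrices `Z` (latent posterior means) and
#' `S` (posterior variances) with cell-line-major, pair-minor column
#' ordering: the first `2 N_d` columns belong to the first cell line, with
#' the canonical pair block followed by the reversed pair block. Reversed
#' orderings and unobserved experiments are dummy-masked: `Z = z0`,
#' `S = 1 / epsilon`, so preconditioned CG inference ignores them.
#'
#' @param summaries list of [latent_summary()] objects, one per observed
#'   experiment (canonical drug ordering).
#' @param cell_lines character vector of all cell lines (kept in the given
#'   order after sorting, see Details).
#' @param pairs data.frame of canonical drug pairs.
#' @param grid the shared [common_grid()].
#' @param z0 dummy response value for masked entries (default -999).
#' @param epsilon dummy-noise scale; masked `S` entries are `1 / epsilon`
#'   (default 1e-12, i.e. masked noise 1e12).
#' @return A `screen_matrices` object: `Z`, `S`, `mask` (TRUE = observed),
#'   ordering metadata, and the observed/total entry counts `M`, `N`.
#' @export
assemble_matrices <- function(summaries, cell_lines, pairs, grid,
                              z0 = -999, epsilon = 1e-12) {
  cell_lines <- sort(unique(as.character(cell_lines)))
  epairs <- extended_pairs(pairs)
  n <- grid$k^2
  n_cols <- length(cell_lines) * nrow(epairs)
  Z <- matrix(z0, n, n_cols)
  S <- matrix(1 / epsilon, n, n_cols)
  mask <- matrix(FALSE, n, n_cols)
  seen <- character()
  for (s in summaries) {
    stopifnot(inherits(s, "latent_summary"))
    if (length(s$z_mean) != n) {
      stop("shape error: summary for (", s$cell_line, ", ", s$drug_a, ", ",
           s$drug_b, ") has length ", length(s$z_mean), ", grid needs ", n)
    }
    k <- summary_key(s)
    if (k %in% seen) {
      stop("duplicate summary for experiment (", s$cell_line, ", ",
           s$drug_a, ", ", s$drug_b, ")")
    }
    seen <- c(seen, k)
    j <- matrix_column(cell_lines, epairs, n_cols, s$cell_line, s$drug_a, s$drug_b)
    Z[, j] <- s$z_mean
    S[, j] <- s$z_var
    mask[, j] <- TRUE
  }
  structure(list(Z = Z, S = S, mask = mask,
                 cell_lines = cell_lines, extended_pairs = epairs,
                 grid = grid, z0 = z0, epsilon = epsilon,
                 M = sum(mask), N = length(Z)),
            class = "screen_matrices")
}

matrix_column <- function(cell_lines, epairs, n_cols, cell, a, b) {
  ci <- match(as.character(cell), cell_lines)
  if (is.na(ci)) stop("unknown cell line: ", cell)
  pi <- which(epairs$drug_a == a & epairs$drug_b == b)
  if (length(pi) != 1L) stop("unknown drug pair: (", a, ", ", b, ")")
  (ci - 1L) * nrow(epairs) + pi
}

#' Column index of an experiment in the stage-2 matrices
#'
#' @param sm a `screen_matrices` object.
#' @param cell_line,drug_a,drug_b experiment identity; a reversed pair
#'   addresses the reversed-ordering column block.
#' @return Integer column index.
#' @export
screen_column <- function(sm, cell_line, drug_a, drug_b) {
  matrix_column(sm$cell_lines, sm$extended_pairs, ncol(sm$Z),
                cell_line, drug_a, drug_b)
}

#' Mask experiments in assembled stage-2 matrices
#'
#' Replaces the columns of the given experiments with dummy values, as used
#' when holding out experiments for prediction.
#'
#' @param sm a `screen_matrices` object.
#' @param keys data.frame with columns `cell_line`, `drug_a`, `drug_b`.
#' @return The modified `screen_matrices`.
#' @export
mask_experiments <- function(sm, keys) {
  for (i in seq_len(nrow(keys))) {
    j <- screen_column(sm, keys$cell_line[i], keys$drug_a[i], keys$drug_b[i])
    sm$Z[, j] <- sm$z0
    sm$S[, j] <- 1 / sm$epsilon
    sm$mask[, j] <- FALSE
  }
  sm$M <- sum(sm$mask)
  sm
}

#' @export
print.screen_matrices <- function(x, ...) {
  cat(sprintf(paste0("<screen_matrices> %d x %d (grid %d, %d cell lines, ",
                     "%d extended pairs)\n  observed entries M = %d of N = %d\n"),
              nrow(x$Z), ncol(x$Z), x$grid$k^2, length(x$cell_lines),
              nrow(x$extended_pairs), x$M, x$N))
  invisible(x)
}
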