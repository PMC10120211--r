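# numerically stable softplus and its inverse, used for all positivity
# constraints in stage-2 hyperparameter learning
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

logit <- function(p) log(p) - log1p(-p)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic per-experiment seed
#'
#' Derives a reproducible 31-bit seed from an experiment identity and a
#' global seed, so that independently fitted experiments do not share RNG
#' streams but remain reproducible.
#'
#' @param key character scalar or vector identifying the experiment
#'   (e.g. `c(cell_line, drug_a, drug_b)`).
#' @param seed integer global seed.
#' @return An integer in `[0, 2^31)`.
#' @export
seed_from_key <- function(key, seed = 0L) {
  txt <- paste(as.character(unlist(key)), collapse = "|")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2147483647
  as.integer(bitwXor(as.integer(h), as.integer(seed %% 2147483647L)))
}

# (Kc ox Ka ox Kx) %*% w without materializing the Kronecker product.
# w is indexed with the Kx dimension fastest, Kc slowest -- matching the
# column-stacking of the n x (Nc * 2Nd) response matrix.
kron3_matvec <- function(Kc, Ka, Kx, w) {
  n <- nrow(Kx); q <- nrow(Ka); m <- nrow(Kc)
  stopifnot(length(w) == n * q * m)
  W <- Kx %*% matrix(w, nrow = n)                       # apply along grid dim
  W <- aperm(array(W, c(n, q, m)), c(2L, 1L, 3L))
  W <- Ka %*% matrix(W, nrow = q)                       # apply along pair dim
  W <- aperm(array(W, c(q, n, m)), c(2L, 1L, 3L))
  W <- matrix(W, nrow = n * q) %*% t(Kc)                # apply along cell dim
  as.vector(W)
}

# relative difference helper used in tests and convergence checks
rel_err <- function(a, b) {
  d <- max(abs(a - b))
  s <- max(abs(b), 1e-12)
  d / s
}
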