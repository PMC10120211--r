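#' Log-logistic monotherapy dose-response
#'
#' `h(x) = l + (u - l) / (1 + 10^(s (x - m)))` with `x` the log10
#' concentration, `l` the lower asymptote (maximum drug effect), `u` the
#' upper asymptote (fixed at 1 under the assumption that no drug promotes
#' growth), `s > 0` the slope and `m` the EC50 on the log10 scale.
#'
#' @param x log10 concentration (vectorized).
#' @param l lower asymptote in `[0, 1]`.
#' @param s slope, positive.
#' @param m EC50 (log10 scale).
#' @param u upper asymptote, fixed at 1.
#' @return Viability in `[l, u]`, monotone non-increasing in `x`.
#' @export
log_logistic_response <- function(x, l, s, m, u = 1) {
  stopifnot(l >= 0, l <= u, s > 0)
  l + (u - l) / (1 + 10^(s * (x - m)))
}

#' Bliss independence non-interaction surface
#'
#' Under Bliss independence the joint effect of two non-interacting drugs is
#' the product of their monotherapy viabilities:
#' `p0(x) = h1(x1) h2(x2)`.
#'
#' @param x1,x2 log10 concentrations of the two drugs (vectorized).
#' @param p1,p2 monotherapy parameter lists with elements `l`, `s`, `m`.
#' @return `p0` in `[0, 1]`; symmetric under jointly swapping drugs and
#'   concentrations.
#' @export
bliss_noninteraction <- function(x1, x2, p1, p2) {
  log_logistic_response(x1, p1$l, p1$s, p1$m) *
    log_logistic_response(x2, p2$l, p2$s, p2$m)
}

#' Bounding transform of the latent interaction GP
#'
#' Maps an unconstrained latent value `z` to an interaction effect
#' `Delta in (-p0, 1 - p0)`, so that `f = p0 + Delta` stays in `(0, 1)`:
#' \deqn{g(z) = \frac{-p_0}{1 + e^{b_1 z + logit(p_0)}} +
#'             \frac{1 - p_0}{1 + e^{-b_2 z - logit(p_0)}}.}
#' `g` is strictly increasing with `g(0) = 0`: with no evidence of
#' interaction the dose-response falls back to the Bliss surface.
#'
#' @param z latent value(s).
#' @param p0 non-interaction viability in `(0, 1)` (recycled against `z`).
#' @param b1,b2 positive shape parameters (identifiability).
#' @return `Delta`, same length as `z`.
#' @export
interaction_transform <- function(z, p0, b1, b2) {
  stopifnot(b1 > 0, b2 > 0)
  if (any(p0 <= 0 | p0 >= 1)) {
    stop("boundary error: interaction transform needs p0 strictly in (0, 1)")
  }
  q <- logit(p0)
  -p0 * plogis(-(b1 * z + q)) + (1 - p0) * plogis(b2 * z + q)
}
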