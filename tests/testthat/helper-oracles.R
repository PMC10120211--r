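# Independent dense oracles: everything here is built entrywise from the
# kernel definitions (not from the package's operator code) so the
# structured implementations have something honest to be checked against.

# dense invariant covariance, entry by entry from the symmetrized kernel:
# kc(c,c') * [ (kd(p,p') + kd(sw p, sw p')) kx(x,x')
#              + (kd(sw p, p') + kd(p, sw p')) kx(x~, x') ]
oracle_dense_K <- function(h, grid, variant = "invariant") {
  Kc <- tcrossprod(h$Lc) + diag(h$vc, length(h$vc))
  Kd <- tcrossprod(h$Ld) + diag(h$vd, length(h$vd))
  pts <- grid$points
  D2 <- as.matrix(dist(pts))^2
  Kx <- exp(-D2 / (2 * h$ell^2))
  n <- nrow(pts)
  Np <- nrow(Kd); Nc <- nrow(Kc)
  if (variant == "non_invariant") return(Kc %x% Kd %x% Kx)
  pg <- grid$reflection
  sw <- c(Np / 2 + seq_len(Np / 2), seq_len(Np / 2))
  Kx_refl <- Kx[pg, , drop = FALSE]   # kx(x~, x')
  K <- matrix(0, Nc * Np * n, Nc * Np * n)
  for (c1 in seq_len(Nc)) for (p1 in seq_len(Np)) {
    for (c2 in seq_len(Nc)) for (p2 in seq_len(Np)) {
      blk <- Kc[c1, c2] * ((Kd[p1, p2] + Kd[sw[p1], sw[p2]]) * Kx +
                           (Kd[sw[p1], p2] + Kd[p1, sw[p2]]) * Kx_refl)
      ri <- ((c1 - 1) * Np + p1 - 1) * n + seq_len(n)
      ci <- ((c2 - 1) * Np + p2 - 1) * n + seq_len(n)
      K[ri, ci] <- blk
    }
  }
  K
}

# random small hyperparameters with well-conditioned factors
random_hyperparams <- function(N_c, N_d, r_c = 1L, r_d = 1L, seed = 1L) {
  set.seed(seed)
  kernel_hyperparams(
    ell = runif(1, 0.3, 1.2),
    Lc = matrix(rnorm(N_c * r_c, sd = 0.5), N_c, r_c),
    vc = runif(N_c, 0.1, 0.5),
    Ld = matrix(rnorm(2 * N_d * r_d, sd = 0.5), 2 * N_d, r_d),
    vd = runif(2 * N_d, 0.1, 0.5),
    sigma2 = runif(1, 0.05, 0.3))
}

# a fully observed screen_matrices with given Z and constant stage-1 noise
full_screen <- function(Z, grid, cell_lines, pairs, S_value = 0) {
  ep <- extended_pairs(pairs)
  structure(list(Z = Z, S = matrix(S_value, nrow(Z), ncol(Z)),
                 mask = matrix(TRUE, nrow(Z), ncol(Z)),
                 cell_lines = sort(cell_lines), extended_pairs = ep,
                 grid = grid, z0 = -999, epsilon = 1e-12,
                 M = length(Z), N = length(Z)),
            class = "screen_matrices")
}

# global index permutation for (c, A, B, x) -> (c, B, A, x~), built from
# first principles (independent of the package's swap_index)
oracle_swap <- function(N_c, N_d, grid) {
  n <- grid$k^2
  pg <- grid$reflection
  sw_p <- c(N_d + seq_len(N_d), seq_len(N_d))
  idx <- integer(N_c * 2 * N_d * n)
  for (ci in seq_len(N_c)) for (p in seq_len(2 * N_d)) {
    j <- (ci - 1) * 2 * N_d + p
    js <- (ci - 1) * 2 * N_d + sw_p[p]
    idx[(j - 1) * n + seq_len(n)] <- (js - 1) * n + pg
  }
  idx
}

# tiny viability table for one experiment (deterministic surface + noise)
make_mono_records <- function(cell = "CL01", drug = "D01", l = 0.1, s = 1.5,
                              m = -6.5, conc = seq(-8, -5, length.out = 8),
                              reps = 4, sigma = 0.03, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(reps), function(r) {
    h <- log_logistic_response(conc, l, s, m)
    data.frame(cell_line = cell, drug_a = drug, drug_b = NA_character_,
               conc_a = conc, conc_b = NA_real_, replicate = r,
               viability = h + rnorm(length(conc), sd = sigma))
  }))
}
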