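# Shared fixtures: scaled-down paradigm configurations and quiet subject
# profiles so signal-level tests run in seconds. Flicker blocks stay an
# integer number of cycles so the exact-bin phase estimator applies.

small_cfg <- function(flashes = 6L, ...) {
  paradigm_config(flicker_duration = 1, inter_phase_gap = 0.25,
                  flashes_per_stimulus = flashes, ...)
}

quiet_profile <- function(noise_sd = 0, jitter = 0, seed = NULL, ...) {
  subject_profile(noise_sd = noise_sd, p300_latency_jitter_sd = jitter,
                  seed = seed, ...)
}

still_nodes <- function(delays = c(0, 0, 0, 0)) node_set(delays,
                                                         flash_jitter_sd = 0)

# Brute-force oracle for center-of-sets type reduction: the weighted mean
# over the admissible firing box is extremal at a vertex, so enumerate all
# 2^n vertices. Independent of the switch-point search in the package.
brute_force_cos <- function(firing, consequents) {
  n <- nrow(firing)
  combos <- as.matrix(expand.grid(rep(list(1:2), n)))
  vl <- c(); vr <- c()
  for (i in seq_len(nrow(combos))) {
    w <- firing[cbind(seq_len(n), combos[i, ])]
    if (sum(w) <= 0) next
    vl <- c(vl, sum(w * consequents[, 1]) / sum(w))
    vr <- c(vr, sum(w * consequents[, 2]) / sum(w))
  }
  c(min(vl), max(vr))
}

# Independent SVD-based CCA oracle: whiten both blocks with inverse
# symmetric square roots, then SVD the cross-covariance.
svd_cca <- function(M, N) {
  M <- M - rowMeans(M); N <- N - rowMeans(N)
  n <- ncol(M)
  C_MM <- tcrossprod(M) / (n - 1); C_NN <- tcrossprod(N) / (n - 1)
  C_MN <- tcrossprod(M, N) / (n - 1)
  isqrt <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300))) %*% t(e$vectors)
  }
  sv <- svd(isqrt(C_MM) %*% C_MN %*% isqrt(C_NN))
  list(rho = sv$d, W_M = isqrt(C_MM) %*% sv$u)
}

random_firing <- function(n) {
  fh <- runif(n)
  fl <- runif(n) * fh * stats::rbinom(n, 1, 0.8)
  if (all(fh < 1e-3)) fh[1] <- 0.5
  cbind(fl, fh)
}

random_consequents <- function(n, lo = 200, hi = 600) {
  t(apply(matrix(runif(2 * n, lo, hi), n), 1, sort))
}
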