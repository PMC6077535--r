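epoch_set_from_array <- function(arr, fs = 500, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(arr)[1]))
  structure(list(data = arr, t0_ms = 0, sampling_rate = fs,
                 channel_labels = labels,
                 info = data.frame(onset_s = seq_len(dim(arr)[3]))),
            class = "epoch_set")
}

test_that("paired datasets concatenate trials against the tiled average", {
  set.seed(1)
  arr <- array(rnorm(5 * 80 * 30), dim = c(5, 80, 30))
  pd <- build_target_signal(epoch_set_from_array(arr))
  expect_equal(dim(pd$M), c(5L, 2400L))
  expect_equal(dim(pd$N), c(5L, 2400L))

  # column means of M per within-epoch position equal the matching N column
  avg <- apply(arr, c(1, 2), mean)
  expect_equal(pd$N[, 1:80], avg)
  m_mean <- matrix(0, 5, 80)
  for (i in 1:30) m_mean <- m_mean + pd$M[, ((i - 1) * 80 + 1):(i * 80)]
  expect_equal(m_mean / 30, avg)

  # identical epochs: N = M
  arr2 <- array(rep(arr[, , 1], 4), dim = c(5, 80, 4))
  pd2 <- build_target_signal(epoch_set_from_array(arr2))
  expect_equal(pd2$M, pd2$N)

  expect_error(build_target_signal(
    epoch_set_from_array(arr[, , 1, drop = FALSE])), "at least 2")
})

test_that("identical datasets give canonical correlations of 1", {
  set.seed(2)
  arr <- array(rnorm(4 * 50 * 6), dim = c(4, 50, 6))
  arr2 <- array(rep(arr[, , 1], 6), dim = c(4, 50, 6))
  suppressMessages(f <- fit_cca(build_target_signal(arr2 |>
                                                      epoch_set_from_array())))
  expect_true(all(abs(f$rho - 1) < 1e-6))
})

test_that("independent white noise has near-zero canonical correlation", {
  set.seed(3)
  n <- 1e4
  pd <- structure(list(M = matrix(rnorm(5 * n), 5),
                       N = matrix(rnorm(5 * n), 5),
                       channel_labels = paste0("ch", 1:5)),
                  class = "paired_dataset")
  f <- fit_cca(pd)
  expect_lt(max(f$rho), 0.1)
})

test_that("eigenvalue-equation CCA matches the SVD oracle", {
  set.seed(4)
  for (rep in 1:5) {
    # correlated structure: shared latent signals mixed into both sides
    n <- 3000
    L <- matrix(rnorm(2 * n), 2)
    M <- matrix(rnorm(10, 0, 1), 5, 2) %*% L + matrix(rnorm(5 * n), 5) * 0.8
    N <- matrix(rnorm(10, 0, 1), 5, 2) %*% L + matrix(rnorm(5 * n), 5) * 0.8
    pd <- structure(list(M = M, N = N, channel_labels = paste0("ch", 1:5)),
                    class = "paired_dataset")
    f <- fit_cca(pd)
    ref <- svd_cca(M, N)
    expect_equal(f$rho, ref$rho, tolerance = 1e-8)
    # rho from the mirrored eigenvalue equation agrees
    expect_equal(f$rho, f$rho_mirror, tolerance = 1e-8)
    # filters agree up to per-component scale: perfect column correlation
    for (k in 1:2) {
      corr <- abs(stats::cor(f$W_M[, k], ref$W_M[, k]))
      expect_gt(corr, 1 - 1e-6)
    }
    # stats::cancor cross-check on the correlations
    cc <- stats::cancor(t(M), t(N))
    expect_equal(f$rho, cc$cor, tolerance = 1e-6)
  }
})

test_that("the filter projects epochs and preserves linear structure", {
  id_filter <- structure(list(W_M = diag(3), W_N = diag(3), rho = rep(1, 3),
                              n_keep = 3L,
                              channel_labels = paste0("ch", 1:3)),
                         class = "spatial_filter")
  set.seed(5)
  arr <- array(rnorm(3 * 20 * 2), dim = c(3, 20, 2))
  eps <- epoch_set_from_array(arr)
  out <- apply_spatial_filter(id_filter, eps)
  expect_equal(out$data, arr, ignore_attr = TRUE)

  zero <- epoch_set_from_array(array(0, dim = c(3, 20, 2)))
  expect_true(all(apply_spatial_filter(id_filter, zero)$data == 0))

  bad <- epoch_set_from_array(array(0, dim = c(4, 20, 2)))
  expect_error(apply_spatial_filter(id_filter, bad), "mismatch")
})

test_that("the learned filter raises template SNR above any single channel", {
  # template on Pz with spatially uncorrelated noise; component 1 of the
  # filter should recover the template more cleanly than each channel
  set.seed(6)
  tmpl <- sin(seq(0, 2 * pi, length.out = 100))
  n_tr <- 60
  arr <- array(rnorm(5 * 100 * n_tr, sd = 2), dim = c(5, 100, n_tr))
  gains <- c(0.5, 1, 0.6, 0.2, 0.2) # P3 Pz P4 O1 O2
  for (i in seq_len(n_tr))
    arr[, , i] <- arr[, , i] + outer(gains, tmpl)
  eps <- epoch_set_from_array(arr, labels = c("P3", "Pz", "P4", "O1", "O2"))
  f <- fit_cca(build_target_signal(eps))
  filt <- apply_spatial_filter(f, eps)
  snr <- function(x) {
    fit <- stats::lm(x ~ tmpl)
    stats::coef(fit)[2]^2 * stats::var(tmpl) / stats::var(stats::resid(fit))
  }
  avg_filt <- apply(filt$data, c(1, 2), mean)[1, ]
  chan_snr <- vapply(1:5, function(ch)
    snr(apply(arr, c(1, 2), mean)[ch, ]), numeric(1))
  expect_gt(snr(avg_filt), max(chan_snr))
})

test_that("spatial filters serialize losslessly", {
  set.seed(7)
  arr <- array(rnorm(5 * 40 * 10), dim = c(5, 40, 10)) +
    rep(outer(c(0, 1, 0, 0, 0), sin(seq_len(40) / 6)), 10)
  f <- fit_cca(build_target_signal(epoch_set_from_array(arr)))
  path <- tempfile(fileext = ".json")
  spatial_filter_to_json(f, path)
  g <- spatial_filter_from_json(path)
  expect_equal(g$W_M, f$W_M)
  expect_equal(g$rho, f$rho)
  expect_equal(g$n_keep, f$n_keep)
})
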