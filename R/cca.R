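# CCA-based spatial filter for ERPs: canonical correlation between the
# concatenated single-trial target epochs (M) and the tiled grand-average
# epoch (N). The leading canonical component of M weights the channels so
# that the trial-to-trial reproducible ERP dominates, acting as a whitening
# spatial filter that improves P300 SNR before classification.

#' Build the paired datasets for the spatial filter
#'
#' `M` is the horizontal concatenation of single-trial target epochs
#' (channels x trials*time); `N` tiles the grand-average target epoch once
#' per trial, column-aligned with `M`.
#'
#' @param target_epochs An `epoch_set` of single-trial target epochs
#'   (>= 2 epochs).
#' @return A `paired_dataset` with matrices `M` and `N`.
#' @export
build_target_signal <- function(target_epochs) {
  d <- dim(target_epochs$data)
  if (d[3] < 2)
    stop("need at least 2 target epochs; the average would equal the trial")
  avg <- apply(target_epochs$data, c(1, 2), mean)
  M <- matrix(target_epochs$data, nrow = d[1], ncol = d[2] * d[3])
  N <- matrix(rep(avg, d[3]), nrow = d[1])
  structure(list(M = M, N = N, channel_labels = target_epochs$channel_labels),
            class = "paired_dataset")
}

#' Fit the canonical-correlation spatial filter
#'
#' Solves the eigenvalue problems
#' `C_MM^-1 C_MN C_NN^-1 C_NM W_M = rho^2 W_M` and its mirrored counterpart
#' for `W_N`, with a small ridge added to near-singular covariance blocks.
#' Canonical correlations are returned sorted descending; each eigenvector's
#' sign is fixed so its largest-magnitude weight is positive.
#'
#' @param data A `paired_dataset` from [build_target_signal()].
#' @param n_keep Number of components retained when the filter is applied
#'   (default 1).
#' @param ridge Relative ridge added when a covariance block is
#'   ill-conditioned (default `1e-6`, times `trace/q`).
#' @return A `spatial_filter`: `W_M`, `W_N` (q x q, columns = components),
#'   `rho` (descending canonical correlations), `n_keep`.
#' @export
fit_cca <- function(data, n_keep = 1L, ridge = 1e-6) {
  M <- data$M - rowMeans(data$M)
  N <- data$N - rowMeans(data$N)
  q <- nrow(M); n <- ncol(M)
  C_MM <- tcrossprod(M) / (n - 1)
  C_NN <- tcrossprod(N) / (n - 1)
  C_MN <- tcrossprod(M, N) / (n - 1)
  C_NM <- t(C_MN)
  regularize <- function(C) {
    if (rcond(C) < 1e-10) {
      message("near-singular covariance: adding ridge ", ridge, " * trace/q")
      C <- C + diag(ridge * sum(diag(C)) / q, q)
    }
    C
  }
  C_MM <- regularize(C_MM); C_NN <- regularize(C_NN)
  fix_signs <- function(W) {
    apply(W, 2, function(w) {
      w <- Re(w)
      if (w[which.max(abs(w))] < 0) -w else w
    })
  }
  solve_side <- function(C_aa, C_ab, C_bb, C_ba) {
    eg <- eigen(solve(C_aa, C_ab %*% solve(C_bb, C_ba)))
    rho2 <- pmin(pmax(Re(eg$values), 0), 1)
    o <- order(rho2, decreasing = TRUE)
    list(rho = sqrt(rho2[o]), W = fix_signs(eg$vectors[, o, drop = FALSE]))
  }
  left <- solve_side(C_MM, C_MN, C_NN, C_NM)
  right <- solve_side(C_NN, C_NM, C_MM, C_MN)
  structure(list(W_M = left$W, W_N = right$W, rho = left$rho,
                 rho_mirror = right$rho, n_keep = as.integer(n_keep),
                 channel_labels = data$channel_labels),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %d channels, rho = %s, keeping %d component(s)\n",
              nrow(x$W_M), paste(sprintf("%.3f", x$rho), collapse = ", "),
              x$n_keep))
  invisible(x)
}

#' Apply the spatial filter to epochs
#'
#' Projects each epoch through the first `n_keep` columns of `W_M`
#' (`W_M^T` applied to the channel dimension), yielding virtual channels.
#'
#' @param filter A `spatial_filter`.
#' @param epochs An `epoch_set` (or single epoch) with matching channel count.
#' @return An `epoch_set` whose channel dimension holds the retained
#'   canonical components (`CC1`, `CC2`, ...).
#' @export
apply_spatial_filter <- function(filter, epochs) {
  d <- dim(epochs$data)
  if (d[1] != nrow(filter$W_M))
    stop("channel count mismatch between filter and epochs")
  W <- filter$W_M[, seq_len(filter$n_keep), drop = FALSE]
  out <- array(0, dim = c(filter$n_keep, d[2], d[3]))
  for (i in seq_len(d[3]))
    out[, , i] <- crossprod(W, epochs$data[, , i])
  structure(list(
    data = out, t0_ms = epochs$t0_ms, sampling_rate = epochs$sampling_rate,
    channel_labels = paste0("CC", seq_len(filter$n_keep)), info = epochs$info
  ), class = "epoch_set")
}

#' Serialize a spatial filter to JSON
#'
#' @param filter A `spatial_filter`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
spatial_filter_to_json <- function(filter, path = NULL) {
  obj <- list(W_M = filter$W_M, W_N = filter$W_N, rho = filter$rho,
              n_keep = filter$n_keep, channel_labels = filter$channel_labels)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a spatial filter from JSON
#' @param path File path or JSON string.
#' @return A `spatial_filter`.
#' @export
spatial_filter_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(W_M = obj$W_M, W_N = obj$W_N, rho = obj$rho,
                 n_keep = as.integer(obj$n_keep),
                 channel_labels = obj$channel_labels),
            class = "spatial_filter")
}
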