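# Interval type-2 fuzzy logic regressor: four crisp phase-lag inputs, three
# Gaussian interval membership functions per input (uncertain mean, fixed
# sigma), a diagonal rule base (rule j uses MF j of every input, product
# t-norm), center-of-sets type reduction via the Karnik-Mendel procedure,
# and midpoint defuzzification to a crisp latency centroid in ms.

N_INPUTS <- 4L
N_MFS <- 3L

#' Interval type-2 fuzzy system parameters
#'
#' @param antecedents Numeric array `4 x 3 x 3`: input x membership function
#'   x (m_low, m_high, sigma), degrees. The footprint of uncertainty is an
#'   uncertain mean in `[m_low, m_high]` with shared `sigma`.
#' @param consequents Numeric matrix `3 x 2`: per-rule interval consequent
#'   `[c_l, c_r]` in ms.
#' @return An `it2f_params` object (parameter dimension D = 4*3*3 + 3*2 = 42).
#' @export
it2f_params <- function(antecedents, consequents) {
  stopifnot(is.array(antecedents), all(dim(antecedents) == c(N_INPUTS, N_MFS, 3)),
            is.matrix(consequents), all(dim(consequents) == c(N_MFS, 2)))
  if (any(antecedents[, , 1] > antecedents[, , 2]))
    stop("m_low must not exceed m_high")
  if (any(antecedents[, , 3] <= 0)) stop("sigma must be positive")
  if (any(consequents[, 1] > consequents[, 2]))
    stop("c_l must not exceed c_r")
  structure(list(antecedents = antecedents, consequents = consequents),
            class = "it2f_params")
}

#' @export
print.it2f_params <- function(x, ...) {
  cat(sprintf("<it2f_params> %d inputs x %d MFs, %d rules (D = %d)\n",
              N_INPUTS, N_MFS, N_MFS, it2f_dim()))
  invisible(x)
}

#' Parameter vector dimension of the fuzzy system
#' @return Integer, `4*3*3 + 3*2 = 42`.
#' @export
it2f_dim <- function() N_INPUTS * N_MFS * 3L + N_MFS * 2L

#' Encode parameters into a flat D-vector
#'
#' Order: for each input, for each MF: (m_low, m_high, sigma); then for each
#' rule: (c_l, c_r). This is the search space of the bee-colony trainer.
#'
#' @param params An [it2f_params()].
#' @return Numeric vector of length 42.
#' @export
it2f_encode <- function(params) {
  v <- numeric(0)
  for (i in seq_len(N_INPUTS))
    for (j in seq_len(N_MFS))
      v <- c(v, params$antecedents[i, j, ])
  c(v, as.vector(t(params$consequents)))
}

#' Decode a flat vector into parameters, repairing order constraints
#'
#' Swaps `(m_low, m_high)` and `(c_l, c_r)` pairs into sorted order and
#' floors sigma at a small positive value, so any point of the box-shaped
#' search space decodes to a valid system.
#'
#' @param v Numeric vector of length 42.
#' @return An [it2f_params()].
#' @export
it2f_decode <- function(v) {
  stopifnot(length(v) == it2f_dim())
  ant <- array(0, dim = c(N_INPUTS, N_MFS, 3))
  p <- 1L
  for (i in seq_len(N_INPUTS))
    for (j in seq_len(N_MFS)) {
      m <- sort(v[p:(p + 1)])
      ant[i, j, ] <- c(m, max(v[p + 2], 1e-3))
      p <- p + 3L
    }
  cons <- matrix(0, N_MFS, 2)
  for (j in seq_len(N_MFS)) {
    cons[j, ] <- sort(v[p:(p + 1)])
    p <- p + 2L
  }
  it2f_params(ant, cons)
}

#' Search-space bounds for the trainer
#'
#' Means live on the phase chart `[0, 360]` degrees, sigmas in `[5, 120]`
#' degrees, consequent endpoints in `[200, 600]` ms (a plausible P300 window).
#'
#' @return `D x 2` matrix of lower/upper bounds.
#' @export
default_it2f_bounds <- function() {
  b <- matrix(0, it2f_dim(), 2)
  p <- 1L
  for (i in seq_len(N_INPUTS))
    for (j in seq_len(N_MFS)) {
      b[p, ] <- c(0, 360); b[p + 1, ] <- c(0, 360); b[p + 2, ] <- c(5, 120)
      p <- p + 3L
    }
  for (j in seq_len(N_MFS)) {
    b[p, ] <- c(200, 600); b[p + 1, ] <- c(200, 600)
    p <- p + 2L
  }
  b
}

#' Fuzzify a crisp input vector
#'
#' Gaussian membership with uncertain mean: the upper grade is 1 when the
#' input lies inside `[m_low, m_high]` and otherwise uses the nearest band
#' edge; the lower grade always uses the farthest edge.
#'
#' @param x Numeric of length 4 (phase lags in degrees) or a
#'   `phase_lag_vector`.
#' @param params An [it2f_params()].
#' @return List with `lower` and `upper`, each a `4 x 3` matrix of grades.
#' @export
it2f_fuzzify <- function(x, params) {
  x <- as.numeric(x)
  stopifnot(length(x) == N_INPUTS)
  lower <- upper <- matrix(0, N_INPUTS, N_MFS)
  for (i in seq_len(N_INPUTS))
    for (j in seq_len(N_MFS)) {
      ml <- params$antecedents[i, j, 1]
      mh <- params$antecedents[i, j, 2]
      s <- params$antecedents[i, j, 3]
      gl <- exp(-(x[i] - ml)^2 / (2 * s^2))
      gh <- exp(-(x[i] - mh)^2 / (2 * s^2))
      upper[i, j] <- if (x[i] >= ml && x[i] <= mh) 1 else max(gl, gh)
      lower[i, j] <- min(gl, gh)
    }
  list(lower = lower, upper = upper)
}

#' Rule firing intervals
#'
#' Product t-norm across the four inputs, applied separately to lower and
#' upper grades, for the diagonal rule base (rule j uses MF j of each input).
#'
#' @param grades Output of [it2f_fuzzify()].
#' @return `3 x 2` matrix with columns `f_low`, `f_high`.
#' @export
it2f_firing <- function(grades) {
  cbind(f_low = apply(grades$lower, 2, prod),
        f_high = apply(grades$upper, 2, prod))
}

#' Center-of-sets type reduction (Karnik-Mendel)
#'
#' Collapses interval firings and interval consequents to the output interval
#' `[y_l, y_r]`: `y_l` minimizes and `y_r` maximizes the weighted mean of the
#' consequent endpoints over weights admissible within the firing intervals.
#' The optimum is found by exact search over the integer switch points of the
#' Karnik-Mendel procedure; no tolerance is involved.
#'
#' @param firing `n x 2` matrix (`f_low`, `f_high`), grades in `[0, 1]`.
#' @param consequents `n x 2` matrix (`c_l`, `c_r`) in ms.
#' @return Numeric `c(y_l, y_r)` with `y_l <= y_r`.
#' @export
type_reduce_cos <- function(firing, consequents) {
  fl <- firing[, 1]; fh <- firing[, 2]
  if (all(fh <= 0))
    stop_bcicalib("no rule fired: all upper firing grades are zero",
                  "bcicalib_no_rule")
  y_l <- km_endpoint(fl, fh, consequents[, 1], left = TRUE)
  y_r <- km_endpoint(fl, fh, consequents[, 2], left = FALSE)
  c(y_l = y_l, y_r = y_r)
}

# One KM endpoint. left = TRUE minimizes over c (left endpoints); FALSE
# maximizes. The optimum has switch-point structure (upper firings on one
# side of the switch, lower on the other, in c-sorted order), so the exact
# answer is the best over the n+1 integer switch points. Searching them all
# avoids the spurious fixed points the classic iteration can reach when
# lower firing grades underflow to ~0.
km_endpoint <- function(fl, fh, cvals, left) {
  o <- order(cvals)
  c_s <- cvals[o]; fl_s <- fl[o]; fh_s <- fh[o]
  n <- length(c_s)
  if (n == 1L) return(c_s)
  best <- NA_real_
  for (k in 0:n) {
    w <- if (left) c(fh_s[seq_len(k)], fl_s[seq_len(n - k) + k])
         else c(fl_s[seq_len(k)], fh_s[seq_len(n - k) + k])
    if (sum(w) <= 0) next
    y <- sum(w * c_s) / sum(w)
    if (is.na(best) || (left && y < best) || (!left && y > best)) best <- y
  }
  best
}

#' Defuzzify the type-reduced interval
#'
#' @param y_l,y_r Interval endpoints from [type_reduce_cos()].
#' @return Crisp output `(y_l + y_r) / 2` in ms.
#' @export
it2f_defuzzify <- function(y_l, y_r) {
  stopifnot(y_l <= y_r + 1e-9)
  unname((y_l + y_r) / 2)
}

#' Predict a P300 latency centroid from a phase-lag vector
#'
#' Composition fuzzify -> firing -> type-reduce -> defuzzify.
#'
#' @param x A `phase_lag_vector` or numeric of length 4 (degrees).
#' @param params Trained [it2f_params()].
#' @return A [latency_centroid()] with `source = "predicted"`.
#' @export
it2f_predict <- function(x, params) {
  fr <- it2f_firing(it2f_fuzzify(x, params))
  y <- type_reduce_cos(fr, params$consequents)
  latency_centroid(it2f_defuzzify(y[1], y[2]), "predicted")
}

#' Batch prediction over rows of a phase-lag matrix
#'
#' Vectorized form of [it2f_predict()] used inside trainer fitness loops;
#' type reduction is done by exact switch-point search (equivalent to the
#' KM result). Rows where no rule fires come back as `NA`.
#'
#' @param X Numeric matrix `K x 4` of phase lags (degrees).
#' @param params An [it2f_params()].
#' @return Numeric vector of K predicted centroids (ms), NA where no rule
#'   fired.
#' @export
it2f_predict_batch <- function(X, params) {
  K <- nrow(X)
  FL <- matrix(1, K, N_MFS); FU <- matrix(1, K, N_MFS)
  for (i in seq_len(N_INPUTS)) {
    xi <- X[, i]
    for (j in seq_len(N_MFS)) {
      ml <- params$antecedents[i, j, 1]
      mh <- params$antecedents[i, j, 2]
      s <- params$antecedents[i, j, 3]
      gl <- exp(-(xi - ml)^2 / (2 * s^2))
      gh <- exp(-(xi - mh)^2 / (2 * s^2))
      up <- pmax(gl, gh); up[xi >= ml & xi <= mh] <- 1
      FU[, j] <- FU[, j] * up
      FL[, j] <- FL[, j] * pmin(gl, gh)
    }
  }
  yl <- km_batch(FL, FU, params$consequents[, 1], left = TRUE)
  yr <- km_batch(FL, FU, params$consequents[, 2], left = FALSE)
  out <- (yl + yr) / 2
  out[rowSums(FU) <= 0] <- NA_real_
  out
}

# Vectorized switch-point enumeration across K instances for one endpoint.
km_batch <- function(FL, FU, cvals, left) {
  o <- order(cvals)
  c_s <- cvals[o]; FLo <- FL[, o, drop = FALSE]; FUo <- FU[, o, drop = FALSE]
  n <- length(c_s); K <- nrow(FL)
  best <- rep(if (left) Inf else -Inf, K)
  for (k in 0:n) {
    hi <- if (left) seq_len(k) else setdiff(seq_len(n), seq_len(k))
    W <- FLo
    if (length(hi)) W[, hi] <- FUo[, hi, drop = FALSE]
    den <- rowSums(W)
    num <- as.vector(W %*% c_s)
    ok <- den > 0
    y <- ifelse(ok, num / den, if (left) Inf else -Inf)
    best <- if (left) pmin(best, y) else pmax(best, y)
  }
  best[!is.finite(best)] <- NA_real_
  best
}

#' Serialize fuzzy-system parameters to JSON
#'
#' All 42 numbers, named, at full precision; round-trips exactly through
#' [it2f_params_from_json()].
#'
#' @param params An [it2f_params()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
it2f_params_to_json <- function(params, path = NULL) {
  obj <- list(
    n_inputs = N_INPUTS, n_mfs = N_MFS,
    antecedents = lapply(seq_len(N_INPUTS), function(i)
      lapply(seq_len(N_MFS), function(j)
        list(m_low = params$antecedents[i, j, 1],
             m_high = params$antecedents[i, j, 2],
             sigma = params$antecedents[i, j, 3]))),
    consequents = lapply(seq_len(N_MFS), function(j)
      list(c_l = params$consequents[j, 1], c_r = params$consequents[j, 2]))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read fuzzy-system parameters from JSON
#'
#' @param path File path or a JSON string from [it2f_params_to_json()].
#' @return An [it2f_params()].
#' @export
it2f_params_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ant <- array(0, dim = c(N_INPUTS, N_MFS, 3))
  for (i in seq_len(N_INPUTS))
    for (j in seq_len(N_MFS)) {
      a <- obj$antecedents[[i]][[j]]
      ant[i, j, ] <- c(a$m_low, a$m_high, a$sigma)
    }
  cons <- t(vapply(obj$consequents, function(cc) c(cc$c_l, cc$c_r),
                   numeric(2)))
  it2f_params(ant, cons)
}
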