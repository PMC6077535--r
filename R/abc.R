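# Artificial bee colony trainer for the interval type-2 fuzzy regressor.
# Food sources are flat 42-dimensional parameter vectors; employed bees
# propose one-coordinate neighbor moves, onlookers reinforce good sources by
# roulette selection, and a scout resamples the most-stagnant source. The
# global best is tracked separately and can never be lost to scouting.

#' ABC trainer configuration
#'
#' @param colony_size Number of food sources M (>= 2, default 30).
#' @param limit Stagnation threshold before a source is scouted (default 50).
#' @param max_cycles Training cycles (default 500).
#' @param bounds `D x 2` matrix of per-parameter lower/upper bounds
#'   (default [default_it2f_bounds()]).
#' @param seed Optional integer seed for the trainer's RNG stream.
#' @return An `abc_config` object.
#' @export
abc_config <- function(colony_size = 30L, limit = 50L, max_cycles = 500L,
                       bounds = default_it2f_bounds(), seed = NULL) {
  stopifnot(colony_size >= 2, limit >= 1, max_cycles >= 0,
            is.matrix(bounds), ncol(bounds) == 2,
            all(bounds[, 1] <= bounds[, 2]))
  structure(list(
    colony_size = as.integer(colony_size), limit = as.integer(limit),
    max_cycles = as.integer(max_cycles), bounds = bounds, seed = seed
  ), class = "abc_config")
}

#' Labeled training dataset for the calibration model
#'
#' Pairs of phase-lag input vectors and measured latency centroids, with a
#' train/eval split (60/40 by default, matching the registration protocol).
#'
#' @param X Numeric matrix `K x 4` of phase lags (degrees).
#' @param y Numeric vector of K latency centroids (ms), in `(0, 1000)`.
#' @param train_frac Fraction assigned to the training split (default 0.6).
#' @param shuffle Logical; permute rows before splitting (default TRUE, uses
#'   the current RNG stream).
#' @param strata Optional grouping vector (e.g. node ids): the split is then
#'   stratified so every stratum contributes at least one training pair.
#'   Without stratification a random split can orphan an entire node into
#'   the eval set, leaving the model untrained on that input region.
#' @return A `training_dataset` with elements `X`, `y`, `split`
#'   (factor `train`/`eval`).
#' @export
training_dataset <- function(X, y, train_frac = 0.6, shuffle = TRUE,
                             strata = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1, ncol(X) == 4,
            all(y > 0 & y < 1000))
  K <- nrow(X)
  spl <- rep("eval", K)
  assign_train <- function(idx) {
    n_train <- max(1L, round(train_frac * length(idx)))
    if (shuffle) idx <- idx[sample.int(length(idx))]
    idx[seq_len(n_train)]
  }
  if (is.null(strata)) {
    spl[assign_train(seq_len(K))] <- "train"
  } else {
    stopifnot(length(strata) == K)
    for (idx in base::split(seq_len(K), strata))
      spl[assign_train(idx)] <- "train"
  }
  structure(list(X = X, y = as.numeric(y), split = factor(spl,
            levels = c("train", "eval"))), class = "training_dataset")
}

#' Analytic registration pairs for a known delay-to-latency map
#'
#' Builds the noiseless training data the registration protocol would
#' measure for nodes with the given transmission delays: each input is the
#' four-condition phase-lag vector `wrap(condition + delay/T * 360)` and the
#' target is `p300_base_latency + delay`. Used for parameter-recovery
#' experiments where the generator's ground truth is the reference.
#'
#' @param delays_ms Transmission delays in ms, one per pair.
#' @param profile A [subject_profile()]; only `p300_base_latency` is used.
#' @param cfg A [paradigm_config()].
#' @return List with `X` (`K x 4`) and `y` (length K).
#' @export
make_training_pairs <- function(delays_ms, profile = subject_profile(),
                                cfg = paradigm_config()) {
  tm <- flicker_timing(cfg)
  X <- t(vapply(delays_ms, function(d)
    wrap_deg(cfg$phase_conditions + delay_to_deg(d, tm$period_ms)),
    numeric(length(cfg$phase_conditions))))
  list(X = X, y = profile$p300_base_latency + delays_ms)
}

#' Fitness of one candidate parameter vector
#'
#' `fitness = 1 / SSE` where SSE is the sum of squared prediction errors over
#' the K training pairs; an SSE below `1e-12` is capped at `1e12` (perfect
#' fit guard). A pair on which no rule fires contributes the squared width of
#' the consequent bound box as a penalty.
#'
#' @param position Flat parameter vector (length 42) or an [it2f_params()].
#' @param X,y Training inputs (`K x 4`) and targets (length K).
#' @param bounds Bounds matrix used for the no-rule penalty (default
#'   [default_it2f_bounds()]).
#' @return Positive scalar fitness.
#' @export
evaluate_fitness <- function(position, X, y, bounds = default_it2f_bounds()) {
  params <- if (inherits(position, "it2f_params")) position
            else it2f_decode(position)
  preds <- it2f_predict_batch(as.matrix(X), params)
  cons_rows <- (it2f_dim() - 2L * 3L + 1L):it2f_dim()
  penalty <- (max(bounds[cons_rows, 2]) - min(bounds[cons_rows, 1]))^2
  sq <- ifelse(is.na(preds), penalty, (preds - y)^2)
  sse <- sum(sq)
  if (sse < 1e-12) 1e12 else 1 / sse
}

# Colony state: positions (M x D), fitness (M), trials (M).
init_colony <- function(cfg) {
  D <- nrow(cfg$bounds)
  pos <- matrix(stats::runif(cfg$colony_size * D, cfg$bounds[, 1],
                             cfg$bounds[, 2]),
                nrow = cfg$colony_size, byrow = TRUE)
  list(positions = pos, fitness = rep(NA_real_, cfg$colony_size),
       trials = integer(cfg$colony_size))
}

# One neighbor move on source m: v = x + phi * (x - x_partner) on a single
# random coordinate, clamped to bounds; greedy replacement.
neighbor_move <- function(colony, m, cfg, X, y) {
  M <- cfg$colony_size
  partner <- sample(setdiff(seq_len(M), m), 1)
  d <- sample.int(nrow(cfg$bounds), 1)
  phi <- stats::runif(1, -1, 1)
  v <- colony$positions[m, ]
  v[d] <- v[d] + phi * (v[d] - colony$positions[partner, d])
  v[d] <- min(max(v[d], cfg$bounds[d, 1]), cfg$bounds[d, 2])
  fit <- evaluate_fitness(v, X, y, cfg$bounds)
  if (fit > colony$fitness[m]) {
    colony$positions[m, ] <- v
    colony$fitness[m] <- fit
    colony$trials[m] <- 0L
  } else {
    colony$trials[m] <- colony$trials[m] + 1L
  }
  colony
}

#' Employed-bee phase
#'
#' Every food source proposes one neighbor move (single random coordinate,
#' random partner) and keeps the better of the two (greedy); the stagnation
#' counter increments when the move fails.
#'
#' @param colony Colony state from the trainer.
#' @param cfg An [abc_config()].
#' @param X,y Training data.
#' @return Updated colony.
#' @export
abc_employed_phase <- function(colony, cfg, X, y) {
  for (m in seq_len(cfg$colony_size))
    colony <- neighbor_move(colony, m, cfg, X, y)
  colony
}

#' Onlooker-bee phase
#'
#' Allocates M neighbor moves across sources by roulette selection with
#' probability proportional to fitness, with the same greedy update.
#'
#' @inheritParams abc_employed_phase
#' @return Updated colony.
#' @export
abc_onlooker_phase <- function(colony, cfg, X, y) {
  p <- colony$fitness / sum(colony$fitness)
  for (k in seq_len(cfg$colony_size)) {
    m <- sample.int(cfg$colony_size, 1, prob = p)
    colony <- neighbor_move(colony, m, cfg, X, y)
  }
  colony
}

#' Scout-bee phase
#'
#' At most one scout per cycle: the source with the largest stagnation
#' counter, if it exceeds `limit`, is replaced by a uniform random position
#' within bounds and its counter reset. The global best is kept outside the
#' colony, so scouting never loses it.
#'
#' @inheritParams abc_employed_phase
#' @return Updated colony.
#' @export
abc_scout_phase <- function(colony, cfg, X, y) {
  m <- which.max(colony$trials)
  if (colony$trials[m] > cfg$limit) {
    colony$positions[m, ] <- stats::runif(nrow(cfg$bounds), cfg$bounds[, 1],
                                          cfg$bounds[, 2])
    colony$fitness[m] <- evaluate_fitness(colony$positions[m, ], X, y,
                                          cfg$bounds)
    colony$trials[m] <- 0L
  }
  colony
}

#' Train the fuzzy calibration model with the artificial bee colony
#'
#' Runs employed, onlooker, and scout phases for `max_cycles` cycles on the
#' training split, tracking the best food source ever seen (elitism), and
#' reports root-mean-square prediction errors on both splits.
#'
#' @param data A [training_dataset()].
#' @param cfg An [abc_config()].
#' @return An `it2f_fit`: `params` (best [it2f_params()]), `history`
#'   (best fitness per cycle, non-decreasing), `best_fitness`, `train_rmse`,
#'   `eval_rmse` (NA when the eval split is empty).
#' @export
train_it2fls <- function(data, cfg = abc_config()) {
  stopifnot(inherits(data, "training_dataset"))
  tr <- data$split == "train"
  if (!any(tr)) stop("training split is empty")
  X <- data$X[tr, , drop = FALSE]; y <- data$y[tr]
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  colony <- init_colony(cfg)
  for (m in seq_len(cfg$colony_size))
    colony$fitness[m] <- evaluate_fitness(colony$positions[m, ], X, y,
                                          cfg$bounds)
  best_i <- which.max(colony$fitness)
  best <- list(position = colony$positions[best_i, ],
               fitness = colony$fitness[best_i])
  history <- numeric(cfg$max_cycles)
  for (cycle in seq_len(cfg$max_cycles)) {
    colony <- abc_employed_phase(colony, cfg, X, y)
    colony <- abc_onlooker_phase(colony, cfg, X, y)
    colony <- abc_scout_phase(colony, cfg, X, y)
    ci <- which.max(colony$fitness)
    if (colony$fitness[ci] > best$fitness)
      best <- list(position = colony$positions[ci, ],
                   fitness = colony$fitness[ci])
    history[cycle] <- best$fitness
  }
  params <- it2f_decode(best$position)
  rmse <- function(mask) {
    if (!any(mask)) return(NA_real_)
    preds <- it2f_predict_batch(data$X[mask, , drop = FALSE], params)
    sqrt(mean((preds - data$y[mask])^2))
  }
  structure(list(
    params = params, history = history, best_fitness = best$fitness,
    train_rmse = rmse(tr), eval_rmse = rmse(data$split == "eval")
  ), class = "it2f_fit")
}

#' @export
print.it2f_fit <- function(x, ...) {
  cat(sprintf(
    "<it2f_fit> best fitness %.4g after %d cycles; RMSE train %.2f ms, eval %s ms\n",
    x$best_fitness, length(x$history), x$train_rmse,
    ifelse(is.na(x$eval_rmse), "NA", sprintf("%.2f", x$eval_rmse))))
  invisible(x)
}
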