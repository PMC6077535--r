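# Feature extraction under calibrated vs fixed windows, RBF-SVM
# target/nontarget classification, 4-way target selection, and the accuracy,
# information-transfer-rate, and phase/latency correlation metrics.

#' Extract classification features from a session
#'
#' Pipeline: band-pass filter, epoch every flash over a base window, average
#' the repetitions of each (block, node) group, cut the feature window, apply
#' the spatial filter, downsample to 62.5 Hz, and flatten. With calibration
#' the window is centered on the node's predicted latency centroid
#' (`[t_c - L/2, t_c + L/2]`); without, it is the fixed interval
#' `[t_s + 300, t_s + 300 + L]` after the trigger.
#'
#' @param session A `bci_session` (registration or operation).
#' @param length_ms Feature window length L in ms (the reference sweep uses
#'   160, 140, 120, 100, 80, 60).
#' @param calibrated Logical; calibrated or fixed window placement.
#' @param t_c Named numeric of predicted latency centroids per node id
#'   (required when `calibrated = TRUE`).
#' @param filter Optional `spatial_filter` applied before downsampling.
#' @param fixed_start_ms Start of the fixed window after the trigger
#'   (default 300).
#' @param base_window_ms Base epoch `c(start, end)` in ms around each flash
#'   from which feature windows are cut (default `c(0, 600)`).
#' @param target_rate Feature sampling rate in Hz (default 62.5).
#' @param prefiltered Set TRUE when `session$recording` is already band-pass
#'   filtered.
#' @return List: `x` (features, groups x values), `y` (factor
#'   target/nontarget), `groups` (block, node_id, n).
#' @export
extract_features <- function(session, length_ms, calibrated = FALSE,
                             t_c = NULL, filter = NULL, fixed_start_ms = 300,
                             base_window_ms = c(0, 600), target_rate = 62.5,
                             prefiltered = FALSE) {
  stopifnot(length_ms > 0)
  rec <- if (prefiltered) session$recording else bandpass_filter(session$recording)
  ev <- session$events[session$events$kind == "flash", ]
  epochs <- extract_epochs(rec, ev, base_window_ms[1],
                           base_window_ms[2] - base_window_ms[1])
  avg <- average_epochs(epochs, c("block", "node_id"))
  fs <- avg$sampling_rate
  if (calibrated) {
    if (is.null(t_c)) stop("calibrated windows need predicted centroids t_c")
    starts <- t_c[as.character(avg$info$node_id)] - length_ms / 2
    if (any(is.na(starts))) stop("missing predicted centroid for a node")
  } else {
    starts <- rep(fixed_start_ms, nrow(avg$info))
  }
  n_len <- round(length_ms / 1000 * fs)
  first <- floor((starts - avg$t0_ms) / 1000 * fs)
  n_base <- dim(avg$data)[2]
  if (any(first < 0 | first + n_len > n_base))
    stop("feature window escapes the base epoch; widen base_window_ms")
  rows <- vector("list", nrow(avg$info))
  for (g in seq_len(nrow(avg$info))) {
    cut <- structure(list(
      data = avg$data[, (first[g] + 1):(first[g] + n_len), g, drop = FALSE],
      t0_ms = starts[g], sampling_rate = fs,
      channel_labels = avg$channel_labels,
      info = avg$info[g, , drop = FALSE]
    ), class = "epoch_set")
    if (!is.null(filter)) cut <- apply_spatial_filter(filter, cut)
    cut <- downsample_epochs(cut, target_rate)
    rows[[g]] <- as.vector(t(cut$data[, , 1]))
  }
  x <- do.call(rbind, rows)
  y <- factor(ifelse(avg$info$is_target, "target", "nontarget"),
              levels = c("target", "nontarget"))
  list(x = x, y = y, groups = avg$info)
}

#' Train the RBF-SVM target/nontarget classifier
#'
#' Soft-margin support vector machine with a radial basis function kernel;
#' `(C, gamma)` are chosen by stratified k-fold cross-validation over a
#' small grid on the training session only.
#'
#' @param x Feature matrix (rows = epochs).
#' @param y Factor with levels `target`/`nontarget`; both must be present.
#' @param cost_grid,gamma_grid Candidate values (defaults
#'   `c(0.1, 1, 10, 100)` and `c(0.001, 0.01, 0.1, 1)`).
#' @param folds Cross-validation folds (default 5).
#' @return A `decode_model`: the fitted `e1071::svm` plus the chosen
#'   hyperparameters and CV accuracy. Classes are weighted inversely to
#'   their frequency (the oddball design yields 1 target per
#'   `n_nodes - 1` nontargets).
#' @export
train_svm <- function(x, y, cost_grid = c(0.1, 1, 10, 100),
                      gamma_grid = c(0.001, 0.01, 0.1, 1), folds = 5) {
  if (nlevels(droplevels(y)) < 2)
    stop("both target and nontarget examples are required")
  wts <- length(y) / (2 * table(y))
  best <- NULL
  for (C in cost_grid)
    for (g in gamma_grid) {
      fit <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = g,
                        scale = FALSE, cross = folds, class.weights = wts)
      acc <- fit$tot.accuracy
      if (is.null(best) || acc > best$acc)
        best <- list(acc = acc, cost = C, gamma = g)
    }
  model <- e1071::svm(x, y, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE, class.weights = wts)
  structure(list(svm = model, cost = best$cost, gamma = best$gamma,
                 cv_accuracy = best$acc), class = "decode_model")
}

#' @export
print.decode_model <- function(x, ...) {
  cat(sprintf("<decode_model> RBF SVM, C = %g, gamma = %g, CV accuracy %.1f%%\n",
              x$cost, x$gamma, x$cv_accuracy))
  invisible(x)
}

# Decision values oriented so larger = more target-like.
decision_values <- function(model, x) {
  pr <- stats::predict(model$svm, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (startsWith(colnames(dv)[1], "nontarget")) dv <- -dv
  as.numeric(dv)
}

#' Select the attended node of one trial
#'
#' Takes the SVM decision value of each node's averaged feature vector and
#' returns the node with the largest (most target-like) value; exact ties go
#' to the lowest node id.
#'
#' @param trial_features Feature matrix with one row per candidate node, in
#'   node-id order.
#' @param node_ids Node ids matching the rows.
#' @param model A `decode_model` from [train_svm()].
#' @return The selected node id.
#' @export
select_target <- function(trial_features, node_ids, model) {
  stopifnot(nrow(trial_features) == length(node_ids))
  o <- order(node_ids)
  scores <- decision_values(model, trial_features[o, , drop = FALSE])
  node_ids[o][which.max(scores)]
}

#' Selection accuracy
#'
#' @param selections Selected node ids.
#' @param truth Cued node ids of the same length.
#' @return Percentage of correct selections (0-100).
#' @export
compute_accuracy <- function(selections, truth) {
  if (length(selections) == 0) stop("no selections to score")
  stopifnot(length(selections) == length(truth))
  100 * mean(selections == truth)
}

#' Information transfer rate (Wolpaw definition)
#'
#' Bits per selection
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, with the
#' `P in {0, 1}` terms taken as continuity limits, scaled to bits/min by the
#' selection time. B is zero exactly at chance (`P = 1/N`) and positive
#' elsewhere.
#'
#' @param p Selection accuracy as a fraction in `[0, 1]`.
#' @param n_choices Number of selectable targets N (>= 2, default 4).
#' @param selection_time_s Seconds per selection (default 3).
#' @return ITR in bits/min.
#' @export
compute_itr <- function(p, n_choices = 4, selection_time_s = 3) {
  stopifnot(p >= 0, p <= 1, n_choices >= 2, selection_time_s > 0)
  xlx <- function(q) ifelse(q > 0, q * log2(q), 0)
  bits <- log2(n_choices) + xlx(p) +
    (if (p < 1) (1 - p) * log2((1 - p) / (n_choices - 1)) else 0)
  max(bits, 0) * 60 / selection_time_s
}

#' Correlation between P300 latency and SSVEP phase
#'
#' Pearson correlation `R = cov(X, Y) / (sd(X) sd(Y))` between measured P300
#' latencies and evoked SSVEP phase lags; the quantity the calibration model
#' relies on being large.
#'
#' @param p300_latencies Numeric vector (ms).
#' @param ssvep_phases Numeric vector (degrees), same length.
#' @return Pearson R.
#' @export
compute_correlation <- function(p300_latencies, ssvep_phases) {
  stopifnot(length(p300_latencies) == length(ssvep_phases),
            length(p300_latencies) >= 2)
  if (stats::sd(p300_latencies) == 0 || stats::sd(ssvep_phases) == 0)
    stop_bcicalib("zero variance: correlation undefined",
                  "bcicalib_zero_variance")
  stats::cor(p300_latencies, ssvep_phases)
}

#' Session-level metrics container
#'
#' @param accuracy Percentage of correct selections.
#' @param itr Information transfer rate in bits/min.
#' @param epoch_length_ms Feature window length.
#' @param calibrated Logical window-placement flag.
#' @return A `session_metrics` object.
#' @export
session_metrics <- function(accuracy, itr, epoch_length_ms, calibrated) {
  stopifnot(accuracy >= 0, accuracy <= 100, itr >= 0)
  structure(list(accuracy = accuracy, itr = itr,
                 epoch_length_ms = epoch_length_ms, calibrated = calibrated),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> %s windows, %g ms: accuracy %.1f%%, ITR %.1f bits/min\n",
              ifelse(x$calibrated, "calibrated", "fixed"), x$epoch_length_ms,
              x$accuracy, x$itr))
  invisible(x)
}
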