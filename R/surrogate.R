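#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Can be negative for
#' predictions worse than the mean; equals 1 only for exact predictions.
#'
#' @param actual Observed values (length >= 2, not all equal).
#' @param predicted Predicted values, same length.
#' @return R-squared.
#' @export
r_squared <- function(actual, predicted) {
  check_number(actual, "actual"); check_number(predicted, "predicted")
  if (length(actual) != length(predicted)) stop_invalid("length mismatch")
  if (length(actual) < 2) stop_invalid("need at least 2 points")
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop_invalid("constant actual values: R^2 undefined")
  1 - sum((actual - predicted)^2) / sst
}

#' Root mean square error
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @export
rmse <- function(actual, predicted) {
  check_number(actual, "actual"); check_number(predicted, "predicted")
  if (length(actual) != length(predicted)) stop_invalid("length mismatch")
  sqrt(mean((actual - predicted)^2))
}

#' Candidate hidden-layer sizes
#'
#' The operative selection mechanism is a scan over a contiguous range of
#' hidden-node counts (default 3..13), picking the size with the best test
#' fit. The additive rule `M = N + L + a` for a tuning constant
#' `a` in \[0, 10\] is also exposed via [heuristic_hidden_nodes()].
#'
#' @param scan Length-2 integer range (inclusive).
#' @return Integer vector of candidate hidden sizes.
#' @export
hidden_node_candidates <- function(scan = c(3, 13)) {
  if (length(scan) != 2 || scan[2] < scan[1])
    stop_invalid("`scan` must be a non-empty (low, high) range")
  seq.int(scan[1], scan[2])
}

#' @rdname hidden_node_candidates
#' @param n_input,n_output Layer sizes.
#' @param a Additive tuning constant in \[0, 10\].
#' @export
heuristic_hidden_nodes <- function(n_input = 3, n_output = 1, a = 0) {
  if (n_input < 1 || n_output < 1) stop_invalid("layer sizes must be >= 1")
  if (a < 0 || a > 10) stop_invalid("`a` must lie in [0, 10]")
  n_input + n_output + a
}

sigmoid <- function(z) 1 / (1 + exp(-z))

minmax_scale <- function(x, lo, hi) (x - lo) / (hi - lo)
minmax_unscale <- function(z, lo, hi) z * (hi - lo) + lo

#' Train a feed-forward surrogate for one response
#'
#' A single-hidden-layer network (3 inputs -> `hidden` sigmoid nodes ->
#' 1 linear output) trained by full-batch backpropagation with momentum on
#' min-max normalized inputs and output. The rows are split into a seeded
#' random train/test partition; training tracks the best-so-far train loss
#' and stops early when no improvement exceeds `tol` for `patience`
#' consecutive epochs. With the same seed the result is bit-identical.
#'
#' @param table Response table (factor columns in actual units + response).
#' @param response Response column name.
#' @param hidden Hidden-layer size.
#' @param split Fraction of rows used for training (default 0.8).
#' @param seed Integer seed controlling the split and the \[-0.5, 0.5\]
#'   uniform weight initialization.
#' @param learning_rate,momentum Gradient-descent hyperparameters.
#' @param max_epochs Epoch budget.
#' @param tol,patience Early-stopping rule on the train loss.
#' @param space [factor_space()] naming the input columns.
#' @return Object of class `surrogate_net` with weights, normalization
#'   bounds, per-split fit metrics (`r_squared`, `rmse` for train/test/all),
#'   the best-so-far loss trace and a `converged` flag.
#' @export
train_surrogate <- function(table, response, hidden = 8, split = 0.8,
                            seed = 1, learning_rate = 0.3, momentum = 0.9,
                            max_epochs = 20000, tol = 1e-10, patience = 1000,
                            space = factor_space()) {
  stopifnot(is.data.frame(table), response %in% names(table))
  if (hidden < 1) stop_invalid("`hidden` must be >= 1")
  n <- nrow(table)
  if (n < 5) stop_invalid("need at least 5 rows to split and train")
  X_raw <- as.matrix(table[space$names])
  y_raw <- table[[response]]
  in_lo <- apply(X_raw, 2, min); in_hi <- apply(X_raw, 2, max)
  out_lo <- min(y_raw); out_hi <- max(y_raw)
  if (any(in_hi == in_lo) || out_hi == out_lo)
    stop_invalid("degenerate column: cannot normalize")
  X <- sweep(sweep(X_raw, 2, in_lo), 2, in_hi - in_lo, "/")
  y <- minmax_scale(y_raw, out_lo, out_hi)

  net <- with_seed(seed, {
    n_train <- max(2, round(split * n))
    idx <- sample.int(n, n_train)
    W1 <- matrix(stats::runif(hidden * 3, -0.5, 0.5), hidden, 3)
    b1 <- stats::runif(hidden, -0.5, 0.5)
    W2 <- matrix(stats::runif(hidden, -0.5, 0.5), 1, hidden)
    b2 <- stats::runif(1, -0.5, 0.5)
    list(idx = idx, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
  idx <- net$idx
  Xt <- X[idx, , drop = FALSE]; yt <- y[idx]
  W1 <- net$W1; b1 <- net$b1; W2 <- net$W2; b2 <- net$b2
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  m <- nrow(Xt)
  best <- Inf; stall <- 0L; trace <- numeric(0); converged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    H <- sigmoid(Xt %*% t(W1) + matrix(b1, m, length(b1), byrow = TRUE))
    yhat <- drop(H %*% t(W2)) + b2
    err <- yhat - yt
    loss <- mean(err^2)
    # backprop (MSE loss, linear output, sigmoid hidden)
    d_out <- 2 * err / m
    gW2 <- matrix(d_out %*% H, 1, ncol(H))
    gb2 <- sum(d_out)
    d_hid <- d_out * matrix(W2, m, ncol(H), byrow = TRUE) * H * (1 - H)
    gW1 <- t(d_hid) %*% Xt
    gb1 <- colSums(d_hid)
    vW2 <- momentum * vW2 - learning_rate * gW2
    vb2 <- momentum * vb2 - learning_rate * gb2
    vW1 <- momentum * vW1 - learning_rate * gW1
    vb1 <- momentum * vb1 - learning_rate * gb1
    W2 <- W2 + vW2; b2 <- b2 + vb2; W1 <- W1 + vW1; b1 <- b1 + vb1
    if (loss < best - tol) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (epoch %% 50 == 0) trace <- c(trace, best)
    if (stall >= patience) { converged <- TRUE; break }
  }
  if (!converged)
    warning("surrogate training hit the epoch budget; returning best-so-far weights")

  obj <- structure(
    list(hidden = hidden, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
         input_lo = in_lo, input_hi = in_hi,
         output_lo = out_lo, output_hi = out_hi,
         response = response, space = space, seed = seed,
         train_index = sort(idx), loss_trace = trace, converged = converged),
    class = "surrogate_net")
  pred_all <- predict(obj, table)
  test_idx <- setdiff(seq_len(n), idx)
  metrics <- list(
    train = list(r_squared = r_squared(y_raw[idx], pred_all[idx]),
                 rmse = rmse(y_raw[idx], pred_all[idx])),
    test = if (length(test_idx) >= 2 && stats::var(y_raw[test_idx]) > 0)
      list(r_squared = r_squared(y_raw[test_idx], pred_all[test_idx]),
           rmse = rmse(y_raw[test_idx], pred_all[test_idx]))
    else list(r_squared = NA_real_,
              rmse = if (length(test_idx)) rmse(y_raw[test_idx], pred_all[test_idx]) else NA_real_),
    all = list(r_squared = r_squared(y_raw, pred_all),
               rmse = rmse(y_raw, pred_all)))
  obj$metrics <- metrics
  obj
}

#' @export
predict.surrogate_net <- function(object, newdata, ...) {
  X_raw <- as.matrix(as.data.frame(newdata)[object$space$names])
  X <- sweep(sweep(X_raw, 2, object$input_lo), 2,
             object$input_hi - object$input_lo, "/")
  m <- nrow(X)
  H <- sigmoid(X %*% t(object$W1) + matrix(object$b1, m, length(object$b1),
                                           byrow = TRUE))
  z <- drop(H %*% t(object$W2)) + object$b2
  minmax_unscale(z, object$output_lo, object$output_hi)
}

#' @export
print.surrogate_net <- function(x, ...) {
  cat(sprintf("<surrogate_net> %s: 3-%d-1, seed %s, all-data R^2 %.4f\n",
              x$response, x$hidden, format(x$seed), x$metrics$all$r_squared))
  invisible(x)
}

#' Scan hidden-layer sizes and pick the best
#'
#' Trains one surrogate per candidate hidden size for each requested
#' response and selects the size maximizing the mean test R-squared across
#' responses (ties broken by the smaller network).
#'
#' @param table Response table.
#' @param responses Response column names to scan over.
#' @param scan Candidate hidden sizes (integer vector).
#' @param seed Base seed; each (response, size) gets a distinct derived seed.
#' @param ... Passed to [train_surrogate()].
#' @return List with `best_hidden`, the per-size summary data frame and the
#'   trained nets for the winning size.
#' @export
scan_hidden_nodes <- function(table, responses = paste0("Y", 1:6),
                              scan = hidden_node_candidates(), seed = 1, ...) {
  if (!length(scan)) stop_invalid("empty hidden-size scan")
  rows <- lapply(seq_along(scan), function(i) {
    h <- scan[i]
    r2s <- vapply(seq_along(responses), function(j) {
      net <- train_surrogate(table, responses[j], hidden = h,
                             seed = seed + 1000L * i + j, ...)
      val <- net$metrics$test$r_squared
      if (is.na(val)) net$metrics$all$r_squared else val
    }, 0)
    data.frame(hidden = h, mean_test_r2 = mean(r2s))
  })
  summary <- do.call(rbind, rows)
  best <- summary$hidden[which.max(summary$mean_test_r2)]
  i_best <- which(scan == best)
  nets <- lapply(seq_along(responses), function(j)
    train_surrogate(table, responses[j], hidden = best,
                    seed = seed + 1000L * i_best + j, ...))
  names(nets) <- responses
  list(best_hidden = best, summary = summary, nets = nets)
}

#' Serialize a surrogate network to JSON text
#'
#' Writes the layer sizes, weight matrices and normalization bounds in a
#' plain JSON layout readable by [read_surrogate()].
#'
#' @param net A `surrogate_net`.
#' @param path Output file path.
#' @export
write_surrogate <- function(net, path) {
  stopifnot(inherits(net, "surrogate_net"))
  payload <- list(
    response = net$response, hidden = net$hidden,
    W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
    input_lo = net$input_lo, input_hi = net$input_hi,
    output_lo = net$output_lo, output_hi = net$output_hi,
    factor_names = net$space$names)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @return `read_surrogate()` returns the reconstructed `surrogate_net`
#'   (without training history or metrics).
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(hidden = p$hidden,
         W1 = matrix(p$W1, nrow = p$hidden), b1 = as.numeric(p$b1),
         W2 = matrix(p$W2, nrow = 1), b2 = as.numeric(p$b2),
         input_lo = stats::setNames(as.numeric(p$input_lo), p$factor_names),
         input_hi = stats::setNames(as.numeric(p$input_hi), p$factor_names),
         output_lo = p$output_lo, output_hi = p$output_hi,
         response = p$response,
         space = factor_space(names = p$factor_names),
         seed = NA, train_index = NULL, loss_trace = NULL, converged = NA,
         metrics = NULL),
    class = "surrogate_net")
}
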