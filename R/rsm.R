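#' Factor space of the drying experiment
#'
#' Three process factors at three levels each: drying temperature A,
#' slice thickness B and infrared radiation distance C. The coding map
#' actual <-> coded {-1, 0, +1} is the usual affine one,
#' `coded = (actual - center) / half_range`.
#'
#' @param low,center,high Actual levels per factor, each length 3 and
#'   ordered low < center < high.
#' @param names Factor names (single letters by convention).
#' @param labels Human-readable labels with units.
#' @return Object of class `factor_space`.
#' @export
factor_space <- function(low = c(55, 4, 80), center = c(60, 6, 120),
                         high = c(65, 8, 160), names = c("A", "B", "C"),
                         labels = c("temperature (degC)", "thickness (mm)",
                                    "radiation distance (mm)")) {
  stopifnot(length(low) == length(center), length(center) == length(high),
            length(names) == length(low))
  if (any(low >= center) || any(center >= high))
    stop_invalid("levels must satisfy low < center < high per factor")
  structure(list(names = names, labels = labels, low = low, center = center,
                 high = high), class = "factor_space")
}

#' Map actual factor settings to coded units (and back)
#'
#' @param space A [factor_space()].
#' @param x Data frame (or matrix) with the space's factor columns.
#' @return Data frame of the same shape in the other parameterization.
#' @export
code_factors <- function(space, x) {
  x <- as.data.frame(x)[space$names]
  for (j in seq_along(space$names)) {
    half <- (space$high[j] - space$low[j]) / 2
    x[[j]] <- (x[[j]] - space$center[j]) / half
  }
  x
}

#' @rdname code_factors
#' @export
decode_factors <- function(space, x) {
  x <- as.data.frame(x)[space$names]
  for (j in seq_along(space$names)) {
    half <- (space$high[j] - space$low[j]) / 2
    x[[j]] <- x[[j]] * half + space$center[j]
  }
  x
}

#' Box-Behnken design for three factors
#'
#' Twelve edge-midpoint runs (all +/-1 pairs on two factors with the third
#' at its center) plus replicated center points, in the deterministic run
#' order used throughout this package: the (A,B), (A,C), (B,C) pair blocks
#' followed by the center replicates.
#'
#' @param space A [factor_space()].
#' @param center_replicates Number of all-center runs (default 5).
#' @return Data frame with `run`, actual factor columns and coded
#'   `cA`, `cB`, `cC` columns.
#' @export
bbd_design <- function(space = factor_space(), center_replicates = 5) {
  stopifnot(inherits(space, "factor_space"), length(space$names) == 3)
  pm <- c(-1, 1, -1, 1)
  pm2 <- c(-1, -1, 1, 1)
  coded <- rbind(
    cbind(pm, pm2, 0),   # A-B block, C at center
    cbind(pm, 0, pm2),   # A-C block
    cbind(0, pm, pm2),   # B-C block
    matrix(0, center_replicates, 3))
  colnames(coded) <- space$names
  actual <- decode_factors(space, as.data.frame(coded))
  out <- cbind(run = seq_len(nrow(coded)), actual)
  out[paste0("c", space$names)] <- as.data.frame(coded)
  out
}

# Quadratic model-matrix columns in the canonical term order.
quad_terms <- function() c("A", "B", "C", "AB", "AC", "BC", "A2", "B2", "C2")

quad_columns <- function(A, B, C) {
  cbind(`(Intercept)` = rep(1, length(A)),
        A = A, B = B, C = C,
        AB = A * B, AC = A * C, BC = B * C,
        A2 = A^2, B2 = B^2, C2 = C^2)
}

#' Fit a second-order response-surface model
#'
#' Ordinary least squares of one response on the full quadratic polynomial in
#' the three factors (intercept, 3 linear, 3 interaction, 3 quadratic terms),
#' or on a stated subset of terms. Fitting in coded or actual units gives
#' identical predictions; coefficients differ by the affine reparameterization.
#'
#' @param table Response table: data frame with the factor columns (actual
#'   units) and the response column.
#' @param response Name of the response column, e.g. `"Y1"`.
#' @param parameterization `"actual"` or `"coded"` coefficient units.
#' @param terms Character vector of non-intercept terms to include, a subset
#'   of `A B C AB AC BC A2 B2 C2`; defaults to all nine.
#' @param space The [factor_space()] (needed for coding and for the box).
#' @return Object of class `quadratic_model` carrying coefficients, standard
#'   errors, residual quantities and the fitting data.
#' @export
fit_quadratic <- function(table, response, parameterization = c("actual", "coded"),
                          terms = quad_terms(), space = factor_space()) {
  parameterization <- match.arg(parameterization)
  stopifnot(is.data.frame(table), response %in% names(table),
            all(space$names %in% names(table)))
  bad <- setdiff(terms, quad_terms())
  if (length(bad)) stop_invalid(paste("unknown terms:", paste(bad, collapse = ", ")))
  y <- table[[response]]
  fac <- table[space$names]
  if (nrow(table) < length(terms) + 1)
    stop_invalid("fewer rows than model coefficients")
  use <- if (parameterization == "coded") code_factors(space, fac) else fac
  X <- quad_columns(use[[1]], use[[2]], use[[3]])[, c("(Intercept)", terms), drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop_invalid("singular design: model matrix rank deficient")
  coefs <- qr.coef(qrx, y)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  df_res <- nrow(X) - ncol(X)
  sigma2 <- if (df_res > 0) sum(resid^2) / df_res else NA_real_
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- names(coefs)
  sst <- sum((y - mean(y))^2)
  structure(
    list(response = response, parameterization = parameterization,
         terms = terms, coefficients = coefs, se = se,
         fitted = fitted, residuals = resid, df_residual = df_res,
         sigma2 = sigma2, r_squared = 1 - sum(resid^2) / sst,
         data = cbind(fac, y = y), space = space),
    class = "quadratic_model")
}

#' Construct a quadratic model from known coefficients
#'
#' Wraps externally given polynomial coefficients (e.g. published reduced
#' regression equations) in the same `quadratic_model` container that
#' [fit_quadratic()] produces, so they can be predicted from and optimized
#' identically. Inference quantities (SEs, ANOVA) are unavailable.
#'
#' @param coefficients Named numeric vector; names from
#'   `"(Intercept)", "A", ..., "C2"`. Actual-unit parameterization.
#' @param response Response label.
#' @param space The [factor_space()].
#' @return Object of class `quadratic_model`.
#' @export
quadratic_model <- function(coefficients, response = "Y", space = factor_space()) {
  stopifnot(!is.null(names(coefficients)))
  bad <- setdiff(names(coefficients), c("(Intercept)", quad_terms()))
  if (length(bad)) stop_invalid(paste("unknown terms:", paste(bad, collapse = ", ")))
  terms <- setdiff(names(coefficients), "(Intercept)")
  structure(
    list(response = response, parameterization = "actual", terms = terms,
         coefficients = coefficients, se = NULL, fitted = NULL,
         residuals = NULL, df_residual = NA_integer_, sigma2 = NA_real_,
         r_squared = NA_real_, data = NULL, space = space),
    class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, digits = 6, ...) {
  cat(sprintf("<quadratic_model> %s (%s units, %d terms)\n",
              x$response, x$parameterization, length(x$terms)))
  print(round(x$coefficients, digits))
  if (!is.na(x$r_squared)) cat(sprintf("R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Predict from a quadratic response-surface model
#'
#' @param object A `quadratic_model`.
#' @param newdata Data frame with the factor columns in actual units (the
#'   model handles its own coding internally).
#' @param extrapolation_warning Warn when points fall outside the design box.
#' @param ... Unused.
#' @return Numeric vector of predicted response values.
#' @export
predict.quadratic_model <- function(object, newdata,
                                    extrapolation_warning = TRUE, ...) {
  space <- object$space
  fac <- as.data.frame(newdata)[space$names]
  if (extrapolation_warning) {
    out_box <- FALSE
    for (j in seq_along(space$names))
      out_box <- out_box | fac[[j]] < space$low[j] | fac[[j]] > space$high[j]
    if (any(out_box)) warning("predicting outside the design box (extrapolation)")
  }
  use <- if (object$parameterization == "coded") code_factors(space, fac) else fac
  X <- quad_columns(use[[1]], use[[2]], use[[3]])
  drop(X[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
}

#' ANOVA of a response-surface model
#'
#' Partial (Type-III) F tests for each model term (each term has 1 numerator
#' df, so the partial F equals the squared t statistic of its coefficient),
#' the overall model F, and the lack-of-fit test splitting the residual into
#' lack-of-fit and pure error estimated from replicated runs. Also reports
#' R^2 and the model coefficient of variation
#' `C.V.% = 100 * sqrt(MSE) / mean(y)`.
#'
#' Term tests are always evaluated in coded factor units — the convention of
#' response-surface software — regardless of how the model was
#' parameterized: in actual units the polynomial columns are far from
#' orthogonal and the partial tests would answer a different question.
#' Predictions, the model F, R^2, C.V.% and the lack-of-fit split are
#' parameterization-invariant.
#'
#' @param model A `quadratic_model` produced by [fit_quadratic()].
#' @return Object of class `rsm_anova`: a list with a per-term data frame
#'   (`term`, `df`, `ss`, `f`, `p`), model/lack-of-fit/pure-error rows,
#'   `r_squared` and `cv_percent`.
#' @export
rsm_anova <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  if (is.null(model$data))
    stop_invalid("model carries no fitting data (constructed from fixed coefficients?)")
  y <- model$data$y
  n <- length(y)
  p <- length(model$coefficients)
  sse <- sum(model$residuals^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  df_model <- p - 1
  df_res <- model$df_residual
  mse <- sse / df_res
  f_model <- (ssr / df_model) / mse
  p_model <- stats::pf(f_model, df_model, df_res, lower.tail = FALSE)
  # per-term partial F (1 df each): squared t statistic of the coded fit
  coded <- if (model$parameterization == "coded") model else {
    tab <- model$data
    names(tab)[ncol(tab)] <- model$response
    fit_quadratic(tab, model$response, parameterization = "coded",
                  terms = model$terms, space = model$space)
  }
  tstat <- (coded$coefficients / coded$se)[model$terms]
  f_terms <- tstat^2
  p_terms <- stats::pf(f_terms, 1, df_res, lower.tail = FALSE)
  term_tab <- data.frame(term = model$terms, df = 1L,
                         ss = unname(f_terms) * mse,
                         f = unname(f_terms), p = unname(p_terms))
  # pure error from exact replicate factor settings
  key <- interaction(model$data[, seq_len(ncol(model$data) - 1), drop = FALSE],
                     drop = TRUE)
  reps <- split(y, key)
  ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), 0))
  df_pe <- n - length(reps)
  lof <- list(df = NA_integer_, ss = NA_real_, f = NA_real_, p = NA_real_)
  pe <- list(df = df_pe, ss = ss_pe)
  if (df_pe > 0) {
    df_lof <- df_res - df_pe
    ss_lof <- sse - ss_pe
    f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    lof <- list(df = df_lof, ss = ss_lof, f = f_lof,
                p = stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE))
  } else {
    warning("no replicated runs: lack-of-fit test unavailable")
  }
  structure(
    list(response = model$response, terms = term_tab,
         model = list(df = df_model, ss = ssr, f = f_model, p = p_model),
         residual = list(df = df_res, ss = sse, ms = mse),
         lack_of_fit = lof, pure_error = pe,
         total = list(df = n - 1, ss = sst),
         r_squared = model$r_squared,
         cv_percent = 100 * sqrt(mse) / mean(y)),
    class = "rsm_anova")
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("ANOVA for %s\n", x$response))
  cat(sprintf("Model      df %d  F %.2f  p %.4f\n", x$model$df, x$model$f, x$model$p))
  tt <- x$terms
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-4s     df %d  F %.2f  p %.4f\n", tt$term[i], tt$df[i],
                tt$f[i], tt$p[i]))
  if (!is.na(x$lack_of_fit$f))
    cat(sprintf("Lack of fit df %d  F %.2f  p %.4f  (pure error df %d)\n",
                x$lack_of_fit$df, x$lack_of_fit$f, x$lack_of_fit$p, x$pure_error$df))
  cat(sprintf("R^2 %.4f   C.V.%% %.2f\n", x$r_squared, x$cv_percent))
  invisible(x)
}

#' Prune a response-surface model to its significant terms
#'
#' Refits by OLS keeping the intercept plus every term with partial-F
#' p-value below `alpha`. Model hierarchy is deliberately not enforced: an
#' interaction may be retained without its parent quadratic terms, matching
#' the simplified regression equations this analysis reproduces. The reduced
#' model is returned in actual units.
#'
#' @param model Full `quadratic_model` from [fit_quadratic()].
#' @param anova Optional precomputed [rsm_anova()] of the model.
#' @param alpha Significance threshold (default 0.05).
#' @return Reduced `quadratic_model`.
#' @export
prune_model <- function(model, anova = NULL, alpha = 0.05) {
  if (is.null(anova)) anova <- rsm_anova(model)
  keep <- anova$terms$term[anova$terms$p < alpha]
  if (!length(keep)) {
    warning("no significant terms at alpha: returning intercept-only model")
    keep <- character(0)
  }
  tab <- model$data
  names(tab)[ncol(tab)] <- model$response
  if (!length(keep)) {
    cf <- c(`(Intercept)` = mean(tab[[model$response]]))
    return(quadratic_model(cf, response = model$response, space = model$space))
  }
  fit_quadratic(tab, model$response, parameterization = "actual",
                terms = keep, space = model$space)
}
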