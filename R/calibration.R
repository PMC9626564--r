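## ---- natural cubic smoothing spline (csaps parametrization) -------------
##
## Minimizes  p * sum w_i (y_i - f(x_i))^2 + (1 - p) * int f''(t)^2 dt
## over natural cubic splines with knots at the data abscissae
## (Green & Silverman formulation: roughness = f' K f with K = Q R^-1 Q').
## p = 1 interpolates; p = 0 degenerates to the weighted least-squares line.
## Problem sizes here are the few hundred spike-in fragments of a digest, so
## the dense linear solve is plenty.

spline_matrices <- function(x) {
  n <- length(x)
  h <- diff(x)
  Q <- matrix(0, n, n - 2L)
  R <- matrix(0, n - 2L, n - 2L)
  for (j in seq_len(n - 2L)) {
    Q[j, j] <- 1 / h[j]
    Q[j + 1L, j] <- -1 / h[j] - 1 / h[j + 1L]
    Q[j + 2L, j] <- 1 / h[j + 1L]
    R[j, j] <- (h[j] + h[j + 1L]) / 3
    if (j < n - 2L) {
      R[j, j + 1L] <- h[j + 1L] / 6
      R[j + 1L, j] <- h[j + 1L] / 6
    }
  }
  list(Q = Q, R = R)
}

smooth_spline_csaps <- function(x, y, w = rep(1, length(x)), p) {
  stopifnot(length(x) == length(y), !is.unsorted(x), all(diff(x) > 0),
            p >= 0, p <= 1)
  n <- length(x)
  if (p == 0) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    f <- fit$fitted.values
    gamma <- rep(0, n)
  } else if (p == 1) {
    f <- y
    m <- spline_matrices(x)
    gamma <- c(0, solve(m$R, crossprod(m$Q, f)), 0)
  } else {
    m <- spline_matrices(x)
    K <- m$Q %*% solve(m$R, t(m$Q))
    A <- p * diag(w, n) + (1 - p) * K
    f <- as.numeric(solve(A, p * w * y))
    gamma <- c(0, solve(m$R, crossprod(m$Q, f)), 0)
  }
  list(x = x, f = as.numeric(f), gamma = as.numeric(gamma), p = p)
}

## evaluate the natural cubic spline defined by knots/values/second derivs;
## linear extrapolation outside the knot range (callers clamp instead)
eval_natural_spline <- function(fit, xnew) {
  x <- fit$x; f <- fit$f; g <- fit$gamma
  n <- length(x)
  if (fit$p == 0) {
    # exact least-squares line limit
    b <- stats::lm.fit(cbind(1, x), f)$coefficients
    return(as.numeric(b[1] + b[2] * xnew))
  }
  i <- findInterval(xnew, x, all.inside = TRUE)
  h <- x[i + 1L] - x[i]
  dl <- xnew - x[i]
  dr <- x[i + 1L] - xnew
  val <- (dr * f[i] + dl * f[i + 1L]) / h -
    dl * dr / 6 * ((1 + dr / h) * g[i] + (1 + dl / h) * g[i + 1L])
  # natural spline: linear beyond the boundary knots
  lo <- xnew < x[1L]
  if (any(lo)) {
    s1 <- (f[2L] - f[1L]) / (x[2L] - x[1L]) - (x[2L] - x[1L]) / 6 * g[2L]
    val[lo] <- f[1L] + s1 * (xnew[lo] - x[1L])
  }
  hi <- xnew > x[n]
  if (any(hi)) {
    hn <- x[n] - x[n - 1L]
    sn <- (f[n] - f[n - 1L]) / hn + hn / 6 * g[n - 1L]
    val[hi] <- f[n] + sn * (xnew[hi] - x[n])
  }
  val
}

roughness <- function(fit) {
  m <- spline_matrices(fit$x)
  as.numeric(crossprod(fit$f, m$Q %*% solve(m$R, crossprod(m$Q, fit$f))))
}

## leave-one-out selection of the smoothing parameter on a log-lambda grid
## centered on the classical h^3 scale heuristic
select_p_loo <- function(x, y, grid_size = 41L) {
  lam0 <- mean(diff(x))^3 / 6
  lambdas <- lam0 * 10^seq(-5, 5, length.out = grid_size)
  ps <- 1 / (1 + lambdas)
  n <- length(x)
  # relative prediction error: count frequencies carry multiplicative
  # noise, so absolute LOO loss would let the peak dominate and oversmooth
  # the low-frequency tails
  scores <- vapply(ps, function(p) {
    se <- vapply(seq_len(n), function(i) {
      fit <- smooth_spline_csaps(x[-i], y[-i], p = p)
      ((eval_natural_spline(fit, x[i]) - y[i]) / y[i])^2
    }, numeric(1))
    mean(se)
  }, numeric(1))
  ps[which.min(scores)]
}

## ---- calibration model ---------------------------------------------------

#' Fit a length-to-sequencing-efficiency calibration from spike-in counts
#'
#' Library preparation and long-read sequencing recover molecules with an
#' efficiency that depends strongly and non-linearly on their length, so raw
#' read counts misstate molar composition. Given counts for an equimolar
#' spike-in digest (e.g. lambda cut with the same enzyme as the sample),
#' this fits the relative efficiency curve e(L): the per-molecule library
#' frequency (`freq_pct / copy_count`) as a function of expected fragment
#' length. The default model is a cubic smoothing spline in the csaps
#' parametrization -- `smooth = 1` interpolates the points, `smooth = 0` is
#' the least-squares line -- with the smoothing level chosen by
#' leave-one-out cross-validation when not supplied. Straight-line baselines
#' (`"linear"`, `"linear_log"`: linear in log length) are available for
#' comparison; they fail on the unimodal efficiency profiles real libraries
#' show. Because counts are roughly constant beyond 10 kb, the curve is not
#' modelled there: predictions plateau at e(10 kb).
#'
#' @param spike_table `fragment_count_table` of the spike-in digest.
#' @param method `"cubic_smoothing_spline"` (default), `"linear"` or
#'   `"linear_log"`.
#' @param smooth Smoothing parameter in `[0, 1]`; `NULL` (default) selects
#'   it by leave-one-out cross-validation.
#' @param source Label recorded in the model (e.g. `"lambda PvuII"`).
#' @param min_points Minimum spike-in fragments with reads; the spline
#'   needs at least 4 (fatal below), and fewer than `min_points` draws a
#'   warning.
#' @return A `calibration_model`.
#' @export
fit_calibration <- function(spike_table,
                            method = c("cubic_smoothing_spline", "linear",
                                       "linear_log"),
                            smooth = NULL, source = NA_character_,
                            min_points = 10L) {
  method <- match.arg(method)
  tab <- spike_table[spike_table$count > 0, , drop = FALSE]
  if (any(tab$length <= 0)) stop("non-positive fragment lengths")
  x <- tab$length
  y <- tab$freq_pct / tab$copy_count     # per-molecule frequency
  # smoothing-spline abscissae must be distinct: average duplicate lengths
  if (anyDuplicated(x)) {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
  } else {
    o <- order(x)
    x <- x[o]; y <- y[o]
  }
  if (length(x) < 4L) stop("need at least 4 spike-in points, got ", length(x))
  if (length(x) < min_points) {
    warning("only ", length(x), " spike-in points; calibration may be poor")
  }
  x <- as.numeric(x)
  fit <- NULL
  coefs <- NULL
  if (method == "cubic_smoothing_spline") {
    p <- if (is.null(smooth)) select_p_loo(x, y) else smooth
    fit <- smooth_spline_csaps(x, y, p = p)
  } else if (method == "linear") {
    coefs <- stats::coef(stats::lm(y ~ x))
    p <- NA_real_
  } else {
    coefs <- stats::coef(stats::lm(y ~ log(x)))
    p <- NA_real_
  }
  model <- structure(list(
    method = method, p = p,
    knots = if (!is.null(fit)) fit$x, f = if (!is.null(fit)) fit$f,
    gamma = if (!is.null(fit)) fit$gamma,
    coefficients = unname(coefs),
    training_range = range(x),
    plateau_length = 10000,
    source = source
  ), class = "calibration_model")
  model$plateau_value <- predict_efficiency_raw(
    model, min(10000, model$training_range[2]))
  model
}

## curve evaluation without clamping
predict_efficiency_raw <- function(model, L) {
  switch(model$method,
    cubic_smoothing_spline = eval_natural_spline(
      list(x = model$knots, f = model$f, gamma = model$gamma, p = model$p), L),
    linear = model$coefficients[1] + model$coefficients[2] * L,
    linear_log = model$coefficients[1] + model$coefficients[2] * log(L))
}

#' Predicted relative sequencing efficiency at given lengths
#'
#' Evaluates the fitted curve with the model's range policy: lengths below
#' the training minimum are clamped to the training minimum (splines
#' extrapolate poorly and the calibration claims nothing outside its
#' spike-in range), lengths above the training maximum are clamped to the
#' training maximum, and lengths beyond 10 kb return the plateau value.
#'
#' @param model A `calibration_model`.
#' @param L Numeric vector of lengths (bp).
#' @return List with `efficiency` and logical `in_range`.
#' @export
predict_efficiency <- function(model, L) {
  lo <- model$training_range[1]
  hi <- min(model$training_range[2], model$plateau_length)
  in_range <- L >= lo & L <= hi
  Lc <- pmin(pmax(L, lo), hi)
  e <- predict_efficiency_raw(model, Lc)
  e[L > model$plateau_length] <- model$plateau_value
  list(efficiency = as.numeric(e), in_range = in_range)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s%s, trained on %s points in [%g, %g] bp\n",
              x$method,
              if (!is.na(x$p)) sprintf(" (p = %.6g)", x$p) else "",
              if (is.null(x$knots)) "summary" else length(x$knots),
              x$training_range[1], x$training_range[2]))
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Goodness of fit on held-out fragments
#'
#' Compares model predictions with observed per-molecule frequencies of a
#' holdout digest (typically the genomic digest the spike-in is meant to
#' calibrate), over holdout fragments inside the training range. Because
#' each library is normalized within itself, predictions are rescaled by a
#' single factor (matching totals) before residuals are computed: the
#' calibration is a relative-efficiency curve and only its shape is
#' transferable between libraries.
#'
#' @param model A `calibration_model` (or a named list of them, compared
#'   side by side).
#' @param holdout_table `fragment_count_table` of the holdout digest.
#' @return Data.frame with one row per model: `method`, `n`, `rmse`,
#'   `median_abs_rel_err`.
#' @export
evaluate_fit <- function(model, holdout_table) {
  models <- if (inherits(model, "calibration_model")) list(model) else model
  tab <- holdout_table[holdout_table$count > 0, , drop = FALSE]
  rows <- lapply(models, function(m) {
    sel <- tab$length >= m$training_range[1] &
      tab$length <= m$training_range[2]
    h <- tab[sel, , drop = FALSE]
    if (nrow(h) == 0L) stop("no holdout fragments inside the training range")
    y <- h$freq_pct / h$copy_count
    e <- predict_efficiency(m, h$length)$efficiency
    e <- e * sum(y) / sum(e)
    data.frame(method = m$method, n = nrow(h),
               rmse = sqrt(mean((e - y)^2)),
               median_abs_rel_err = stats::median(abs(e - y) / y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correct raw frequencies into molar abundance estimates
#'
#' Divides each fragment's library frequency by the predicted relative
#' sequencing efficiency at its length and renormalizes so the corrected
#' abundances sum to 100. For an equimolar input this recovers a flat
#' profile; for an unknown mixture it estimates molar composition across
#' the calibrated 200 bp - 10 kb range.
#'
#' @param sample_table `fragment_count_table` of the sample.
#' @param model A `calibration_model` fitted on spike-in counts.
#' @return Data.frame `fragment_id`, `length`, `freq_pct`, `efficiency`,
#'   `corrected_abundance` (summing to 100), `in_range`.
#' @export
calibrate <- function(sample_table, model) {
  pe <- predict_efficiency(model, sample_table$length)
  if (any(pe$efficiency <= 0)) {
    stop("model predicts non-positive efficiency; refit with more smoothing ",
         "or a narrower range")
  }
  a <- sample_table$freq_pct / pe$efficiency
  out <- data.frame(fragment_id = sample_table$fragment_id,
                    length = sample_table$length,
                    freq_pct = sample_table$freq_pct,
                    efficiency = pe$efficiency,
                    corrected_abundance = 100 * a / sum(a),
                    in_range = pe$in_range,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## ---- model serialization -------------------------------------------------

num_out <- function(x) if (is.null(x)) NULL else sprintf("%.17g", x)
num_in <- function(x) if (is.null(x)) NULL else as.numeric(x)

#' Serialize / restore a calibration model (JSON)
#'
#' Numeric fields are written as full-precision (`%.17g`) strings so the
#' model round-trips bit-exactly through the file.
#'
#' @param model A `calibration_model`.
#' @param path JSON path.
#' @export
write_calibration <- function(model, path) {
  obj <- list(method = model$method, p = num_out(model$p),
              knots = num_out(model$knots), f = num_out(model$f),
              gamma = num_out(model$gamma),
              coefficients = num_out(model$coefficients),
              training_range = num_out(model$training_range),
              plateau_length = num_out(model$plateau_length),
              plateau_value = num_out(model$plateau_value),
              source = model$source)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(
    method = obj$method, p = num_in(obj$p),
    knots = num_in(obj$knots), f = num_in(obj$f), gamma = num_in(obj$gamma),
    coefficients = num_in(obj$coefficients),
    training_range = num_in(obj$training_range),
    plateau_length = num_in(obj$plateau_length),
    plateau_value = num_in(obj$plateau_value),
    source = if (is.null(obj$source)) NA_character_ else obj$source
  ), class = "calibration_model")
}
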