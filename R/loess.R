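#' Local polynomial regression with tricubic weights
#'
#' From-scratch loess engine used throughout the campaign analysis. At each
#' query point the `q = ceiling(span * n)` nearest source points by absolute
#' time distance are selected (all equidistant ties included), weighted by the
#' tricube kernel `w = (1 - (d/dmax)^3)^3`, and a weighted least-squares
#' polynomial of the requested degree is fitted in coordinates centred on the
#' query point. The fitted value is the local intercept; the pointwise
#' standard error combines the local weighted residual variance with the local
#' hat vector. No robustness iterations are performed (Gaussian family).
#'
#' @param ts a [cyto_ts()] (missing values are dropped with a message).
#' @param span fraction of points in each local neighbourhood, in `(0, 1]`.
#' @param degree polynomial degree: 0, 1 or 2 (default 2).
#' @param step_h grid spacing in hours for the fitted grid (default 1).
#' @return An object of class `cyto_loess`: a list with the source points
#'   (`x_h`, `y`, `origin`), `span`, `degree`, `q`, the regular grid (`grid_h`,
#'   hours since origin), `fitted`, `se` and `slopes` (units per hour, central
#'   finite differences).
#' @export
loess_fit <- function(ts, span, degree = 2, step_h = 1) {
  stopifnot(inherits(ts, "cyto_ts"))
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    stop("`span` must be in (0, 1]", call. = FALSE)
  }
  if (!degree %in% 0:2) stop("`degree` must be 0, 1 or 2", call. = FALSE)
  keep <- !is.na(ts$value)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("loess_fit: dropped %d missing value(s)", n_dropped))
  }
  time <- ts$time[keep]
  y <- ts$value[keep]
  n <- length(y)
  if (n < degree + 2) {
    stop(sprintf("need at least %d non-missing points for degree %d",
                 degree + 2, degree), call. = FALSE)
  }
  origin <- time[1]
  x <- hours_since(time, origin)
  if (all(x == x[1])) stop("all timestamps identical", call. = FALSE)
  q <- ceiling(span * n)
  if (q < degree + 1) {
    stop(sprintf("span * n = %.2f gives a neighbourhood smaller than degree + 1",
                 span * n), call. = FALSE)
  }
  grid_h <- seq(x[1], x[n], by = step_h)
  fit <- .loess_solve(x, y, grid_h, q, degree)
  structure(list(
    x_h = x, y = y, origin = origin, span = span, degree = degree, q = q,
    step_h = step_h, grid_h = grid_h, fitted = fit$fitted, se = fit$se,
    slopes = loess_slope_values(fit$fitted, step_h),
    variable = ts_variable(ts), units = ts_units(ts)
  ), class = "cyto_loess")
}

# Definitional weighted least-squares solve at each query point.
# Returns fitted values and pointwise SE. Neighbourhood points at exactly
# d = dmax receive tricube weight zero; the neighbourhood is widened until at
# least degree + 1 points carry positive weight.
.loess_solve <- function(x, y, x0s, q, degree) {
  n <- length(x)
  p <- degree + 1
  m <- length(x0s)
  fitted <- numeric(m)
  se <- numeric(m)
  for (j in seq_len(m)) {
    x0 <- x0s[j]
    d <- abs(x - x0)
    ord <- order(d)
    qj <- min(q, n)
    repeat {
      dmax <- d[ord[qj]]
      idx <- which(d <= dmax)          # include all equidistant ties
      if (dmax == 0) {
        w <- rep(1, length(idx))
      } else {
        w <- (1 - (d[idx] / dmax)^3)^3
      }
      if (sum(w > 0) >= p || qj >= n) break
      qj <- qj + 1
    }
    pos <- w > 0
    xi <- x[idx][pos]; yi <- y[idx][pos]; wi <- w[pos]
    z <- xi - x0
    X <- outer(z, 0:degree, `^`)
    sw <- sqrt(wi)
    qr_fit <- qr(X * sw)
    beta <- qr.coef(qr_fit, yi * sw)
    beta[is.na(beta)] <- 0
    fitted[j] <- beta[1]
    # local hat vector l: fitted = sum(l * y) over the neighbourhood
    XtWX_inv_e1 <- tryCatch(
      qr.solve(crossprod(X * sw), c(1, rep(0, degree))),
      error = function(e) rep(NA_real_, p))
    if (anyNA(XtWX_inv_e1)) {
      se[j] <- NA_real_
      next
    }
    l <- wi * drop(X %*% XtWX_inv_e1)
    resid <- yi - drop(X %*% beta)
    dof <- sum(wi) - p * max(wi)
    sigma2 <- if (dof > 0) sum(wi * resid^2) / dof else 0
    se[j] <- sqrt(max(sigma2, 0) * sum(l^2))
  }
  list(fitted = fitted, se = se)
}

#' Predict a fitted loess model on new time points
#'
#' Re-solves the local regression at the requested times. Extrapolation
#' outside the source range is refused unless explicitly enabled.
#'
#' @param object a `cyto_loess` model.
#' @param times POSIXct vector of query times.
#' @param allow_extrapolation logical (default `FALSE`).
#' @param ... unused.
#' @return data frame with `time`, `value`, `se`.
#' @export
predict.cyto_loess <- function(object, times, allow_extrapolation = FALSE, ...) {
  x0 <- hours_since(as_utc(times), object$origin)
  rng <- range(object$x_h)
  if (!allow_extrapolation && (any(x0 < rng[1]) || any(x0 > rng[2]))) {
    stop("prediction outside the observed time range; set ",
         "`allow_extrapolation = TRUE` to override", call. = FALSE)
  }
  fit <- .loess_solve(object$x_h, object$y, x0, object$q, object$degree)
  data.frame(time = as_utc(times), value = fit$fitted, se = fit$se)
}

#' Regularize an irregular series onto an hourly grid
#'
#' Convenience wrapper: fits a loess model and returns the regular fitted
#' series with pointwise standard errors. Grid points farther than
#' `max_gap_h` from any source observation (e.g. inside an instrument outage)
#' are flagged `low_confidence`.
#'
#' @inheritParams loess_fit
#' @param max_gap_h flag grid points farther than this many hours from the
#'   nearest source point (default 6).
#' @return data frame of class `cyto_regular` with columns `time`, `value`,
#'   `se`, `low_confidence`; attributes `variable`, `units`, `span`, `degree`.
#' @export
regularize <- function(ts, span, degree = 2, step_h = 1, max_gap_h = 6) {
  model <- loess_fit(ts, span, degree, step_h)
  time <- model$origin + model$grid_h * 3600
  nearest <- vapply(model$grid_h, function(g) min(abs(model$x_h - g)), numeric(1))
  out <- data.frame(time = time, value = model$fitted, se = model$se,
                    low_confidence = nearest > max_gap_h)
  attr(out, "variable") <- model$variable
  attr(out, "units") <- model$units
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  attr(out, "step_h") <- step_h
  class(out) <- c("cyto_regular", "data.frame")
  out
}

#' Slopes of the fitted grid values
#'
#' Central finite differences on the regular fitted values, one-sided at the
#' two ends; units per hour.
#'
#' @param model a `cyto_loess` model (or use `loess_slope_values()` on a bare
#'   numeric vector).
#' @return numeric vector of slopes, one per grid point.
#' @export
loess_slope <- function(model) {
  stopifnot(inherits(model, "cyto_loess"))
  model$slopes
}

#' @rdname loess_slope
#' @param fitted numeric vector of regular fitted values.
#' @param step_h grid spacing in hours.
#' @export
loess_slope_values <- function(fitted, step_h = 1) {
  m <- length(fitted)
  if (m < 2) stop("need at least 2 grid points for slopes", call. = FALSE)
  slopes <- numeric(m)
  slopes[1] <- (fitted[2] - fitted[1]) / step_h
  slopes[m] <- (fitted[m] - fitted[m - 1]) / step_h
  if (m > 2) {
    slopes[2:(m - 1)] <- (fitted[3:m] - fitted[1:(m - 2)]) / (2 * step_h)
  }
  slopes
}

#' @export
print.cyto_loess <- function(x, ...) {
  cat(sprintf("<cyto_loess> %s: n = %d, span = %.3f (q = %d), degree = %d, grid = %d pts\n",
              x$variable, length(x$y), x$span, x$q, x$degree, length(x$grid_h)))
  invisible(x)
}
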