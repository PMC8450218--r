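# Smoothing and resampling of raw digitizer traces.
#
# Each coordinate of a trace is fitted as a quadratic polynomial of the
# normalized cumulative chord length of the raw points (a monotone abscissa that
# is robust to variable hand speed at the fixed digitizer sampling rate). The
# fitted space curve is then evaluated at 20 points with equal arc-length
# spacing; fascicle length is the sum of the 19 segment lengths.

# 5-point Gauss-Legendre rule on [-1, 1]
GL5_X <- c(-0.906179845938664, -0.5384693101056831, 0,
           0.5384693101056831, 0.906179845938664)
GL5_W <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
           0.4786286704993665, 0.2369268850561891)

#' Fit a quadratic space curve to a raw fascicle trace
#'
#' @param trace Data frame (or matrix) with the digitized points of one
#'   fascicle: columns `x_mm, y_mm, z_mm` (a full point table with a single
#'   `fascicle_id` is accepted).
#' @return An object of class `fascicle_curve`: quadratic coefficients per
#'   coordinate, the fit residual RMS (mm), and the parameter range.
#' @export
smooth_fascicle <- function(trace) {
  m <- if (is.matrix(trace)) trace else {
    if (!all(c("x_mm", "y_mm", "z_mm") %in% names(trace))) {
      abort("`trace` needs columns x_mm, y_mm, z_mm")
    }
    if ("fascicle_id" %in% names(trace) &&
        length(unique(trace$fascicle_id)) > 1) {
      abort("`trace` must contain a single fascicle")
    }
    as.matrix(trace[, c("x_mm", "y_mm", "z_mm")])
  }
  if (nrow(m) < 3) abort("quadratic smoothing needs at least 3 points")
  if (any(!is.finite(m))) abort("trace contains non-finite coordinates")
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) abort("zero-length trace: all points identical")
  s <- c(0, cumsum(seg)) / total
  X <- cbind(1, s, s^2)
  fit <- .lm.fit(X, m)
  coefs <- matrix(coef(fit), nrow = 3,
                  dimnames = list(c("c0", "c1", "c2"), c("x", "y", "z")))
  res <- m - X %*% coefs
  structure(
    list(coef = coefs,
         residual_rms = sqrt(mean(rowSums(res^2))),
         n_raw = nrow(m)),
    class = "fascicle_curve"
  )
}

#' @export
print.fascicle_curve <- function(x, ...) {
  cat("Quadratic fascicle curve (", x$n_raw, " raw points, residual RMS ",
      format(x$residual_rms, digits = 4), " mm)\n", sep = "")
  invisible(x)
}

curve_eval <- function(curve, u) {
  cbind(1, u, u^2) %*% curve$coef
}

curve_speed <- function(curve, u) {
  d <- cbind(0, 1, 2 * u) %*% curve$coef
  sqrt(rowSums(d^2))
}

# Arc length of the fitted curve from 0 to each value of `u` (Gauss-Legendre
# on a fine subdivision; effectively exact for the smooth quadratic speed).
curve_arclength <- function(curve, u, n_grid = 256) {
  grid <- seq(0, 1, length.out = n_grid + 1)
  h <- grid[2] - grid[1]
  # cumulative integral at grid nodes
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  nodes <- outer(GL5_X * h / 2, mid, `+`)      # 5 x n_grid
  sp <- matrix(curve_speed(curve, as.vector(nodes)), nrow = 5)
  inc <- as.vector(GL5_W %*% sp) * h / 2
  cumS <- c(0, cumsum(inc))
  S_of <- function(uu) {
    j <- pmin(pmax(findInterval(uu, grid), 1L), n_grid)
    a <- grid[j]
    part <- vapply(seq_along(uu), function(k) {
      if (uu[k] <= a[k]) return(0)
      half <- (uu[k] - a[k]) / 2
      x <- a[k] + half * (GL5_X + 1)
      sum(GL5_W * curve_speed(curve, x)) * half
    }, numeric(1))
    cumS[j] + part
  }
  list(S = S_of, total = cumS[n_grid + 1], grid = grid, cum = cumS)
}

# Invert arc length: u such that S(u) = s, safeguarded Newton within the
# bracketing grid cell (tolerance ~1e-12 of the total length).
invert_arclength <- function(curve, arc, targets) {
  tol <- max(arc$total * 1e-13, 1e-15)
  vapply(targets, function(s) {
    if (s <= 0) return(0)
    if (s >= arc$total) return(1)
    j <- findInterval(s, arc$cum, rightmost.closed = TRUE)
    lo <- arc$grid[j]; hi <- arc$grid[j + 1]
    u <- lo + (hi - lo) * (s - arc$cum[j]) /
      max(arc$cum[j + 1] - arc$cum[j], .Machine$double.xmin)
    for (it in 1:60) {
      f <- arc$S(u) - s
      if (abs(f) < tol) break
      if (f > 0) hi <- u else lo <- u
      sp <- curve_speed(curve, u)
      u_new <- if (sp > 1e-12) u - f / sp else (lo + hi) / 2
      u <- if (u_new <= lo || u_new >= hi) (lo + hi) / 2 else u_new
    }
    u
  }, numeric(1))
}

#' Resample a fitted fascicle curve to equidistant points
#'
#' Evaluates the quadratic space curve at `n` points whose spacing is equal in
#' arc length along the curve (default, matching the definition of fascicle
#' length as the sum of segment lengths) or equal in the fit parameter.
#'
#' @param curve A `fascicle_curve` from [smooth_fascicle()].
#' @param n Number of points (default 20).
#' @param spacing `"arc"` (equal arc length) or `"parameter"`.
#' @return Matrix `n` x 3 of coordinates (mm).
#' @export
resample_fascicle <- function(curve, n = 20, spacing = c("arc", "parameter")) {
  stopifnot(inherits(curve, "fascicle_curve"), n >= 2)
  spacing <- match.arg(spacing)
  if (spacing == "parameter") {
    u <- seq(0, 1, length.out = n)
  } else {
    arc <- curve_arclength(curve)
    if (arc$total <= 0) abort("zero-length curve cannot be resampled")
    u <- invert_arclength(curve, arc, seq(0, arc$total, length.out = n))
  }
  out <- curve_eval(curve, u)
  colnames(out) <- c("x_mm", "y_mm", "z_mm")
  out
}

#' Smooth and resample all fascicle traces of a dataset
#'
#' The standard preprocessing step: every raw trace is quadratically smoothed
#' and resampled to `n_points` arc-length-equidistant points. Traces with fewer
#' than 3 points are dropped with a warning.
#'
#' @param points Raw fascicle point tibble.
#' @param n_points Points per fascicle after resampling (default 20).
#' @param spacing Passed to [resample_fascicle()].
#' @return Tibble of resampled fascicle points; the per-fascicle smoothing
#'   diagnostics (residual RMS, arc length) are attached as the `smoothing`
#'   attribute, and landmarks/metadata attributes are preserved.
#' @export
#' @examples
#' sim <- simulate_muscle(n_fascicles = 8, seed = 1)
#' smooth <- preprocess_fascicles(sim$points)
#' attr(smooth, "smoothing")
preprocess_fascicles <- function(points, n_points = 20,
                                 spacing = c("arc", "parameter")) {
  spacing <- match.arg(spacing)
  mats <- fascicle_split(points)
  short <- names(mats)[vapply(mats, nrow, integer(1)) < 3]
  if (length(short) > 0) {
    warn(sprintf("dropping %d trace(s) with fewer than 3 points: %s",
                 length(short), paste(short, collapse = ", ")))
    mats <- mats[!names(mats) %in% short]
  }
  if (length(mats) == 0) abort("no traces with at least 3 points")
  curves <- lapply(mats, smooth_fascicle)
  res <- lapply(curves, resample_fascicle, n = n_points, spacing = spacing)
  out <- fascicles_to_tbl(res, template = points)
  attr(out, "smoothing") <- tibble::tibble(
    fascicle_id = names(curves),
    residual_rms_mm = unname(vapply(curves, function(cv) cv$residual_rms,
                                    numeric(1))),
    arc_length_mm = unname(vapply(res, polyline_length, numeric(1)))
  )
  out
}

#' Per-fascicle lengths and midpoints
#'
#' @param points Fascicle point tibble (typically preprocessed).
#' @return Tibble with `fascicle_id`, arc length `length_mm` and the arc-length
#'   midpoint coordinates.
#' @export
fascicle_lengths <- function(points) {
  mats <- fascicle_split(points)
  mids <- t(vapply(mats, polyline_midpoint, numeric(3)))
  tibble::tibble(
    fascicle_id = names(mats),
    length_mm = unname(vapply(mats, polyline_length, numeric(1))),
    mid_x_mm = unname(mids[, 1]), mid_y_mm = unname(mids[, 2]),
    mid_z_mm = unname(mids[, 3])
  )
}
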