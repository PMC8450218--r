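# Synthetic unipennate muscle generator with analytic ground truth.
#
# The phantom emulates the geometry of a primarily unipennate calf muscle:
# fascicles run between two superficial aponeurosis sheets separated by the
# muscle height, all tilted by the pennation angle in the length-height plane
# (transversal angle 0 — the unipennate idealization), placed on a jittered
# grid over length x width. Fascicle lengths are drawn from a normal law with
# similar standard deviation across ages; an optional central crest tilts the
# two halves of the upper sheet; an optional quadratic bow and Gaussian
# digitizer noise exercise the smoothing stage. Default dimensions mirror a
# young rabbit plantaris (about 250 digitized fascicles, belly 50.8 x 7.7 mm,
# fascicles 13.7 +/- 1.2 mm at 11.6 degrees, free tendon 14.5 mm) and the
# digitizer accuracy of 0.076 mm.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a unipennate muscle with known architecture
#'
#' Generates raw digitizer-style fascicle traces plus the analytic ground-truth
#' architecture of the constructed geometry (computed from the exact curves,
#' not through the measurement pipeline).
#'
#' @param n_fascicles Number of fascicles (default 252).
#' @param belly_length,belly_width Nominal belly dimensions (mm).
#' @param fascicle_length_mean,fascicle_length_sd Normal law for fascicle
#'   lengths (mm).
#' @param pennation_mean Mean pennation angle (degrees).
#' @param height Sheet separation (mm); derived as
#'   `fascicle_length_mean * sin(pennation_mean)` when `NULL`.
#' @param crest_angle Dihedral tilt of the two halves of the upper aponeurosis
#'   (degrees; 0 = planar).
#' @param curvature Quadratic bow amplitude at the fascicle midpoint (mm).
#' @param noise_sd Gaussian digitizer noise, per coordinate (mm).
#' @param free_tendon Free tendon length encoded in the MTC landmarks (mm);
#'   `NULL` for no landmarks.
#' @param points_per_trace Raw points per digitized trace.
#' @param seed Integer seed for bit-reproducible output (restores the global
#'   RNG state afterwards).
#' @return A list with `points` (raw trace tibble, landmarks/metadata attached),
#'   `truth` (one-row tibble of ground-truth parameters), `frame` (the exact
#'   construction frame as a [muscle_frame()], endpoint membership included),
#'   and `config`.
#' @export
#' @examples
#' sim <- simulate_muscle(n_fascicles = 20, seed = 42)
#' sim$truth$fascicle_length_mean_mm
simulate_muscle <- function(n_fascicles = 252,
                            belly_length = 50.8,
                            belly_width = 7.7,
                            fascicle_length_mean = 13.7,
                            fascicle_length_sd = 1.2,
                            pennation_mean = 11.6,
                            height = NULL,
                            crest_angle = 0,
                            curvature = 0,
                            noise_sd = 0.076,
                            free_tendon = 14.5,
                            points_per_trace = 25,
                            seed = NULL) {
  stopifnot(n_fascicles >= 4, belly_length > 0, belly_width > 0,
            fascicle_length_mean > 0, fascicle_length_sd >= 0,
            pennation_mean > 0, pennation_mean < 90,
            crest_angle >= 0, crest_angle < 90,
            curvature >= 0, noise_sd >= 0, points_per_trace >= 5)
  beta0 <- deg2rad(pennation_mean)
  h <- if (is.null(height)) fascicle_length_mean * sin(beta0) else height
  if (h <= 0) abort("muscle height must be positive")
  if (fascicle_length_mean <= h) {
    abort(sprintf(
      "infeasible geometry: mean fascicle length %.2f mm does not span the sheet separation %.2f mm",
      fascicle_length_mean, h))
  }
  chord0 <- sqrt(fascicle_length_mean^2 - h^2)
  x_span <- belly_length - chord0
  if (x_span <= 0) {
    abort(sprintf(
      "infeasible geometry: belly length %.2f mm is shorter than one fascicle's length-axis span %.2f mm",
      belly_length, chord0))
  }

  with_local_seed(seed, {
    # grid over length x width
    n_wid <- max(2L, as.integer(round(sqrt(n_fascicles * belly_width / x_span))))
    n_len <- max(2L, as.integer(ceiling(n_fascicles / n_wid)))
    gx <- seq(0, x_span, length.out = n_len)
    gy <- seq(-belly_width / 2, belly_width / 2, length.out = n_wid)
    cells <- expand.grid(ix = seq_len(n_len), iy = seq_len(n_wid))
    # fill row by row along the length axis; within the last, partial row take
    # central width columns first so no systematic length-width covariance
    # (and hence no spurious frame tilt) is introduced
    centrality <- abs(cells$iy - (n_wid + 1) / 2)
    cells <- cells[order(cells$ix, centrality, cells$iy),
                   , drop = FALSE][seq_len(n_fascicles), ]
    dx <- if (n_len > 1) gx[2] - gx[1] else 0
    dy <- if (n_wid > 1) gy[2] - gy[1] else 0

    lens <- fascicle_length_mean + fascicle_length_sd * stats::rnorm(n_fascicles)
    x0 <- gx[cells$ix] + stats::runif(n_fascicles, -0.3, 0.3) * dx
    y0 <- gy[cells$iy] + stats::runif(n_fascicles, -0.3, 0.3) * dy

    lift <- tan(deg2rad(crest_angle)) * (belly_width / 2 - abs(y0))
    span <- h + lift
    bad <- lens <= span
    if (any(bad)) {
      abort(sprintf(
        "infeasible geometry: %d fascicle length(s) shorter than the local sheet separation (min length %.2f mm, max separation %.2f mm)",
        sum(bad), min(lens), max(span)))
    }
    dxf <- sqrt(lens^2 - span^2)

    ids <- sprintf("f%03d", seq_len(n_fascicles))
    p1 <- cbind(x0, y0, -h / 2)
    p2 <- cbind(x0 + dxf, y0, -h / 2 + span)

    # exact quadratic curve: chord + symmetric bow in the vertical plane
    curve_pts <- function(i, t) {
      chord <- p2[i, ] - p1[i, ]
      base <- outer(rep(1, length(t)), p1[i, ]) + outer(t, chord)
      if (curvature > 0) {
        u <- chord / sqrt(sum(chord^2))
        zv <- c(0, 0, 1)
        nv <- zv - sum(zv * u) * u
        nn <- sqrt(sum(nv^2))
        if (nn > 1e-12) {
          base <- base + outer(4 * curvature * t * (1 - t), nv / nn)
        }
      }
      base
    }

    # raw traces: monotone jittered parameter, then digitizer noise
    traces <- vector("list", n_fascicles)
    for (i in seq_len(n_fascicles)) {
      w <- stats::runif(points_per_trace - 1, 0.5, 1.5)
      t <- c(0, cumsum(w)) / sum(w)
      traces[[i]] <- curve_pts(i, t)
    }
    if (noise_sd > 0) {
      for (i in seq_len(n_fascicles)) {
        traces[[i]] <- traces[[i]] +
          matrix(stats::rnorm(3 * points_per_trace, 0, noise_sd),
                 ncol = 3)
      }
    }
    names(traces) <- ids
    points <- fascicles_to_tbl(traces)

    # ground truth from the exact construction
    tt <- seq(0, 1, length.out = 513)
    exact_len <- numeric(n_fascicles)
    x_lo <- Inf; x_hi <- -Inf
    for (i in seq_len(n_fascicles)) {
      ep <- curve_pts(i, tt)
      exact_len[i] <- polyline_length(ep)
      x_lo <- min(x_lo, ep[, 1]); x_hi <- max(x_hi, ep[, 1])
    }
    x_rng <- c(x_lo, x_hi)
    beta_i <- rad2deg(asin(span / lens))
    apo_len <- function(x) max(x) - min(x)
    upper_x <- p2[, 1]; lower_x <- p1[, 1]
    vol_truth <- if (crest_angle == 0 && curvature == 0) {
      (max(x0) - min(x0)) * h * (max(y0) - min(y0))
    } else NA_real_
    mean_lf <- mean(exact_len)
    truth <- tibble::tibble(
      n_fascicles = n_fascicles,
      belly_length_mm = x_rng[2] - x_rng[1],
      belly_width_mm = max(y0) - min(y0),
      fascicle_length_mean_mm = mean_lf,
      fascicle_length_sd_mm = sd(exact_len),
      pennation_mean_deg = mean(beta_i),
      pennation_sd_deg = sd(beta_i),
      transversal_mean_deg = 0,
      transversal_sd_deg = 0,
      aponeurosis_length_upper_mm = apo_len(upper_x),
      aponeurosis_length_lower_mm = apo_len(lower_x),
      aponeurosis_length_mm = (apo_len(upper_x) + apo_len(lower_x)) / 2,
      aponeurosis_width_upper_mm = max(y0) - min(y0),
      aponeurosis_width_lower_mm = max(y0) - min(y0),
      aponeurosis_width_mm = max(y0) - min(y0),
      muscle_height_mm = mean(p2[, 3]) - mean(p1[, 3]),
      muscle_volume_mm3 = vol_truth,
      muscle_mass_g = vol_truth * MUSCLE_DENSITY_G_MM3,
      pcsa_mm2 = vol_truth / mean_lf,
      free_tendon_mm = if (is.null(free_tendon)) NA_real_ else free_tendon
    )

    if (!is.null(free_tendon)) {
      landmarks <- tibble::tibble(
        name = c("origin", "insertion"),
        x_mm = c(x_rng[1], x_rng[2] + free_tendon),
        y_mm = c(0, 0), z_mm = c(0, 0)
      )
      points <- set_muscle_attrs(points, landmarks = landmarks)
    }
    points <- set_muscle_attrs(points, metadata = list(
      generator = "pennate::simulate_muscle", seed = seed
    ))

    # exact construction frame; with e3 = +y the B->A normal convention puts
    # aponeurosis A on the lower sheet (trace start)
    true_frame <- muscle_frame(c(1, 0, 0), c(0, 1, 0),
                               origin = c(mean(x0), mean(y0), 0))
    true_frame$membership <- tibble::tibble(
      fascicle_id = rep(ids, each = 2),
      end = rep(c(1L, 2L), n_fascicles),
      aponeurosis = rep(c("A", "B"), n_fascicles)
    )
    list(points = points,
         truth = truth,
         frame = true_frame,
         config = list(n_fascicles = n_fascicles, belly_length = belly_length,
                       belly_width = belly_width,
                       fascicle_length_mean = fascicle_length_mean,
                       fascicle_length_sd = fascicle_length_sd,
                       pennation_mean = pennation_mean, height = h,
                       crest_angle = crest_angle, curvature = curvature,
                       noise_sd = noise_sd, free_tendon = free_tendon,
                       points_per_trace = points_per_trace, seed = seed))
  })
}
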