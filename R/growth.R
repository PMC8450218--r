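# Four-parameter growth transformation for unipennate muscles.
#
# Growth is modelled as the superposition of four geometric operations applied
# per fascicle: (1) scaling in belly length by shifting fascicles along e1 in
# proportion to their midpoint coordinate, with a correction factor f_c that
# makes the belly extent hit the target exactly; (2) scaling in belly width by
# shifting fascicles away from a dividing plane along per-side transversal
# directions y-/y+; (3) homogeneous fascicle lengthening, with endpoint
# displacements proportional to the endpoint's distance to the muscle's line of
# action; (4) rigid rotation of each fascicle about its midpoint changing the
# pennation angle by delta_beta while leaving the transversal angle unchanged.
# The frame, belly dimensions, side split and line of action are determined
# once from the input dataset.

#' Precompute the growth context of a dataset
#'
#' @param points Preprocessed fascicle point tibble.
#' @param landmarks Optional landmarks; default from the attribute. When both
#'   `origin` and `insertion` are present the line of action runs through them,
#'   otherwise along `e1` through the centroid of all fascicle points.
#' @param frame Optional `muscle_frame` (with endpoint membership) to use
#'   instead of the PCA estimate — e.g. the exact construction frame of a
#'   phantom, so transformation contracts can be studied without
#'   frame-estimation error.
#' @return An object of class `growth_context`: the muscle frame, belly
#'   dimensions, per-fascicle midpoint coordinates `x_F` (from the proximal
#'   extreme), the [build_side_split()] result, and the line of action.
#' @export
growth_context <- function(points, landmarks = muscle_landmarks(points),
                           frame = NULL) {
  if (is.null(frame)) frame <- compute_frame(points, landmarks = landmarks)
  mats <- fascicle_split(points)
  mids <- t(vapply(mats, polyline_midpoint, numeric(3)))
  all_t1 <- all_coords(points) %*% frame$e1
  x_min <- min(all_t1)
  dims <- belly_dims(points, frame)
  loa <- NULL
  if (!is.null(landmarks)) {
    o <- landmark_coord(landmarks, "origin")
    i <- landmark_coord(landmarks, "insertion")
    if (!is.null(o) && !is.null(i)) {
      loa <- list(point = o, dir = unitize(i - o))
    }
  }
  if (is.null(loa)) {
    loa <- list(point = colMeans(all_coords(points)), dir = frame$e1)
  }
  structure(
    list(frame = frame,
         belly_length_mm = dims[["belly_length_mm"]],
         belly_width_mm = dims[["belly_width_mm"]],
         x_min = x_min,
         x_F = as.vector(mids %*% frame$e1) - x_min,
         midpoints = mids,
         side_split = build_side_split(points, frame),
         line_of_action = loa,
         fascicle_ids = names(mats)),
    class = "growth_context"
  )
}

#' @export
print.growth_context <- function(x, ...) {
  cat(sprintf("Growth context: belly %.1f x %.1f mm, %d fascicles\n",
              x$belly_length_mm, x$belly_width_mm, length(x$fascicle_ids)))
  invisible(x)
}

# Belly e1-extent after shifting each fascicle by x_F * g along e1.
shifted_extent <- function(mats, ctx, g) {
  e1 <- ctx$frame$e1
  lo <- Inf; hi <- -Inf
  for (k in seq_along(mats)) {
    t1 <- mats[[k]] %*% e1 + ctx$x_F[k] * g
    lo <- min(lo, min(t1)); hi <- max(hi, max(t1))
  }
  hi - lo
}

#' Correction factor for belly length scaling
#'
#' Shifting fascicles by `x_F * (delta_L_MB / L_MB)` moves only midpoints and
#' therefore under-shoots the intended belly length change; the correction
#' factor `f_c >= 1` is the unique value for which the shifted point cloud's
#' extent along `e1` equals `L_MB + delta_L_MB` (found by bisection, 1e-9 mm).
#'
#' @param points Preprocessed fascicle point tibble.
#' @param delta_L_MB Belly length change (mm).
#' @param ctx Optional precomputed [growth_context()].
#' @return The correction factor `f_c` (1 when `delta_L_MB = 0`).
#' @export
determine_fc <- function(points, delta_L_MB, ctx = NULL) {
  if (is.null(ctx)) ctx <- growth_context(points)
  if (delta_L_MB == 0) return(1)
  L <- ctx$belly_length_mm
  if (delta_L_MB <= -L) abort("delta_L_MB must exceed -L_MB")
  mats <- fascicle_split(points)
  target <- L + delta_L_MB
  phi <- function(f) shifted_extent(mats, ctx, (delta_L_MB / L) * f) - target
  lo <- 1; hi <- 10
  plo <- phi(lo); phi_hi <- phi(hi)
  if (plo == 0) return(lo)
  if (plo * phi_hi > 0) abort("no correction factor in [1, 10]; pathological geometry")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    pm <- phi(mid)
    if (abs(pm) < 1e-10 || (hi - lo) < 1e-14) return(mid)
    if (pm * plo <= 0) hi <- mid else { lo <- mid; plo <- pm }
  }
  (lo + hi) / 2
}

#' Scale the muscle in belly length direction
#'
#' Each fascicle is translated rigidly along `e1` by
#' `x_F * (delta_L_MB / L_MB) * f_c` (its midpoint coordinate measured from the
#' proximal extreme). Fascicle lengths and angles are unchanged; the belly
#' extent becomes `L_MB + delta_L_MB`.
#'
#' @inheritParams determine_fc
#' @param f_c Correction factor; computed by [determine_fc()] when `NULL`.
#' @return Transformed fascicle point tibble.
#' @export
scale_length <- function(points, delta_L_MB, ctx = NULL, f_c = NULL) {
  if (delta_L_MB == 0) return(points)
  if (is.null(ctx)) ctx <- growth_context(points)
  if (is.null(f_c)) f_c <- determine_fc(points, delta_L_MB, ctx = ctx)
  g <- (delta_L_MB / ctx$belly_length_mm) * f_c
  mats <- fascicle_split(points)
  out <- lapply(seq_along(mats), function(k) {
    sweep(mats[[k]], 2, ctx$x_F[k] * g * ctx$frame$e1, `+`)
  })
  names(out) <- names(mats)
  fascicles_to_tbl(out, template = points)
}

#' Transversal scaling directions on the two sides of the muscle
#'
#' The cross section is divided by the plane spanned by `e1` and `e2` through
#' the centroid of the fascicle midpoints. On each side, the endpoints of
#' aponeurosis A (the crested side for non-planar muscles) define — by
#' principal component analysis — a local sheet whose in-plane width direction
#' (orthogonal to `e1`, pointing away from the dividing plane) becomes the
#' side's scaling direction `y-` or `y+`. A side with fewer than 3 endpoints
#' falls back to `-e3`/`+e3` with a warning.
#'
#' @param points Preprocessed fascicle point tibble.
#' @param frame A [compute_frame()] result.
#' @return An object of class `side_split`: dividing-plane `point` and `normal`
#'   (`e3`), and unit vectors `y_minus`, `y_plus`.
#' @export
build_side_split <- function(points, frame) {
  mats <- fascicle_split(points)
  mids <- t(vapply(mats, polyline_midpoint, numeric(3)))
  plane_point <- colMeans(mids)
  both <- aponeurosis_points(points, frame)
  # use the crested (least planar) aponeurosis: larger out-of-plane variance
  resid <- vapply(both, function(m) {
    if (nrow(m) < 3) return(0)
    pca_axes(m)$values[3]
  }, numeric(1))
  ap <- if (resid[["B"]] > resid[["A"]]) both$B else both$A
  side_coord <- as.vector(sweep(ap, 2, plane_point) %*% frame$e3)
  side_dir <- function(sign_side) {
    pts <- ap[if (sign_side > 0) side_coord > 0 else side_coord < 0, , drop = FALSE]
    if (nrow(pts) < 3) {
      warn(sprintf("side %s of the dividing plane has < 3 aponeurosis points; using %se3",
                   if (sign_side > 0) "+" else "-", if (sign_side > 0) "+" else "-"))
      return(sign_side * frame$e3)
    }
    pc <- pca_axes(pts)
    nrm <- pc$vectors[, 3]
    y <- cross3(nrm, frame$e1)
    y <- y - sum(y * frame$e1) * frame$e1  # numerically enforce y . e1 = 0
    ny <- sqrt(sum(y^2))
    if (ny < 1e-9) {
      warn("degenerate side sheet; using +/-e3")
      return(sign_side * frame$e3)
    }
    y <- y / ny
    if (sum(y * frame$e3) * sign_side < 0) y <- -y
    y
  }
  structure(
    list(point = plane_point, normal = frame$e3,
         y_minus = side_dir(-1), y_plus = side_dir(+1)),
    class = "side_split"
  )
}

#' Scale the muscle in belly width direction
#'
#' Each fascicle is translated rigidly along its side's transversal direction by
#' `y_F * (delta_W_MB / W_MB)`, where `y_F` is the distance of the fascicle
#' midpoint from the dividing plane measured along that direction. Displacements
#' are orthogonal to `e1`, so the belly length is unchanged.
#'
#' @inheritParams scale_length
#' @param delta_W_MB Belly width change (mm).
#' @return Transformed fascicle point tibble.
#' @export
scale_width <- function(points, delta_W_MB, ctx = NULL) {
  if (delta_W_MB == 0) return(points)
  if (is.null(ctx)) ctx <- growth_context(points)
  W <- ctx$belly_width_mm
  if (W <= 0) abort("belly width must be positive")
  ss <- ctx$side_split
  mats <- fascicle_split(points)
  mids <- t(vapply(mats, polyline_midpoint, numeric(3)))
  d3 <- as.vector(sweep(mids, 2, ss$point) %*% ss$normal)
  out <- lapply(seq_along(mats), function(k) {
    y_dir <- if (d3[k] >= 0) ss$y_plus else ss$y_minus
    denom <- sum(y_dir * ss$normal)
    y_F <- if (abs(denom) > 1e-9) d3[k] / denom else abs(d3[k])
    sweep(mats[[k]], 2, abs(y_F) * (delta_W_MB / W) * y_dir, `+`)
  })
  names(out) <- names(mats)
  fascicles_to_tbl(out, template = points)
}

#' Lengthen every fascicle homogeneously
#'
#' Each fascicle is stretched affinely along its chord direction about an
#' anchor placed on the chord at the fraction `d1 / (d1 + d2)` from endpoint 1,
#' where `d1`, `d2` are the endpoints' perpendicular distances to the muscle's
#' line of action. The stretch factor is solved so the resampled arc length
#' equals `L_F + delta_L_F` (1e-9 mm). For straight fascicles the endpoint
#' displacements then satisfy `|u2|/|u1| = d2/d1` and `|u1|+|u2| = delta_L_F`
#' exactly; fascicle curvature never increases.
#'
#' @inheritParams scale_length
#' @param delta_L_F Fascicle length change (mm); must keep all lengths positive.
#' @return Transformed fascicle point tibble.
#' @export
lengthen_fascicles <- function(points, delta_L_F, ctx = NULL) {
  if (delta_L_F == 0) return(points)
  if (is.null(ctx)) ctx <- growth_context(points)
  loa <- ctx$line_of_action
  mats <- fascicle_split(points)
  warned <- FALSE
  out <- lapply(mats, function(m) {
    p1 <- m[1, ]; p2 <- m[nrow(m), ]
    perp_dist <- function(p) {
      v <- p - loa$point
      sqrt(max(sum(v^2) - sum(v * loa$dir)^2, 0))
    }
    d1 <- perp_dist(p1); d2 <- perp_dist(p2)
    if (d1 + d2 < 1e-12) {
      if (!warned) {
        warn("fascicle lies on the line of action; splitting delta_L_F equally")
        warned <<- TRUE
      }
      frac <- 0.5
    } else frac <- d1 / (d1 + d2)
    chord <- p2 - p1
    if (sqrt(sum(chord^2)) < 1e-12) abort("fascicle with zero chord length")
    u_hat <- unitize(chord)
    anchor <- p1 + frac * chord
    rel <- sweep(m, 2, anchor)
    a <- as.vector(rel %*% u_hat)
    perp <- rel - outer(a, u_hat)
    da <- diff(a)
    dperp2 <- rowSums((perp[-1, , drop = FALSE] - perp[-nrow(perp), , drop = FALSE])^2)
    arc_of <- function(k) sum(sqrt((k * da)^2 + dperp2))
    L <- arc_of(1)
    target <- L + delta_L_F
    if (target <= 0) abort("delta_L_F would make a fascicle length non-positive")
    if (target < sum(sqrt(dperp2))) {
      abort("delta_L_F is below the transverse residual of a curved fascicle")
    }
    lo <- 0; hi <- 2
    while (arc_of(hi) < target) hi <- hi * 2
    for (it in 1:200) {
      k <- (lo + hi) / 2
      f <- arc_of(k) - target
      if (abs(f) < 1e-12 || (hi - lo) < 1e-15) break
      if (f > 0) hi <- k else lo <- k
    }
    sweep(outer(k * a, u_hat) + perp, 2, anchor, `+`)
  })
  names(out) <- names(mats)
  fascicles_to_tbl(out, template = points)
}

#' Rotate every fascicle to change its pennation angle
#'
#' Each fascicle polyline is rotated rigidly by `delta_beta` about the axis
#' through its arc-length midpoint perpendicular to the vertical plane spanned
#' by `e2` and the chord's projection onto the aponeurosis plane. Pennation
#' increases by exactly `delta_beta` (clamped to \[0, 90\] degrees with a
#' warning), the transversal angle, fascicle length and midpoint are unchanged.
#' Fascicles at `beta = 90` (undefined projection) are skipped with a warning.
#'
#' @inheritParams scale_length
#' @param delta_beta Pennation angle change (degrees).
#' @return Transformed fascicle point tibble.
#' @export
rotate_fascicles <- function(points, delta_beta, ctx = NULL) {
  if (delta_beta == 0) return(points)
  if (is.null(ctx)) ctx <- growth_context(points)
  e2 <- ctx$frame$e2
  mats <- fascicle_split(points)
  clamped <- character(0); skipped <- character(0)
  out <- lapply(seq_along(mats), function(kk) {
    m <- mats[[kk]]
    chord <- m[nrow(m), ] - m[1, ]
    c2 <- sum(chord * e2)
    proj <- chord - c2 * e2
    np <- sqrt(sum(proj^2))
    if (np < 1e-12 * sqrt(sum(chord^2))) {
      skipped <<- c(skipped, names(mats)[kk])
      return(m)
    }
    cp <- proj / np
    s <- if (c2 >= 0) 1 else -1
    z <- s * e2
    beta <- rad2deg(atan2(abs(c2), np))
    db <- delta_beta
    if (beta + db > 90) { db <- 90 - beta; clamped <<- c(clamped, names(mats)[kk]) }
    if (beta + db < 0) { db <- -beta; clamped <<- c(clamped, names(mats)[kk]) }
    th <- deg2rad(db)
    R <- diag(3) +
      sin(th) * (outer(z, cp) - outer(cp, z)) +
      (cos(th) - 1) * (outer(cp, cp) + outer(z, z))
    mid <- polyline_midpoint(m)
    sweep(sweep(m, 2, mid) %*% t(R), 2, mid, `+`)
  })
  if (length(skipped) > 0) {
    warn(sprintf("skipped %d fascicle(s) at beta = 90 deg: %s",
                 length(skipped), paste(skipped, collapse = ", ")))
  }
  if (length(clamped) > 0) {
    warn(sprintf("pennation clamped to [0, 90] deg for %d fascicle(s)",
                 length(clamped)))
  }
  names(out) <- names(mats)
  res <- fascicles_to_tbl(out, template = points)
  attr(res, "clamped") <- clamped
  attr(res, "skipped") <- skipped
  res
}

#' Grow a muscle by the four architectural parameters
#'
#' Applies the full growth transformation — length scaling, width scaling,
#' fascicle lengthening, fascicle rotation, in that order — with the frame,
#' belly dimensions, side split and line of action determined once from the
#' input. The length-scaling rate (equivalently `f_c`) is solved by bisection
#' on the *composed* transformation so that the output belly length equals
#' `L_MB + delta_L_MB` to 1e-9 mm even though the later operations also move
#' points along `e1`. With all four parameters zero the input is returned
#' unchanged.
#'
#' @param points Preprocessed fascicle point tibble.
#' @param delta_L_MB Belly length change (mm).
#' @param delta_W_MB Belly width change (mm).
#' @param delta_L_F Fascicle length change (mm).
#' @param delta_beta Pennation angle change (degrees).
#' @param landmarks Optional landmarks (line of action); default from attribute.
#' @param ctx Optional precomputed [growth_context()].
#' @return The grown fascicle point tibble. Attribute `growth` records the
#'   parameters, the solved scaling rate and `f_c`, and the achieved belly
#'   length. Landmarks are dropped (their grown positions are not modelled);
#'   metadata is preserved.
#' @export
#' @examples
#' sim <- simulate_muscle(n_fascicles = 30, noise_sd = 0, seed = 3)
#' young <- preprocess_fascicles(sim$points)
#' old <- grow_muscle(young, delta_L_MB = 10, delta_W_MB = 3,
#'                    delta_L_F = 2, delta_beta = 1.5)
#' attr(old, "growth")$f_c
grow_muscle <- function(points, delta_L_MB = 0, delta_W_MB = 0, delta_L_F = 0,
                        delta_beta = 0, landmarks = muscle_landmarks(points),
                        ctx = NULL) {
  params <- c(delta_L_MB = delta_L_MB, delta_W_MB = delta_W_MB,
              delta_L_F = delta_L_F, delta_beta = delta_beta)
  if (any(!is.finite(params))) abort("growth parameters must be finite")
  if (all(params == 0)) return(points)
  if (is.null(ctx)) ctx <- growth_context(points, landmarks = landmarks)
  L <- ctx$belly_length_mm; W <- ctx$belly_width_mm
  if (L + delta_L_MB <= 0) {
    abort(sprintf("delta_L_MB = %g would make the belly length non-positive", delta_L_MB))
  }
  if (W + delta_W_MB <= 0) {
    abort(sprintf("delta_W_MB = %g would make the belly width non-positive", delta_W_MB))
  }
  min_lf <- min(fascicle_lengths(points)$length_mm)
  if (min_lf + delta_L_F <= 0) {
    abort(sprintf("delta_L_F = %g would make a fascicle length non-positive", delta_L_F))
  }

  e1 <- ctx$frame$e1
  eng <- grow_engine(points, ctx, delta_W_MB, delta_L_F, delta_beta)
  extent_after <- function(g) {
    t1 <- eng$run(g)$P %*% e1
    max(t1) - min(t1)
  }
  target <- L + delta_L_MB
  base <- delta_L_MB / L
  lo <- max(-0.9, min(0, 10 * base) - 0.5)
  hi <- max(0, 10 * base) + 0.5
  plo <- extent_after(lo) - target
  phi <- extent_after(hi) - target
  tries <- 0
  while (plo * phi > 0 && tries < 8) {
    if (phi < 0) hi <- hi * 2 else lo <- max(-0.95, lo - (hi - lo))
    plo <- extent_after(lo) - target
    phi <- extent_after(hi) - target
    tries <- tries + 1
  }
  if (plo * phi > 0) abort("cannot reach the target belly length; pathological geometry")
  # Illinois regula falsi: the extent is piecewise linear in g, so this
  # converges in a handful of evaluations to the 1e-9 mm contract.
  g <- NA_real_
  side <- 0L
  for (it in 1:100) {
    g <- (lo * phi - hi * plo) / (phi - plo)
    if (!is.finite(g) || g <= min(lo, hi) || g >= max(lo, hi)) g <- (lo + hi) / 2
    f <- extent_after(g) - target
    if (abs(f) < 1e-11 || abs(hi - lo) < 1e-15) break
    if (f * plo < 0) {
      hi <- g; phi <- f
      if (side == -1L) plo <- plo / 2
      side <- -1L
    } else {
      lo <- g; plo <- f
      if (side == 1L) phi <- phi / 2
      side <- 1L
    }
  }
  res <- eng$run(g)
  out <- eng$to_tbl(res)
  attr(out, "landmarks") <- NULL
  attr(out, "growth") <- list(
    params = params,
    scaling_rate = g,
    f_c = if (delta_L_MB != 0) g * L / delta_L_MB else NA_real_,
    input_belly_length_mm = L,
    achieved_belly_length_mm = {
      t1 <- res$P %*% e1
      max(t1) - min(t1)
    },
    clamped = res$clamped,
    skipped = res$skipped
  )
  out
}

# Matrix-level engine for the composed growth transformation. Width scaling is
# applied once up front (its displacement amounts depend only on the context
# midpoints and commute with the e1 shift); per candidate scaling rate g, the
# length shift, fascicle lengthening and rotation are applied on a flat
# coordinate matrix. Numerically equivalent to composing scale_length /
# scale_width / lengthen_fascicles / rotate_fascicles.
grow_engine <- function(points, ctx, delta_W_MB, delta_L_F, delta_beta) {
  mats <- fascicle_split(points)
  ids <- names(mats)
  nf <- length(mats)
  nrows <- vapply(mats, nrow, integer(1))
  idx <- split(seq_len(sum(nrows)), rep(seq_len(nf), nrows))
  P0 <- do.call(rbind, mats)
  e1 <- ctx$frame$e1; e2 <- ctx$frame$e2
  loa <- ctx$line_of_action

  # width displacement per fascicle (zero when delta_W_MB == 0)
  wdisp <- matrix(0, nf, 3)
  if (delta_W_MB != 0) {
    W <- ctx$belly_width_mm
    if (W <= 0) abort("belly width must be positive")
    ss <- ctx$side_split
    d3 <- as.vector(sweep(ctx$midpoints, 2, ss$point) %*% ss$normal)
    for (k in seq_len(nf)) {
      y_dir <- if (d3[k] >= 0) ss$y_plus else ss$y_minus
      denom <- sum(y_dir * ss$normal)
      y_F <- if (abs(denom) > 1e-9) d3[k] / denom else abs(d3[k])
      wdisp[k, ] <- abs(y_F) * (delta_W_MB / W) * y_dir
    }
  }
  Pw <- P0 + wdisp[rep(seq_len(nf), nrows), , drop = FALSE]
  xF_pt <- ctx$x_F[rep(seq_len(nf), nrows)]

  run <- function(g) {
    P <- Pw + outer(xF_pt * g, e1)
    clamped <- character(0); skipped <- character(0)
    for (k in seq_len(nf)) {
      rows <- idx[[k]]
      m <- P[rows, , drop = FALSE]
      if (delta_L_F != 0) {
        p1 <- m[1, ]; p2 <- m[nrow(m), ]
        pd <- function(p) {
          v <- p - loa$point
          sqrt(max(sum(v^2) - sum(v * loa$dir)^2, 0))
        }
        d1 <- pd(p1); d2 <- pd(p2)
        frac <- if (d1 + d2 < 1e-12) 0.5 else d1 / (d1 + d2)
        chord <- p2 - p1
        u_hat <- chord / sqrt(sum(chord^2))
        anchor <- p1 + frac * chord
        rel <- sweep(m, 2, anchor)
        a <- as.vector(rel %*% u_hat)
        perp <- rel - outer(a, u_hat)
        da <- diff(a)
        dp2 <- rowSums((perp[-1, , drop = FALSE] -
                          perp[-nrow(perp), , drop = FALSE])^2)
        L <- sum(sqrt(da^2 + dp2))
        target <- L + delta_L_F
        if (target <= 0) abort("delta_L_F would make a fascicle length non-positive")
        # Newton on the closed-form arc length of the stretched polyline
        kk <- max(target / max(L, 1e-12), 1e-6)
        for (it in 1:50) {
          r <- sqrt((kk * da)^2 + dp2)
          f <- sum(r) - target
          if (abs(f) < 1e-12) break
          dr <- sum(kk * da^2 / pmax(r, 1e-300))
          kk_new <- kk - f / max(dr, 1e-300)
          kk <- if (is.finite(kk_new) && kk_new > 0) kk_new else kk / 2
        }
        m <- sweep(outer(kk * a, u_hat) + perp, 2, anchor, `+`)
      }
      if (delta_beta != 0) {
        chord <- m[nrow(m), ] - m[1, ]
        c2 <- sum(chord * e2)
        proj <- chord - c2 * e2
        np <- sqrt(sum(proj^2))
        if (np < 1e-12 * sqrt(sum(chord^2))) {
          skipped <- c(skipped, ids[k])
        } else {
          cp <- proj / np
          s <- if (c2 >= 0) 1 else -1
          z <- s * e2
          beta <- rad2deg(atan2(abs(c2), np))
          db <- delta_beta
          if (beta + db > 90) { db <- 90 - beta; clamped <- c(clamped, ids[k]) }
          if (beta + db < 0) { db <- -beta; clamped <- c(clamped, ids[k]) }
          th <- deg2rad(db)
          R <- diag(3) +
            sin(th) * (outer(z, cp) - outer(cp, z)) +
            (cos(th) - 1) * (outer(cp, cp) + outer(z, z))
          mid <- polyline_midpoint(m)
          m <- sweep(sweep(m, 2, mid) %*% t(R), 2, mid, `+`)
        }
      }
      P[rows, ] <- m
    }
    list(P = P, clamped = clamped, skipped = skipped)
  }

  to_tbl <- function(res) {
    out <- lapply(seq_len(nf), function(k) res$P[idx[[k]], , drop = FALSE])
    names(out) <- ids
    tb <- fascicles_to_tbl(out, template = points)
    if (length(res$skipped) > 0) {
      warn(sprintf("skipped %d fascicle(s) at beta = 90 deg", length(res$skipped)))
    }
    if (length(res$clamped) > 0) {
      warn(sprintf("pennation clamped to [0, 90] deg for %d fascicle(s)",
                   length(res$clamped)))
    }
    tb
  }

  list(run = run, to_tbl = to_tbl)
}
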