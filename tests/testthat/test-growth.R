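test_that("correction factor f_c solves the belly-extent contract", {
  pts <- fc_phantom()  # blocks [0,10] and [40,50], midpoints 5 and 45
  ctx <- growth_context(pts)
  expect_equal(ctx$belly_length_mm, 50, tolerance = 1e-9)
  # closed-form two-block algebra: extent = 50 + 8 f, target 60 -> f = 1.25
  fc <- determine_fc(pts, 10, ctx = ctx)
  expect_equal(fc, 1.25, tolerance = 1e-7)
  expect_equal(determine_fc(pts, 0, ctx = ctx), 1)
  # shifted dataset reaches the target extent to 1e-9 mm
  out <- scale_length(pts, 10, ctx = ctx, f_c = fc)
  t1 <- as.matrix(out[, 3:5]) %*% ctx$frame$e1
  expect_equal(max(t1) - min(t1), 60, tolerance = 1e-9)
  # hand-computed shifts: +1.25 mm (x_F = 5) and +11.25 mm (x_F = 45)
  dx <- as.matrix(out[, 3:5]) - as.matrix(pts[, 3:5])
  shift <- tapply(dx[, 1], pts$fascicle_id, function(v) unique(round(v, 9)))
  expect_setequal(unlist(shift), c(1.25, 11.25))
})

test_that("f_c is 1 when midpoints already span the full belly", {
  # vertical chords: each fascicle has zero extent along e1
  pts <- dplyr::bind_rows(
    straight_fascicle("a", c(0, -1, 0), c(0, -1, 5)),
    straight_fascicle("b", c(0, 1, 5), c(0, 1, 0)),
    straight_fascicle("c", c(50, -1, 0), c(50, -1, 5)),
    straight_fascicle("d", c(50, 1, 5), c(50, 1, 0))
  )
  ctx <- growth_context(pts)
  expect_equal(determine_fc(pts, 7, ctx = ctx), 1, tolerance = 1e-7)
})

test_that("f_c agrees with a brute-force grid scan on a random muscle", {
  sim <- simulate_muscle(n_fascicles = 25, noise_sd = 0, seed = 14)
  pts <- preprocess_fascicles(sim$points)
  ctx <- growth_context(pts)
  fc <- determine_fc(pts, 12, ctx = ctx)
  mats <- pennate:::fascicle_split(pts)
  grid <- seq(1, 2, by = 1e-3)
  target <- ctx$belly_length_mm + 12
  err <- vapply(grid, function(f) {
    abs(pennate:::shifted_extent(mats, ctx, (12 / ctx$belly_length_mm) * f) - target)
  }, numeric(1))
  expect_lt(abs(fc - grid[which.min(err)]), 1e-3)
  expect_lt(min(err[which.min(abs(grid - fc))]), 1e-2)
})

test_that("length and width scaling are fascicle-wise isometries", {
  sim <- simulate_muscle(n_fascicles = 20, noise_sd = 0, seed = 15)
  pts <- preprocess_fascicles(sim$points)
  ctx <- growth_context(pts)
  L0 <- fascicle_lengths(pts)$length_mm
  s1 <- scale_length(pts, 8, ctx = ctx)
  expect_equal(fascicle_lengths(s1)$length_mm, L0, tolerance = 1e-12)
  s2 <- scale_width(pts, 3, ctx = ctx)
  expect_equal(fascicle_lengths(s2)$length_mm, L0, tolerance = 1e-12)
  # width scaling leaves the belly length unchanged
  t1a <- as.matrix(pts[, 3:5]) %*% ctx$frame$e1
  t1b <- as.matrix(s2[, 3:5]) %*% ctx$frame$e1
  expect_equal(max(t1b) - min(t1b), max(t1a) - min(t1a), tolerance = 1e-9)
  # identity at zero
  expect_identical(scale_length(pts, 0, ctx = ctx), pts)
  expect_identical(scale_width(pts, 0, ctx = ctx), pts)
})

test_that("length scaling preserves the muscle height", {
  sim <- simulate_muscle(n_fascicles = 20, noise_sd = 0, seed = 16)
  pts <- preprocess_fascicles(sim$points)
  ctx <- growth_context(pts)
  h0 <- muscle_height(pts, ctx$frame)
  grown <- grow_muscle(pts, delta_L_MB = 15, ctx = ctx)
  expect_equal(muscle_height(grown, ctx$frame), h0, tolerance = 1e-9)
})

test_that("side split recovers planar and crested transversal directions", {
  # planar: y- = -e3, y+ = +e3
  pts <- plane_phantom(n_len = 8, n_wid = 6)
  fr <- compute_frame(pts)
  ss <- build_side_split(pts, fr)
  expect_lt(axis_angle_deg(ss$y_plus, fr$e3), 1e-4)
  expect_lt(axis_angle_deg(ss$y_minus, fr$e3), 1e-4)
  expect_gt(sum(ss$y_plus * fr$e3), 0)
  expect_lt(sum(ss$y_minus * fr$e3), 0)
  expect_lt(abs(sum(ss$y_plus * fr$e1)), 1e-12)
  # crested (20 degree tent on the upper sheet): y+/- tilt by ~20 degrees
  sim <- simulate_muscle(n_fascicles = 80, noise_sd = 0, crest_angle = 20,
                         seed = 17)
  cp <- preprocess_fascicles(sim$points)
  frc <- compute_frame(cp)
  # side split must use the crested sheet; pick membership accordingly
  ssc <- build_side_split(cp, frc)
  expect_equal(axis_angle_deg(ssc$y_plus, frc$e3), 20, tolerance = 0.5)
  expect_equal(axis_angle_deg(ssc$y_minus, frc$e3), 20, tolerance = 0.5)
  # all midpoints on the dividing plane: both sides degenerate, fall back to e3
  flatids <- c("a", "b", "c", "d")
  flat <- dplyr::bind_rows(
    straight_fascicle("a", c(0, 0, 0), c(10, 0, 5)),
    straight_fascicle("b", c(15, 0, 0), c(25, 0, 5)),
    straight_fascicle("c", c(30, 0, 0), c(40, 0, 5)),
    straight_fascicle("d", c(45, 0, 0), c(55, 0, 5))
  )
  frf <- muscle_frame(c(1, 0, 0), c(0, 1, 0),
                      membership = pennate:::end2_membership(flatids))
  expect_warning(ssf <- build_side_split(flat, frf), "fewer than 3|< 3")
  expect_equal(abs(sum(ssf$y_plus * frf$e3)), 1, tolerance = 1e-12)
})

test_that("width scaling displaces midpoints by y_F * dW / W along the side direction", {
  pts <- plane_phantom(n_len = 6, n_wid = 5, width_y = 10)
  ctx <- growth_context(pts)
  W <- ctx$belly_width_mm
  mids0 <- ctx$midpoints
  d0 <- as.vector(sweep(mids0, 2, ctx$side_split$point) %*% ctx$frame$e3)
  out <- scale_width(pts, W, ctx = ctx)  # delta_W = W: distances double
  mids1 <- t(vapply(pennate:::fascicle_split(out), pennate:::polyline_midpoint,
                    numeric(3)))
  d1 <- as.vector(sweep(mids1, 2, ctx$side_split$point) %*% ctx$frame$e3)
  expect_equal(d1, 2 * d0, tolerance = 1e-9)
  # per-fascicle displacement magnitude equals |y_F| * dW / W
  disp <- sqrt(rowSums((mids1 - mids0)^2))
  expect_equal(unname(disp), abs(d0), tolerance = 1e-9)
  # the worked 4 mm / 10 mm / 5 mm case
  k <- which.min(abs(abs(d0) - 4))
  out2 <- scale_width(pts, 5, ctx = ctx)
  mids2 <- t(vapply(pennate:::fascicle_split(out2), pennate:::polyline_midpoint,
                    numeric(3)))
  expect_equal(sqrt(sum((mids2[k, ] - mids0[k, ])^2)),
               abs(d0[k]) * 5 / W, tolerance = 1e-9)
})

test_that("fascicle lengthening honors the line-of-action displacement ratio", {
  # straight fascicle, d1 = 2, d2 = 6, delta = 4 -> |u1| = 1, |u2| = 3
  ctx <- list(line_of_action = list(point = c(0, 0, 0), dir = c(1, 0, 0)))
  f <- straight_fascicle("f", c(0, 2, 0), c(8, 6, 0))
  out <- lengthen_fascicles(f, 4, ctx = ctx)
  u1 <- sqrt(sum((as.numeric(out[1, 3:5]) - c(0, 2, 0))^2))
  u2 <- sqrt(sum((as.numeric(out[20, 3:5]) - c(8, 6, 0))^2))
  expect_equal(u1, 1, tolerance = 1e-9)
  expect_equal(u2, 3, tolerance = 1e-9)
  expect_equal(u2 / u1, 6 / 2, tolerance = 1e-9)
  expect_equal(fascicle_lengths(out)$length_mm,
               fascicle_lengths(f)$length_mm + 4, tolerance = 1e-9)
  # symmetric distances: each endpoint moves delta/2
  fs <- straight_fascicle("s", c(0, 3, 0), c(10, 3, 0))
  ctx2 <- list(line_of_action = list(point = c(0, 0, 0), dir = c(1, 0, 0)))
  outs <- lengthen_fascicles(fs, 2, ctx = ctx2)
  expect_equal(as.numeric(outs[1, 3:5]), c(-1, 3, 0), tolerance = 1e-9)
  expect_equal(as.numeric(outs[20, 3:5]), c(11, 3, 0), tolerance = 1e-9)
})

test_that("lengthening a curved fascicle hits the target arc length and reduces curvature", {
  t <- seq(0, 1, length.out = 20)
  f <- tibble::tibble(fascicle_id = "c", point_index = 1:20,
                      x_mm = 12 * t, y_mm = 3, z_mm = 2 + 1.5 * 4 * t * (1 - t))
  ctx <- list(line_of_action = list(point = c(0, 3, 0), dir = c(1, 0, 0)))
  L0 <- fascicle_lengths(f)$length_mm
  out <- lengthen_fascicles(f, 3, ctx = ctx)
  expect_equal(fascicle_lengths(out)$length_mm, L0 + 3, tolerance = 1e-6)
  curv <- function(p) {
    m <- as.matrix(p[, 3:5])
    chord <- m[20, ] - m[1, ]
    u <- chord / sqrt(sum(chord^2))
    rel <- sweep(m, 2, m[1, ])
    perp <- rel - outer(as.vector(rel %*% u), u)
    max(sqrt(rowSums(perp^2))) / sqrt(sum(chord^2))
  }
  expect_lte(curv(out), curv(f))
  # endpoint ratio still equals d2/d1 for the curved case (chord-direction stretch)
  m0 <- as.matrix(f[, 3:5]); m1 <- as.matrix(out[, 3:5])
  d <- function(p) sqrt(sum((p - c(0, 3, 0))^2) - (p[1] - 0)^2)
  r_target <- d(m0[20, ]) / d(m0[1, ])
  u1 <- sqrt(sum((m1[1, ] - m0[1, ])^2)); u2 <- sqrt(sum((m1[20, ] - m0[20, ])^2))
  expect_equal(u2 / u1, unname(r_target), tolerance = 1e-9)
})

test_that("rotation shifts pennation by exactly delta_beta and changes nothing else", {
  fr <- muscle_frame(c(1, 0, 0), c(0, 1, 0))
  ctx <- list(frame = fr)
  b0 <- 10
  f <- straight_fascicle("r", c(0, 0, 0),
                         14 * c(cos(b0 * pi / 180), 0, sin(b0 * pi / 180)))
  out <- rotate_fascicles(f, 5, ctx = ctx)
  a1 <- fascicle_angles(out, fr)
  expect_equal(a1$beta_deg, 15, tolerance = 1e-9)
  expect_equal(a1$alpha_deg, 0, tolerance = 1e-9)
  expect_equal(fascicle_lengths(out)$length_mm,
               fascicle_lengths(f)$length_mm, tolerance = 1e-12)
  mid0 <- pennate:::polyline_midpoint(as.matrix(f[, 3:5]))
  mid1 <- pennate:::polyline_midpoint(as.matrix(out[, 3:5]))
  expect_equal(mid1, mid0, tolerance = 1e-12)
  # negative rotation, oblique fascicle: alpha invariant as well
  g <- straight_fascicle("g", c(0, 0, 0), c(10, 4, 3))
  a0 <- fascicle_angles(g, fr)
  outg <- rotate_fascicles(g, -2, ctx = ctx)
  ag <- fascicle_angles(outg, fr)
  expect_equal(ag$beta_deg, a0$beta_deg - 2, tolerance = 1e-9)
  expect_equal(ag$alpha_deg, a0$alpha_deg, tolerance = 1e-9)
  # clamping above 90 degrees warns
  h <- straight_fascicle("h", c(0, 0, 0), c(1, 0, 10))
  expect_warning(outh <- rotate_fascicles(h, 20, ctx = ctx), "clamped")
  expect_equal(fascicle_angles(outh, fr)$beta_deg, 90, tolerance = 1e-9)
  expect_identical(rotate_fascicles(f, 0, ctx = ctx), f)
})

test_that("grow with zero parameters is the exact identity", {
  sim <- simulate_muscle(n_fascicles = 15, seed = 18)
  pts <- preprocess_fascicles(sim$points)
  out <- grow_muscle(pts)
  expect_identical(out, pts)
})

test_that("grow composes the four operations and recovers its own parameters", {
  sim <- simulate_muscle(n_fascicles = 40, noise_sd = 0, seed = 19)
  pts <- preprocess_fascicles(sim$points)
  ctx <- growth_context(pts)
  g0 <- glance(measure_architecture(pts, compute_volume = FALSE,
                                    frame = sim$frame))
  grown <- grow_muscle(pts, delta_L_MB = 18, delta_W_MB = 4, delta_L_F = 3.5,
                       delta_beta = 1.8, ctx = ctx)
  info <- attr(grown, "growth")
  # the f_c contract on the full composition, measured in the model frame
  t1 <- as.matrix(grown[, 3:5]) %*% ctx$frame$e1
  expect_equal(max(t1) - min(t1), ctx$belly_length_mm + 18, tolerance = 1e-9)
  expect_gt(info$f_c, 1)
  g1 <- glance(measure_architecture(grown, compute_volume = FALSE,
                                    frame = sim$frame))
  expect_equal(g1$belly_length_mm - g0$belly_length_mm, 18,
               tolerance = 0.005 * g0$belly_length_mm)
  expect_equal(g1$belly_width_mm - g0$belly_width_mm, 4,
               tolerance = 0.005 * g0$belly_width_mm)
  expect_equal(g1$fascicle_length_mean_mm - g0$fascicle_length_mean_mm, 3.5,
               tolerance = 1e-6)
  expect_equal(g1$pennation_mean_deg - g0$pennation_mean_deg, 1.8,
               tolerance = 0.2)
  # parameter combinations producing degenerate muscles are rejected up front
  expect_error(grow_muscle(pts, delta_L_MB = -100), "delta_L_MB")
  expect_error(grow_muscle(pts, delta_W_MB = -100), "delta_W_MB")
  expect_error(grow_muscle(pts, delta_L_F = -100), "delta_L_F")
})

test_that("operation order matters and the canonical order is fixed", {
  # line of action off the muscle's symmetry axis: endpoint distances d1, d2
  # then differ, so the lengthening anchor depends on the rotation state and
  # swapping lengthening with rotation changes the result
  pts <- plane_phantom(n_len = 6, n_wid = 4, height = 5)
  lm <- tibble::tibble(name = c("origin", "insertion"),
                       x_mm = c(-5, 70), y_mm = c(5, 5), z_mm = c(0, 0))
  pts <- pennate:::set_muscle_attrs(pts, landmarks = lm)
  ctx <- growth_context(pts)
  ab <- rotate_fascicles(lengthen_fascicles(pts, 2, ctx = ctx), 2, ctx = ctx)
  ba <- lengthen_fascicles(rotate_fascicles(pts, 2, ctx = ctx), 2, ctx = ctx)
  expect_gt(max(abs(as.matrix(ab[, 3:5]) - as.matrix(ba[, 3:5]))), 1e-6)
})
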