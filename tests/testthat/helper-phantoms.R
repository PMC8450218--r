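# Phantom builders and rigid-motion helpers used across the suite.

# Straight 3D polyline between two points as a fascicle point block.
straight_fascicle <- function(id, p1, p2, n = 20) {
  t <- seq(0, 1, length.out = n)
  tibble::tibble(
    fascicle_id = id,
    point_index = seq_len(n),
    x_mm = p1[1] + t * (p2[1] - p1[1]),
    y_mm = p1[2] + t * (p2[2] - p1[2]),
    z_mm = p1[3] + t * (p2[3] - p1[3])
  )
}

# Parallel-plane phantom: fascicles from z = 0 to z = height on an x-y grid,
# tilted along +x by the pennation angle. Endpoint 1 on the lower sheet.
plane_phantom <- function(n_len = 6, n_wid = 4, length_x = 50, width_y = 10,
                          height = 5, pennation_deg = 15, n = 20) {
  dx <- height / tan(pennation_deg * pi / 180)
  gx <- seq(0, length_x - dx, length.out = n_len)
  gy <- seq(0, width_y, length.out = n_wid)
  grid <- expand.grid(x = gx, y = gy)
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    straight_fascicle(sprintf("p%03d", i),
                      c(grid$x[i], grid$y[i], 0),
                      c(grid$x[i] + dx, grid$y[i], height), n = n)
  }))
}

# Symmetric two-block phantom for the f_c algebra: fascicles spanning
# x in [0,10] and x in [40,50] (midpoints 5 and 45), mirrored in y and in the
# vertical direction so the PCA frame is exactly axis-aligned.
fc_phantom <- function() {
  blocks <- list(c(0, 10), c(40, 50))
  out <- list()
  i <- 0
  for (b in blocks) for (y in c(-1.5, 1.5)) for (up in c(TRUE, FALSE)) {
    i <- i + 1
    z <- if (up) c(0, 2) else c(2, 0)
    out[[i]] <- straight_fascicle(sprintf("f%02d", i),
                                  c(b[1], y, z[1]), c(b[2], y, z[2]))
  }
  dplyr::bind_rows(out)
}

rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rigid_transform <- function(points, R = diag(3), t = c(0, 0, 0)) {
  m <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")]) %*% t(R)
  points$x_mm <- m[, 1] + t[1]
  points$y_mm <- m[, 2] + t[2]
  points$z_mm <- m[, 3] + t[3]
  lm <- attr(points, "landmarks")
  if (!is.null(lm)) {
    lmm <- as.matrix(lm[, c("x_mm", "y_mm", "z_mm")]) %*% t(R)
    lm$x_mm <- lmm[, 1] + t[1]; lm$y_mm <- lmm[, 2] + t[2]
    lm$z_mm <- lmm[, 3] + t[3]
    attr(points, "landmarks") <- lm
  }
  points
}

# absolute angle between two unit vectors ignoring sign, in degrees
axis_angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
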