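# Muscle coordinate frame from fascicle endpoints.
#
# e1 = aponeurosis length direction, e3 = width direction (together the
# aponeurosis plane), e2 = plane normal; derived by PCA: a provisional PCA of
# all endpoints assigns each fascicle endpoint to the upper (A) or lower (B)
# aponeurosis, then per-aponeurosis PCAs are averaged. One refinement pass
# re-assigns the endpoints with the updated normal.

pca_axes <- function(m) {
  ctr <- colMeans(m)
  cm <- crossprod(sweep(m, 2, ctr)) / max(nrow(m) - 1, 1)
  e <- eigen(cm, symmetric = TRUE)
  list(center = ctr, vectors = e$vectors, values = e$values)
}

# Align sign of vector v to reference r (flip if pointing away).
align_sign <- function(v, r) if (sum(v * r) < 0) -v else v

#' Compute the muscle coordinate frame
#'
#' Principal-component analysis of the fascicle endpoints yields an orthonormal
#' right-handed triad: `e1` along the aponeurosis length, `e3` along its width,
#' `e2` normal to the aponeurosis plane. Each fascicle gets exactly one endpoint
#' on aponeurosis A (larger `e2` coordinate) and one on B. When muscle-tendon
#' landmarks are present `e1` is oriented proximal-to-distal; otherwise its sign
#' is fixed by making the endpoint distribution's skewness along `e1`
#' non-negative. `e2` points from aponeurosis B to A.
#'
#' @param points Preprocessed fascicle point tibble (>= 2 fascicles).
#' @param landmarks Optional landmarks tibble; defaults to the `landmarks`
#'   attribute of `points`.
#' @return An object of class `muscle_frame`: unit axes `e1`, `e2`, `e3`,
#'   `origin` (centroid of endpoints), and a `membership` tibble
#'   (`fascicle_id`, `end`, `aponeurosis`).
#' @export
compute_frame <- function(points, landmarks = muscle_landmarks(points)) {
  ep <- fascicle_endpoints(points)
  if (length(unique(ep$fascicle_id)) < 2) {
    abort("frame computation needs at least 2 fascicles")
  }
  m <- as.matrix(ep[, c("x_mm", "y_mm", "z_mm")])
  pca0 <- pca_axes(m)
  if (pca0$values[2] < 1e-12 * max(pca0$values[1], 1)) {
    abort("degenerate endpoint cloud (rank < 2); cannot define a frame")
  }
  normal <- pca0$vectors[, 3]

  ids <- unique(ep$fascicle_id)
  p1 <- m[ep$end == 1L, , drop = FALSE]
  p2 <- m[ep$end == 2L, , drop = FALSE]

  assign_ab <- function(nrm) {
    s1 <- as.vector(p1 %*% nrm)
    s2 <- as.vector(p2 %*% nrm)
    ifelse(s1 >= s2, 1L, 2L)  # which end lies on the high-normal side
  }
  axes_from <- function(a_end) {
    a_pts <- rbind(p1[a_end == 1L, , drop = FALSE], p2[a_end == 2L, , drop = FALSE])
    b_pts <- rbind(p1[a_end == 2L, , drop = FALSE], p2[a_end == 1L, , drop = FALSE])
    if (nrow(a_pts) < 2 || nrow(b_pts) < 2) {
      abort("an aponeurosis received fewer than 2 endpoints; cannot define a frame")
    }
    pa <- pca_axes(a_pts)
    pb <- pca_axes(b_pts)
    v1 <- unitize(pa$vectors[, 1] + align_sign(pb$vectors[, 1], pa$vectors[, 1]))
    v2a <- pa$vectors[, 2]
    v2 <- v2a + align_sign(pb$vectors[, 2], v2a)
    v2 <- v2 - sum(v2 * v1) * v1
    if (sqrt(sum(v2^2)) < 1e-12) {
      abort("aponeurosis endpoint sets are degenerate along the width direction")
    }
    e1 <- v1
    e3 <- unitize(v2)
    e2 <- cross3(e3, e1)  # right-handed: det[e1 e2 e3] = +1
    list(e1 = e1, e2 = e2, e3 = e3,
         centroid_a = colMeans(a_pts), centroid_b = colMeans(b_pts))
  }

  a_end <- assign_ab(normal)
  ax <- axes_from(a_end)
  # one refinement pass with the updated normal
  a_end2 <- assign_ab(ax$e2)
  if (!identical(a_end2, a_end)) ax <- axes_from(a_end2)
  a_end <- a_end2

  e1 <- ax$e1; e2 <- ax$e2; e3 <- ax$e3

  # orientation of e1: proximal -> distal (landmarks), else positive skewness.
  flip_e1 <- FALSE
  if (!is.null(landmarks)) {
    o <- landmark_coord(landmarks, "origin")
    i <- landmark_coord(landmarks, "insertion")
    if (!is.null(o) && !is.null(i)) flip_e1 <- sum((i - o) * e1) < 0
  } else {
    t1 <- as.vector(m %*% e1)
    sk <- mean((t1 - mean(t1))^3)
    flip_e1 <- sk < 0
  }
  if (flip_e1) { e1 <- -e1; e3 <- -e3 }  # flip two axes: handedness preserved

  # e2 points from aponeurosis B to A; relabel if needed
  if (sum((ax$centroid_a - ax$centroid_b) * e2) < 0) {
    a_end <- ifelse(a_end == 1L, 2L, 1L)
  }

  membership <- tibble::tibble(
    fascicle_id = rep(ids, each = 2),
    end = rep(c(1L, 2L), length(ids)),
    aponeurosis = as.vector(vapply(seq_along(ids), function(k) {
      if (a_end[k] == 1L) c("A", "B") else c("B", "A")
    }, character(2)))
  )

  structure(
    list(e1 = e1, e2 = e2, e3 = e3,
         origin = colMeans(m), membership = membership),
    class = "muscle_frame"
  )
}

#' @export
print.muscle_frame <- function(x, ...) {
  cat("Muscle coordinate frame\n")
  cat("  e1 (length):", format(x$e1, digits = 4), "\n")
  cat("  e2 (normal):", format(x$e2, digits = 4), "\n")
  cat("  e3 (width): ", format(x$e3, digits = 4), "\n")
  cat("  origin (mm):", format(x$origin, digits = 5), "\n")
  invisible(x)
}

# Coordinates of a point matrix in the frame (origin-relative).
frame_coords <- function(m, frame) {
  sweep(m, 2, frame$origin) %*% cbind(frame$e1, frame$e2, frame$e3)
}

# Endpoint coordinate tables split by aponeurosis membership.
aponeurosis_points <- function(points, frame) {
  ep <- fascicle_endpoints(points)
  key <- paste(ep$fascicle_id, ep$end)
  mkey <- paste(frame$membership$fascicle_id, frame$membership$end)
  apo <- frame$membership$aponeurosis[match(key, mkey)]
  if (any(is.na(apo))) {
    abort("frame membership does not match the supplied points")
  }
  m <- as.matrix(ep[, c("x_mm", "y_mm", "z_mm")])
  list(A = m[apo == "A", , drop = FALSE], B = m[apo == "B", , drop = FALSE])
}

#' Construct a muscle frame manually
#'
#' Builds a `muscle_frame` from user-supplied axes (orthonormalized, completed
#' to a right-handed triad with `e2 = e3 x e1`), e.g. for phantoms with a known
#' frame or datasets too degenerate for PCA.
#'
#' @param e1 Aponeurosis length direction.
#' @param e3 Width direction (orthogonalized against `e1`).
#' @param origin Frame origin (mm).
#' @param membership Optional endpoint membership tibble
#'   (`fascicle_id`, `end`, `aponeurosis`); required by the operations that
#'   split endpoints by aponeurosis.
#' @return A `muscle_frame` object.
#' @export
muscle_frame <- function(e1, e3, origin = c(0, 0, 0), membership = NULL) {
  e1 <- unitize(e1)
  e3 <- e3 - sum(e3 * e1) * e1
  e3 <- unitize(e3)
  structure(
    list(e1 = e1, e2 = cross3(e3, e1), e3 = e3, origin = origin,
         membership = membership),
    class = "muscle_frame"
  )
}

# Endpoint membership table where end 2 (the trace's last point) lies on
# aponeurosis A; convenience for constructed phantoms.
end2_membership <- function(ids) {
  tibble::tibble(
    fascicle_id = rep(ids, each = 2),
    end = rep(c(1L, 2L), length(ids)),
    aponeurosis = rep(c("B", "A"), length(ids))
  )
}
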