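# Internal geometry helpers. Fascicle point tables cross the API as tibbles
# (fascicle_id, point_index, x_mm, y_mm, z_mm); geometry is done on per-fascicle
# coordinate matrices.

POINT_COLS <- c("fascicle_id", "point_index", "x_mm", "y_mm", "z_mm")

check_points_df <- function(points, arg = "points") {
  if (!is.data.frame(points)) {
    abort(sprintf("`%s` must be a data frame of fascicle points.", arg))
  }
  missing <- setdiff(POINT_COLS, names(points))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  arg, paste(missing, collapse = ", ")))
  }
  coords <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    abort(sprintf("`%s` contains non-finite or non-numeric coordinates.", arg))
  }
  invisible(points)
}

# Named list of n_i x 3 coordinate matrices, one per fascicle, ordered by
# point_index within fascicle and by first appearance across fascicles.
fascicle_split <- function(points) {
  check_points_df(points)
  ids <- unique(points$fascicle_id)
  ord <- order(match(points$fascicle_id, ids), points$point_index)
  pts <- points[ord, , drop = FALSE]
  m <- as.matrix(pts[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- NULL
  lapply(split(seq_len(nrow(m)), factor(pts$fascicle_id, levels = ids)),
         function(i) m[i, , drop = FALSE])
}

# Rebuild a points tibble from a named list of coordinate matrices,
# preserving landmarks/metadata attributes of `template` when given.
fascicles_to_tbl <- function(mats, template = NULL) {
  ids <- names(mats)
  n <- vapply(mats, nrow, integer(1))
  out <- tibble::tibble(
    fascicle_id = rep(ids, n),
    point_index = unlist(lapply(n, seq_len), use.names = FALSE),
    x_mm = unlist(lapply(mats, function(m) m[, 1]), use.names = FALSE),
    y_mm = unlist(lapply(mats, function(m) m[, 2]), use.names = FALSE),
    z_mm = unlist(lapply(mats, function(m) m[, 3]), use.names = FALSE)
  )
  if (!is.null(template)) {
    attr(out, "landmarks") <- attr(template, "landmarks")
    attr(out, "metadata") <- attr(template, "metadata")
  }
  out
}

all_coords <- function(points) {
  check_points_df(points)
  unname(as.matrix(points[, c("x_mm", "y_mm", "z_mm")]))
}

polyline_length <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

# Point at arc length L/2, linearly interpolated on the polyline.
polyline_midpoint <- function(m) {
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  half <- s[length(s)] / 2
  i <- findInterval(half, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(m) - 1L)
  t <- if (seg[i] > 0) (half - s[i]) / seg[i] else 0
  m[i, ] + t * (m[i + 1, ] - m[i, ])
}

# First and last point of each fascicle polyline.
fascicle_endpoints <- function(points) {
  mats <- fascicle_split(points)
  ids <- names(mats)
  p1 <- t(vapply(mats, function(m) m[1, ], numeric(3)))
  p2 <- t(vapply(mats, function(m) m[nrow(m), ], numeric(3)))
  tibble::tibble(
    fascicle_id = rep(ids, each = 2),
    end = rep(c(1L, 2L), length(ids)),
    x_mm = as.vector(rbind(p1[, 1], p2[, 1])),
    y_mm = as.vector(rbind(p1[, 2], p2[, 2])),
    z_mm = as.vector(rbind(p1[, 3], p2[, 3]))
  )
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) abort("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Attach/retrieve optional landmarks (tibble name,x_mm,y_mm,z_mm) and metadata.
muscle_landmarks <- function(points) attr(points, "landmarks", exact = TRUE)
muscle_metadata <- function(points) attr(points, "metadata", exact = TRUE)

set_muscle_attrs <- function(points, landmarks = NULL, metadata = NULL) {
  if (!is.null(landmarks)) {
    stopifnot(is.data.frame(landmarks),
              all(c("name", "x_mm", "y_mm", "z_mm") %in% names(landmarks)))
    attr(points, "landmarks") <- tibble::as_tibble(landmarks)
  }
  if (!is.null(metadata)) attr(points, "metadata") <- metadata
  points
}

landmark_coord <- function(landmarks, name) {
  i <- which(landmarks$name == name)
  if (length(i) == 0) return(NULL)
  as.numeric(landmarks[i[1], c("x_mm", "y_mm", "z_mm")])
}
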