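# Architectural parameters: angles, aponeurosis and belly dimensions, height,
# mass, PCSA, free tendon length, and the full summary object.

#' Pennation and transversal angles per fascicle
#'
#' Angles are computed from the fascicle chord (endpoint to endpoint). The
#' pennation angle `beta` is the chord's deviation from the aponeurosis plane
#' (`e1`-`e3`); the transversal angle `alpha` is the deviation of the chord's
#' in-plane projection from the length axis `e1`. Both lie in \[0, 90\] degrees.
#' A chord perpendicular to the aponeurosis plane has `beta = 90` and an
#' undefined `alpha`, reported as 0 with `alpha_defined = FALSE`.
#'
#' @param points Preprocessed fascicle point tibble.
#' @param frame A [compute_frame()] result.
#' @return Tibble with `fascicle_id`, `alpha_deg`, `beta_deg`, `alpha_defined`.
#' @export
fascicle_angles <- function(points, frame) {
  mats <- fascicle_split(points)
  res <- t(vapply(mats, function(m) {
    chord <- m[nrow(m), ] - m[1, ]
    len <- sqrt(sum(chord^2))
    if (len <= 0) abort("fascicle with zero chord length")
    c1 <- sum(chord * frame$e1)
    c2 <- sum(chord * frame$e2)
    c3 <- sum(chord * frame$e3)
    proj <- sqrt(c1^2 + c3^2)
    beta <- rad2deg(atan2(abs(c2), proj))
    if (proj < 1e-12 * len) {
      c(0, 90, 0)
    } else {
      c(rad2deg(atan2(abs(c3), abs(c1))), beta, 1)
    }
  }, numeric(3)))
  tibble::tibble(
    fascicle_id = names(mats),
    alpha_deg = unname(res[, 1]),
    beta_deg = unname(res[, 2]),
    alpha_defined = unname(res[, 3] > 0)
  )
}

#' Aponeurosis length and width
#'
#' For each aponeurosis the length is the largest distance of two of its
#' endpoint projections along `e1`, the width the same along `e3`. The `"mean"`
#' row averages the two aponeuroses (the reporting convention for summary
#' tables).
#'
#' @inheritParams fascicle_angles
#' @return Tibble with rows `A`, `B`, `mean` and columns `length_mm`,
#'   `width_mm`.
#' @export
aponeurosis_dims <- function(points, frame) {
  ap <- aponeurosis_points(points, frame)
  dims <- lapply(ap, function(m) {
    if (nrow(m) < 2) {
      warn("aponeurosis with fewer than 2 endpoints; dimensions set to 0")
      return(c(length_mm = 0, width_mm = 0))
    }
    t1 <- m %*% frame$e1
    t3 <- m %*% frame$e3
    c(length_mm = max(t1) - min(t1), width_mm = max(t3) - min(t3))
  })
  tibble::tibble(
    aponeurosis = c("A", "B", "mean"),
    length_mm = unname(c(dims$A[1], dims$B[1], (dims$A[1] + dims$B[1]) / 2)),
    width_mm = unname(c(dims$A[2], dims$B[2], (dims$A[2] + dims$B[2]) / 2))
  )
}

#' Muscle height
#'
#' Distance of the two aponeurosis centroids along the plane normal `e2`.
#'
#' @inheritParams fascicle_angles
#' @return Height in mm.
#' @export
muscle_height <- function(points, frame) {
  ap <- aponeurosis_points(points, frame)
  if (nrow(ap$A) == 0 || nrow(ap$B) == 0) abort("empty aponeurosis")
  abs(sum((colMeans(ap$A) - colMeans(ap$B)) * frame$e2))
}

#' Muscle belly length and width
#'
#' Belly length `L_MB` is the extent of *all* fascicle points (not only
#' endpoints) along `e1`; belly width `W_MB` is the extent along `e3`.
#'
#' @inheritParams fascicle_angles
#' @return Named numeric vector `c(belly_length_mm, belly_width_mm)`.
#' @export
belly_dims <- function(points, frame) {
  m <- all_coords(points)
  t1 <- m %*% frame$e1
  t3 <- m %*% frame$e3
  c(belly_length_mm = max(t1) - min(t1), belly_width_mm = max(t3) - min(t3))
}

#' Muscle mass and physiological cross-sectional area
#'
#' Mass is volume times the skeletal muscle density (1.056 g/cm^3, i.e.
#' 1.056e-3 g/mm^3); PCSA is volume over mean fascicle length.
#'
#' @param volume_mm3 Muscle volume (mm^3).
#' @param mean_fascicle_mm Mean fascicle length (mm), > 0.
#' @param density_g_mm3 Density in g/mm^3.
#' @return Tibble with `muscle_mass_g` and `pcsa_mm2`.
#' @export
#' @examples
#' mass_and_pcsa(1000, 12.5)  # 1.056 g, 80 mm^2
mass_and_pcsa <- function(volume_mm3, mean_fascicle_mm,
                          density_g_mm3 = MUSCLE_DENSITY_G_MM3) {
  if (volume_mm3 < 0) abort("volume must be non-negative")
  if (volume_mm3 > 0 && mean_fascicle_mm <= 0) {
    abort("mean fascicle length must be positive")
  }
  tibble::tibble(
    muscle_mass_g = volume_mm3 * density_g_mm3,
    pcsa_mm2 = if (volume_mm3 == 0) 0 else volume_mm3 / mean_fascicle_mm
  )
}

#' Free tendon length
#'
#' Muscle-tendon-complex length (Euclidean distance between the origin and
#' insertion landmarks) minus the muscle belly length. A negative value signals
#' an inconsistency between landmarks and fascicle data and is returned with a
#' warning.
#'
#' @param points Fascicle point tibble carrying landmarks, or `NULL`.
#' @param belly_length_mm Muscle belly length (mm).
#' @param landmarks Landmarks tibble; defaults to the attribute of `points`.
#' @return Free tendon length (mm).
#' @export
free_tendon_length <- function(points, belly_length_mm,
                               landmarks = muscle_landmarks(points)) {
  if (is.null(landmarks)) abort("free tendon length needs MTC landmarks")
  o <- landmark_coord(landmarks, "origin")
  i <- landmark_coord(landmarks, "insertion")
  if (is.null(o) || is.null(i)) {
    abort("landmarks must include `origin` and `insertion`")
  }
  mtc <- sqrt(sum((i - o)^2))
  out <- mtc - belly_length_mm
  if (out < 0) {
    warn(sprintf(
      "belly length (%.2f mm) exceeds MTC length (%.2f mm); negative free tendon",
      belly_length_mm, mtc))
  }
  out
}

#' Measure the complete muscle architecture
#'
#' One call from a preprocessed fascicle point table to every standard
#' architectural parameter: belly dimensions, fascicle length and angle
#' statistics (mean and sample standard deviation over fascicles), per- and
#' mean-aponeurosis dimensions, muscle height, boundary volume (alpha complex at
#' the given shrink factor), mass, PCSA, and — when landmarks are present — the
#' free tendon length.
#'
#' @param points Preprocessed fascicle point tibble.
#' @param landmarks Optional landmarks tibble (defaults to the attribute).
#' @param shrink Boundary shrink factor in \[0, 1\] (default 0.6).
#' @param density_g_mm3 Muscle density, g/mm^3.
#' @param compute_volume Set `FALSE` to skip the boundary volume (then volume,
#'   mass and PCSA are `NA`); useful when only frame-based parameters matter.
#' @param frame Optional `muscle_frame` (with endpoint membership) to use
#'   instead of computing one by PCA; allows degenerate datasets (e.g. a single
#'   fascicle) to be summarized against a known frame.
#' @return An object of class `muscle_architecture` with [glance()], [tidy()]
#'   and [autoplot()] methods. Components: `summary` (one-row tibble),
#'   `per_fascicle`, `frame`, `boundary`.
#' @export
#' @examples
#' sim <- simulate_muscle(n_fascicles = 40, noise_sd = 0, seed = 2)
#' arch <- measure_architecture(preprocess_fascicles(sim$points))
#' glance(arch)
measure_architecture <- function(points, landmarks = muscle_landmarks(points),
                                 shrink = 0.6,
                                 density_g_mm3 = MUSCLE_DENSITY_G_MM3,
                                 compute_volume = TRUE, frame = NULL) {
  if (is.null(frame)) frame <- compute_frame(points, landmarks = landmarks)
  lens <- fascicle_lengths(points)
  angles <- fascicle_angles(points, frame)
  per_fascicle <- dplyr::left_join(lens, angles, by = "fascicle_id")
  mem <- frame$membership
  apo_of_end1 <- mem$aponeurosis[mem$end == 1L]
  per_fascicle$aponeurosis_end1 <- apo_of_end1[match(per_fascicle$fascicle_id,
                                                     mem$fascicle_id[mem$end == 1L])]
  dims <- belly_dims(points, frame)
  apod <- aponeurosis_dims(points, frame)
  height <- muscle_height(points, frame)
  boundary <- NULL
  vol <- NA_real_
  if (compute_volume) {
    boundary <- muscle_volume(points, shrink = shrink)
    vol <- boundary$volume_mm3
  }
  mean_lf <- mean(lens$length_mm)
  mp <- if (is.na(vol)) {
    tibble::tibble(muscle_mass_g = NA_real_, pcsa_mm2 = NA_real_)
  } else {
    mass_and_pcsa(vol, mean_lf, density_g_mm3)
  }
  tendon <- NA_real_
  if (!is.null(landmarks)) {
    tendon <- free_tendon_length(points, dims[["belly_length_mm"]],
                                 landmarks = landmarks)
  }
  n_f <- nrow(per_fascicle)
  summary <- tibble::tibble(
    n_fascicles = n_f,
    belly_length_mm = dims[["belly_length_mm"]],
    belly_width_mm = dims[["belly_width_mm"]],
    fascicle_length_mean_mm = mean_lf,
    fascicle_length_sd_mm = if (n_f > 1) sd(lens$length_mm) else 0,
    pennation_mean_deg = mean(angles$beta_deg),
    pennation_sd_deg = if (n_f > 1) sd(angles$beta_deg) else 0,
    transversal_mean_deg = mean(angles$alpha_deg),
    transversal_sd_deg = if (n_f > 1) sd(angles$alpha_deg) else 0,
    aponeurosis_length_a_mm = apod$length_mm[apod$aponeurosis == "A"],
    aponeurosis_length_b_mm = apod$length_mm[apod$aponeurosis == "B"],
    aponeurosis_length_mm = apod$length_mm[apod$aponeurosis == "mean"],
    aponeurosis_width_a_mm = apod$width_mm[apod$aponeurosis == "A"],
    aponeurosis_width_b_mm = apod$width_mm[apod$aponeurosis == "B"],
    aponeurosis_width_mm = apod$width_mm[apod$aponeurosis == "mean"],
    muscle_height_mm = height,
    muscle_volume_mm3 = vol,
    muscle_mass_g = mp$muscle_mass_g,
    pcsa_mm2 = mp$pcsa_mm2,
    free_tendon_mm = tendon
  )
  structure(
    list(summary = summary, per_fascicle = per_fascicle, frame = frame,
         boundary = boundary, shrink = shrink, density_g_mm3 = density_g_mm3),
    class = "muscle_architecture"
  )
}

#' @export
print.muscle_architecture <- function(x, ...) {
  s <- x$summary
  cat("Muscle architecture (", s$n_fascicles, " fascicles)\n", sep = "")
  cat(sprintf("  belly %0.1f x %0.1f mm, height %0.2f mm\n",
              s$belly_length_mm, s$belly_width_mm, s$muscle_height_mm))
  cat(sprintf("  fascicle length %0.1f +/- %0.1f mm, pennation %0.1f +/- %0.1f deg\n",
              s$fascicle_length_mean_mm, s$fascicle_length_sd_mm,
              s$pennation_mean_deg, s$pennation_sd_deg))
  if (!is.na(s$muscle_volume_mm3)) {
    cat(sprintf("  volume %0.0f mm^3, mass %0.2f g, PCSA %0.1f mm^2\n",
                s$muscle_volume_mm3, s$muscle_mass_g, s$pcsa_mm2))
  }
  if (!is.na(s$free_tendon_mm)) {
    cat(sprintf("  free tendon %0.1f mm\n", s$free_tendon_mm))
  }
  invisible(x)
}

#' @rdname measure_architecture
#' @param x A `muscle_architecture` object.
#' @param ... Unused.
#' @method glance muscle_architecture
#' @export
glance.muscle_architecture <- function(x, ...) x$summary

#' @rdname measure_architecture
#' @method tidy muscle_architecture
#' @export
tidy.muscle_architecture <- function(x, ...) {
  s <- x$summary
  unit_of <- function(nm) {
    if (grepl("_mm3$", nm)) "mm^3"
    else if (grepl("_mm2$", nm)) "mm^2"
    else if (grepl("_mm$", nm)) "mm"
    else if (grepl("_deg$", nm)) "deg"
    else if (grepl("_g$", nm)) "g"
    else ""
  }
  nm <- names(s)
  tibble::tibble(
    parameter = sub("_(mm3|mm2|mm|deg|g)$", "", nm),
    value = as.numeric(s[1, ]),
    unit = vapply(nm, unit_of, character(1))
  )
}
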