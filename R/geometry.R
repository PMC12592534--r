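#' Construct an axon profile
#'
#' An `axon_profile` holds a cross-sectional area record `A(l)` sampled on a
#' uniform arc-length grid, the basic object from which all geometric
#' statistics (tortuosity, spectral plateau, volume weights) are computed.
#' All lengths are in micrometers, areas in square micrometers.
#'
#' @param arc_um numeric vector of arc-length positions (um), strictly
#'   increasing with constant spacing.
#' @param area_um2 numeric vector of cross-sectional areas (um^2), all > 0.
#' @param skeleton optional numeric matrix (n x 3) of ordered 3-D skeleton
#'   coordinates (um); used for sinuosity.
#' @param axon_id identifier, coerced to character.
#' @return An object of class `"axon_profile"`: a list with elements
#'   `arc_um`, `area_um2`, `dl`, `skeleton`, `axon_id`.
#' @export
axon_profile <- function(arc_um, area_um2, skeleton = NULL, axon_id = "axon") {
  arc_um <- as.numeric(arc_um)
  area_um2 <- as.numeric(area_um2)
  if (length(arc_um) != length(area_um2))
    stop("arc_um and area_um2 must have equal length")
  if (length(arc_um) < 16L)
    stop("an axon profile needs at least 16 samples")
  d <- diff(arc_um)
  if (any(d <= 0))
    stop("arc_um must be strictly increasing")
  dl <- mean(d)
  if (max(abs(d - dl)) > 1e-9 * dl)
    stop("arc_um must be uniformly spaced (relative tolerance 1e-9); ",
         "use resample_arclength() to re-grid")
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stop("all areas must be finite and strictly positive")
  if (!is.null(skeleton)) {
    skeleton <- as.matrix(skeleton)
    if (ncol(skeleton) != 3L) stop("skeleton must be an n x 3 matrix")
  }
  structure(
    list(arc_um = arc_um, area_um2 = area_um2, dl = dl,
         skeleton = skeleton, axon_id = as.character(axon_id)),
    class = "axon_profile")
}

#' @export
print.axon_profile <- function(x, ...) {
  cat(sprintf("Axon profile '%s': %d samples, dl = %.4g um, L = %.4g um\n",
              x$axon_id, length(x$arc_um), x$dl, profile_length(x)))
  cat(sprintf("  mean area %.4g um^2, range [%.4g, %.4g] um^2\n",
              mean(x$area_um2), min(x$area_um2), max(x$area_um2)))
  if (!is.null(x$skeleton)) cat("  3-D skeleton attached\n")
  invisible(x)
}

#' Arc length of a profile
#' @param profile an `axon_profile`.
#' @return Record length L (um).
#' @export
profile_length <- function(profile) {
  stopifnot(inherits(profile, "axon_profile"))
  profile$arc_um[length(profile$arc_um)] - profile$arc_um[1L]
}

#' Resample a skeleton + area record onto a uniform arc-length grid
#'
#' The arc coordinate is the cumulative chord length of the ordered skeleton
#' points; areas are interpolated by a natural cubic spline of A against arc
#' length and sampled on a uniform grid of spacing `dl` covering `[0, L]`
#' (`floor(L/dl) + 1` samples). Equidistant sampling gives the uniformly
#' spaced Fourier grid the spectral-density estimate relies on.
#'
#' @param skeleton_points numeric matrix (n x 3) of ordered, pairwise
#'   distinct 3-D points (um), n >= 4.
#' @param areas_at_points areas (um^2) at the skeleton points, all > 0.
#' @param dl target spacing (um), default 0.1.
#' @param axon_id identifier.
#' @return An `axon_profile` with the resampled skeleton attached.
#' @export
resample_arclength <- function(skeleton_points, areas_at_points, dl = 0.1,
                               axon_id = "axon") {
  pts <- as.matrix(skeleton_points)
  if (ncol(pts) != 3L) stop("skeleton_points must be an n x 3 matrix")
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 skeleton points")
  areas_at_points <- as.numeric(areas_at_points)
  if (length(areas_at_points) != n)
    stop("areas_at_points must match the number of skeleton points")
  if (any(areas_at_points <= 0)) stop("areas must be strictly positive")
  if (dl <= 0) stop("dl must be positive")
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-n, , drop = FALSE])^2))
  if (any(seg == 0))
    stop("duplicate consecutive skeleton points give a non-monotone ",
         "arc length; remove duplicates")
  arc <- c(0, cumsum(seg))
  L <- arc[n]
  grid <- seq(0, by = dl, length.out = floor(L / dl) + 1L)
  afun <- stats::splinefun(arc, areas_at_points, method = "natural")
  a_new <- afun(grid)
  if (any(a_new <= 0)) {
    bad <- grid[which(a_new <= 0)[1L]]
    stop(sprintf("interpolated area is non-positive near l = %.4g um", bad))
  }
  sk_new <- apply(pts, 2L, function(z)
    stats::splinefun(arc, z, method = "natural")(grid))
  axon_profile(grid, a_new, skeleton = sk_new, axon_id = axon_id)
}

#' Relative cross-section and its logarithm
#'
#' Normalizes a profile to the dimensionless relative area
#' `alpha(l) = A(l) / mean(A)` and its logarithm `eta(l) = log(alpha)`,
#' the two stochastic fields whose statistics determine the diffusive
#' dynamics along the tube.
#'
#' @param profile an `axon_profile`.
#' @return An object of class `"relative_profile"`: list with `alpha`,
#'   `eta`, `mean_area` (um^2), `length` (um), `dl` (um), `axon_id`.
#' @export
relative_profile <- function(profile) {
  stopifnot(inherits(profile, "axon_profile"))
  abar <- mean(profile$area_um2)
  alpha <- profile$area_um2 / abar
  structure(
    list(alpha = alpha, eta = log(alpha), mean_area = abar,
         length = profile_length(profile), dl = profile$dl,
         axon_id = profile$axon_id),
    class = "relative_profile")
}

#' @export
print.relative_profile <- function(x, ...) {
  cat(sprintf(
    "Relative profile '%s': %d samples, var(alpha) = %.4g, <1/alpha> = %.5g\n",
    x$axon_id, length(x$alpha), stats::var(x$alpha), tortuosity(x)))
  invisible(x)
}

#' Geometric tortuosity
#'
#' The average reciprocal relative cross-section `<1/alpha>`, which equals
#' `D0 / Dinf` for Fick-Jacobs diffusion along the tube (series-resistor
#' analogy). Always >= 1, with equality only for a constant cross-section.
#'
#' @param rel a `relative_profile` (or an `axon_profile`, converted first).
#' @return Dimensionless tortuosity factor.
#' @export
tortuosity <- function(rel) {
  if (inherits(rel, "axon_profile")) rel <- relative_profile(rel)
  stopifnot(inherits(rel, "relative_profile"))
  mean(1 / rel$alpha)
}

#' Sinuosity of a skeleton
#'
#' Ratio of arc length (cumulative chord length) to the Euclidean
#' end-to-end distance, xi >= 1. Undulations of the skeleton rescale the
#' along-axon diffusivity by `1/xi^2`.
#'
#' @param skeleton_points numeric matrix (n x 3) of ordered points (um), or
#'   an `axon_profile` with a skeleton attached.
#' @return Dimensionless sinuosity xi.
#' @export
sinuosity <- function(skeleton_points) {
  if (inherits(skeleton_points, "axon_profile")) {
    if (is.null(skeleton_points$skeleton))
      stop("profile has no skeleton attached")
    skeleton_points <- skeleton_points$skeleton
  }
  pts <- as.matrix(skeleton_points)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points")
  ee <- sqrt(sum((pts[n, ] - pts[1L, ])^2))
  if (ee == 0) stop("coincident endpoints: Euclidean length is zero")
  arc <- sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-n, , drop = FALSE])^2)))
  arc / ee
}

#' Minimum-area quality-control check
#'
#' Flags profiles with necks narrower than a threshold area, the analog of
#' excluding axons whose thinnest cross-section falls below a few voxels in
#' segmented volumes. Disabled by default everywhere (the sensible
#' threshold is voxel-size specific); readers expose it via their
#' `min_area_um2` argument.
#'
#' @param profile an `axon_profile`.
#' @param min_area_um2 threshold (um^2).
#' @return `TRUE` if all areas are at or above the threshold.
#' @export
passes_area_qc <- function(profile, min_area_um2) {
  stopifnot(inherits(profile, "axon_profile"))
  min(profile$area_um2) >= min_area_um2
}

#' Coarsen a profile by integer subsampling
#'
#' Keeps every `by`-th sample, giving a lattice of spacing `by * dl`.
#' Useful for cutting the cost of walker simulations when the area varies
#' on scales much longer than the grid spacing (bead widths of several um
#' versus a 0.1 um grid); the subsampled tortuosity is unchanged to high
#' accuracy in that regime.
#'
#' @param profile an `axon_profile`.
#' @param by positive integer stride.
#' @return An `axon_profile` on the coarser grid.
#' @export
thin_profile <- function(profile, by) {
  stopifnot(inherits(profile, "axon_profile"))
  by <- as.integer(by)
  if (by < 1L) stop("by must be a positive integer")
  idx <- seq(1L, length(profile$arc_um), by = by)
  axon_profile(profile$arc_um[idx], profile$area_um2[idx],
               skeleton = if (!is.null(profile$skeleton))
                 profile$skeleton[idx, , drop = FALSE] else NULL,
               axon_id = profile$axon_id)
}

#' Volume weights of a set of profiles
#'
#' Each axon contributes to the ensemble diffusivity in proportion to its
#' water volume, `w_i` proportional to `Abar_i * L_i`, normalized to sum
#' to one.
#'
#' @param profiles list of `axon_profile` objects.
#' @return Numeric vector of weights summing to 1.
#' @export
volume_weights <- function(profiles) {
  if (length(profiles) < 1L) stop("need at least one profile")
  v <- vapply(profiles, function(p) {
    stopifnot(inherits(p, "axon_profile"))
    mean(p$area_um2) * profile_length(p)
  }, numeric(1))
  v / sum(v)
}
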