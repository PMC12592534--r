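#' Read a profile table
#'
#' TSV/CSV with header columns `arc_um`, `area_um2` and optional
#' `x_um,y_um,z_um`; comment lines start with `#`. If the arc grid is
#' already uniform (relative tolerance 1e-9) the samples are used as-is,
#' otherwise the record is re-gridded at `dl` via [resample_arclength()]
#' (when skeleton columns are present) or by natural-spline interpolation
#' of A over arc length.
#'
#' @param path file path.
#' @param dl re-gridding spacing (um) used only when the input grid is
#'   non-uniform; default 0.1.
#' @param axon_id identifier; defaults to the file name.
#' @param min_area_um2 optional quality-control threshold: reject the
#'   profile if any cross-section falls below it (see
#'   [passes_area_qc()]); default `NULL`, disabled.
#' @return An `axon_profile`.
#' @export
read_profile <- function(path, dl = 0.1, axon_id = NULL,
                         min_area_um2 = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", check.names = FALSE)
  need <- c("arc_um", "area_um2")
  if (!all(need %in% names(tab)))
    stop("profile table must have columns 'arc_um' and 'area_um2': ", path)
  if (is.null(axon_id)) axon_id <- sub("\\.[^.]*$", "", basename(path))
  sk <- NULL
  if (all(c("x_um", "y_um", "z_um") %in% names(tab)))
    sk <- as.matrix(tab[, c("x_um", "y_um", "z_um")])
  arc <- tab$arc_um
  d <- diff(arc)
  uniform <- length(d) > 0 && all(d > 0) &&
    max(abs(d - mean(d))) <= 1e-9 * mean(d)
  prof <- if (uniform) {
    axon_profile(arc, tab$area_um2, skeleton = sk, axon_id = axon_id)
  } else if (!is.null(sk)) {
    resample_arclength(sk, tab$area_um2, dl = dl, axon_id = axon_id)
  } else {
    if (any(d <= 0)) stop("arc_um must be strictly increasing: ", path)
    L <- arc[length(arc)] - arc[1L]
    grid <- seq(0, by = dl, length.out = floor(L / dl) + 1L)
    a_new <- stats::splinefun(arc - arc[1L], tab$area_um2,
                              method = "natural")(grid)
    if (any(a_new <= 0))
      stop("interpolated area non-positive while re-gridding: ", path)
    axon_profile(grid, a_new, axon_id = axon_id)
  }
  if (!is.null(min_area_um2) && !passes_area_qc(prof, min_area_um2))
    stop(sprintf("profile fails the minimum-area QC (min %.4g < %.4g um^2): %s",
                 min(prof$area_um2), min_area_um2, path))
  prof
}

#' Write a profile table
#'
#' @param profile an `axon_profile`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "axon_profile"))
  tab <- data.frame(arc_um = profile$arc_um, area_um2 = profile$area_um2)
  if (!is.null(profile$skeleton)) {
    tab$x_um <- profile$skeleton[, 1L]
    tab$y_um <- profile$skeleton[, 2L]
    tab$z_um <- profile$skeleton[, 3L]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axondt profile v1: axon_id=%s dl=%.6g um",
                     profile$axon_id, profile$dl), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an SWC morphology as an axon profile
#'
#' Standard SWC (columns id, type, x, y, z, radius, parent; `#` comments).
#' Only unbranched root-to-tip paths are accepted: any node with more than
#' one child is rejected, mirroring the exclusion of bifurcating axons from
#' morphometric analysis. Cross-sectional areas are `pi * r^2` from the
#' node radii; the path is re-gridded at `dl` via [resample_arclength()].
#'
#' @param path SWC file path.
#' @param dl arc-length spacing (um), default 0.1.
#' @param axon_id identifier; defaults to file name.
#' @param min_area_um2 optional quality-control threshold, as in
#'   [read_profile()]; default `NULL`, disabled.
#' @return An `axon_profile`.
#' @export
read_swc <- function(path, dl = 0.1, axon_id = NULL, min_area_um2 = NULL) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 7L) stop("SWC file must have 7 columns: ", path)
  names(tab)[1:7] <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (is.null(axon_id)) axon_id <- sub("\\.[^.]*$", "", basename(path))
  kids <- table(tab$parent[tab$parent != -1])
  if (any(kids > 1L))
    stop("SWC skeleton bifurcates (node(s) ",
         paste(names(kids)[kids > 1L], collapse = ", "),
         " have multiple children); only unbranched paths are accepted")
  root <- tab$id[tab$parent == -1]
  if (length(root) != 1L) stop("SWC file must have exactly one root")
  # follow the single-child chain from the root
  child_of <- stats::setNames(tab$id, as.character(tab$parent))
  ord <- integer(nrow(tab))
  ord[1L] <- root
  for (i in seq_len(nrow(tab) - 1L)) {
    nxt <- child_of[as.character(ord[i])]
    if (is.na(nxt)) stop("SWC chain broken at node ", ord[i])
    ord[i + 1L] <- nxt
  }
  idx <- match(ord, tab$id)
  pts <- as.matrix(tab[idx, c("x", "y", "z")])
  areas <- pi * tab$radius[idx]^2
  prof <- resample_arclength(pts, areas, dl = dl, axon_id = axon_id)
  if (!is.null(min_area_um2) && !passes_area_qc(prof, min_area_um2))
    stop(sprintf("SWC axon fails the minimum-area QC (min %.4g < %.4g um^2): %s",
                 min(prof$area_um2), min_area_um2, path))
  prof
}

#' Read / write a D(t) curve table
#'
#' TSV with columns `t_ms`, `D_um2_per_ms`, optional `sd`.
#'
#' @param path file path.
#' @return A `dt_curve`.
#' @export
read_dt_curve <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  if (!all(c("t_ms", "D_um2_per_ms") %in% names(tab)))
    stop("curve table must have columns 't_ms' and 'D_um2_per_ms': ", path)
  dt_curve(tab$t_ms, tab$D_um2_per_ms,
           sd = if ("sd" %in% names(tab)) tab$sd else NULL)
}

#' @rdname read_dt_curve
#' @param curve a `dt_curve`.
#' @export
write_dt_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dt_curve"))
  tab <- data.frame(t_ms = curve$t_ms, D_um2_per_ms = curve$D_um2_per_ms)
  if (!is.null(curve$sd)) tab$sd <- curve$sd
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axondt D(t) curve v1: kind=%s", curve$kind), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spectral density table
#'
#' TSV with columns `q_rad_per_um`, `gamma_eta_um`.
#' @param spec a `spectral_density`.
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectral_density"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axondt spectrum v1: L=%.6g um dl=%.6g um",
                     spec$record_length, spec$dl), con)
  utils::write.table(
    data.frame(q_rad_per_um = spec$q, gamma_eta_um = spec$gamma),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
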