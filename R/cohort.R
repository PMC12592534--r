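#' Volume-weighted ensemble D(t) curve
#'
#' Pointwise weighted mean of per-axon D(t) curves,
#' `D(t) = sum_i w_i D_i(t)`, with the weighted standard deviation
#' reported as the per-point uncertainty. All curves must share a common
#' time grid unless `interpolate = TRUE`, in which case each curve is
#' linearly interpolated onto the first curve's grid (restricted to the
#' overlap).
#'
#' @param curves list of `dt_curve`s of a common kind.
#' @param weights nonnegative weights; normalized to sum to 1.
#' @param interpolate allow linear re-gridding onto the first curve's
#'   grid.
#' @return A `dt_curve` with `sd` set to the weighted standard deviation.
#' @export
ensemble_curve <- function(curves, weights, interpolate = FALSE) {
  if (length(curves) < 1L) stop("need at least one curve")
  lapply(curves, function(cu) stopifnot(inherits(cu, "dt_curve")))
  if (length(weights) != length(curves))
    stop("one weight per curve required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  w <- weights / sum(weights)
  kinds <- unique(vapply(curves, `[[`, character(1), "kind"))
  if (length(kinds) > 1L) stop("curves mix cumulative and instantaneous kinds")
  tref <- curves[[1L]]$t_ms
  vals <- matrix(NA_real_, length(tref), length(curves))
  for (i in seq_along(curves)) {
    ci <- curves[[i]]
    if (length(ci$t_ms) == length(tref) &&
        max(abs(ci$t_ms - tref)) <= 1e-9 * max(tref)) {
      vals[, i] <- ci$D_um2_per_ms
    } else if (interpolate) {
      if (min(ci$t_ms) > min(tref) || max(ci$t_ms) < max(tref))
        stop("curve ", i, " does not cover the reference grid; ",
             "cannot interpolate")
      vals[, i] <- stats::approx(ci$t_ms, ci$D_um2_per_ms, xout = tref)$y
    } else {
      stop("curves are on different time grids; set interpolate = TRUE")
    }
  }
  m <- drop(vals %*% w)
  sdw <- sqrt(pmax(drop(vals^2 %*% w) - m^2, 0))
  dt_curve(tref, m, sd = sdw, kind = kinds)
}

#' Hodges-Lehmann pseudo-median
#'
#' Median of all pairwise (Walsh) averages `(x_i + x_j)/2`, `i <= j` — a
#' robust location estimator.
#'
#' @param x numeric sample.
#' @return The pseudo-median.
#' @export
hodges_lehmann <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1L) stop("empty sample")
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  stats::median((x[idx[, 1L]] + x[idx[, 2L]]) / 2)
}

#' Median absolute deviation about the Hodges-Lehmann pseudo-median
#'
#' `median(|x_i - HL(x)|)`: the robust scale used in the nonparametric
#' effect size. `center = "median"` gives the plain-median variant.
#'
#' @param x numeric sample.
#' @param center `"hodges_lehmann"` (default) or `"median"`.
#' @return The MAD (no consistency constant applied).
#' @export
mad_hl <- function(x, center = c("hodges_lehmann", "median")) {
  center <- match.arg(center)
  c0 <- if (center == "hodges_lehmann") hodges_lehmann(x)
        else stats::median(x)
  stats::median(abs(x - c0))
}

#' Nonparametric effect size between two samples
#'
#' `d_eff = (median(X) - median(Y)) / PMAD_XY`, where each sample's MAD is
#' taken about its Hodges-Lehmann pseudo-median and the pooled MAD uses
#' (n - 1) degrees-of-freedom weights,
#' `PMAD = sqrt(((nX-1) MAD_X^2 + (nY-1) MAD_Y^2) / (nX + nY - 2))`.
#' Chosen over hypothesis tests because with large axon cohorts trivially
#' small shifts become "significant"; the effect size stays interpretable.
#'
#' @param x,y numeric samples, each with at least 5 values.
#' @param center MAD centering, see [mad_hl()].
#' @return Object of class `"effect_size"`: list with `d_eff`,
#'   `median_x`, `median_y`, `mad_x`, `mad_y`, `pooled_mad`, `n_x`, `n_y`.
#' @export
effect_size <- function(x, y, center = "hodges_lehmann") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 5L || length(y) < 5L)
    stop("each sample needs at least 5 values")
  mx <- mad_hl(x, center); my <- mad_hl(y, center)
  nx <- length(x); ny <- length(y)
  pmad <- sqrt(((nx - 1) * mx^2 + (ny - 1) * my^2) / (nx + ny - 2))
  if (pmad == 0)
    stop("pooled MAD is zero (both samples constant); d_eff undefined")
  structure(
    list(d_eff = (stats::median(x) - stats::median(y)) / pmad,
         median_x = stats::median(x), median_y = stats::median(y),
         mad_x = mx, mad_y = my, pooled_mad = pmad,
         n_x = nx, n_y = ny),
    class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("d_eff = %.4g (medians %.4g vs %.4g, pooled MAD %.4g; n = %d, %d)\n",
              x$d_eff, x$median_x, x$median_y, x$pooled_mad, x$n_x, x$n_y))
  invisible(x)
}

#' Max-margin projection separating two groups in a 2-D parameter plane
#'
#' Fits a linear maximum-margin (support-vector) classifier to two groups
#' of 2-D points — e.g. (tortuosity, Gamma0) or (Dinf, cD) per axon — and
#' projects every point onto the hyperplane normal, yielding a scalar
#' score z per point whose between-group effect size summarizes the
#' separation. Class imbalance is handled by subsampling the larger group
#' (without replacement, seeded) to the smaller group's size before
#' fitting; all original points are then projected. Features are robustly
#' standardized (pooled median/MAD per feature) before fitting, and z is
#' oriented so the first (control) group has the lower median.
#'
#' @param points_x numeric matrix (n x 2), group A (control/reference).
#' @param points_y numeric matrix (m x 2), group B.
#' @param seed RNG seed for the subsampling.
#' @param cost soft-margin regularization, default 1.
#' @return Object of class `"margin_projection"`: list with `z_x`, `z_y`
#'   (signed distances to the hyperplane), `normal` (unit normal in
#'   standardized coordinates), `offset`, `d_eff` (an `effect_size` of
#'   z_y vs z_x), `center`, `scale` (the standardization), `seed`.
#' @export
max_margin_projection <- function(points_x, points_y, seed = 1, cost = 1) {
  X <- as.matrix(points_x); Y <- as.matrix(points_y)
  if (ncol(X) != 2L || ncol(Y) != 2L) stop("points must be n x 2 matrices")
  if (nrow(X) < 10L || nrow(Y) < 10L)
    stop("each group needs at least 10 points")
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("coordinates must be finite")
  pooled <- rbind(X, Y)
  ctr <- apply(pooled, 2L, stats::median)
  scl <- apply(pooled, 2L, stats::mad)
  if (any(scl == 0))
    stop("degenerate points: a coordinate has zero spread")
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Ys <- sweep(sweep(Y, 2L, ctr), 2L, scl, "/")
  set.seed(as.integer(seed))
  n <- min(nrow(Xs), nrow(Ys))
  Xf <- Xs[sample.int(nrow(Xs), n), , drop = FALSE]
  Yf <- Ys[sample.int(nrow(Ys), n), , drop = FALSE]
  lab <- factor(rep(c("A", "B"), each = n))
  fit <- e1071::svm(rbind(Xf, Yf), lab, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("degenerate separating direction")
  w <- w / nw; b <- b / nw
  z_x <- drop(Xs %*% w) + b
  z_y <- drop(Ys %*% w) + b
  if (stats::median(z_x) > stats::median(z_y)) {
    w <- -w; b <- -b; z_x <- -z_x; z_y <- -z_y
  }
  structure(
    list(z_x = z_x, z_y = z_y, normal = w, offset = b,
         d_eff = effect_size(z_y, z_x), center = ctr, scale = scl,
         seed = as.integer(seed)),
    class = "margin_projection")
}

#' @export
print.margin_projection <- function(x, ...) {
  cat(sprintf("Max-margin projection: normal (%.3f, %.3f), offset %.3f\n",
              x$normal[1L], x$normal[2L], x$offset))
  cat(sprintf("  group separation d_eff(z) = %.4g\n", x$d_eff$d_eff))
  invisible(x)
}

#' Read / write a cohort table
#'
#' TSV with header columns `axon_id`, `group`, `tortuosity`, `gamma0_um`,
#' `Dinf`, `cD`, `weight`, `xi`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("axon_id", "group", "tortuosity", "gamma0_um", "Dinf", "cD",
            "weight", "xi")
  if (!all(need %in% names(tab)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_cohort_table
#' @param tab cohort data.frame.
#' @export
write_cohort_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# axondt cohort v1", con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
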