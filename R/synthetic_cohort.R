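#' Recipe for a two-group synthetic cohort
#'
#' Defines per-group parameter ranges for the bead generator
#' ([generate_bead_profile()]); each axon draws its parameters uniformly
#' from its group's ranges. Group contrasts are parameterized shifts
#' (e.g. a "TBI-like" group with more prominent beads and shorter
#' inter-bead spacing), so only the direction of downstream effects is
#' meaningful, not their magnitude.
#'
#' @param control,case named lists of ranges; each element is a length-2
#'   numeric `c(lo, hi)` for any of `A1`, `sigma1`, `a_bar`,
#'   `sigma_a_rel` (sd as a fraction of a_bar). Missing entries use the
#'   defaults `A1 = c(0.1, 2.5)`, `sigma1 = c(3, 7)`, `a_bar = c(3, 7)`,
#'   `sigma_a_rel = c(0.8, 1.2)`.
#' @param n_axons axons per group, default 20.
#' @param L profile length (um), default 300.
#' @param dl grid spacing (um), default 0.1.
#' @param A0 base area (um^2), default `pi * 0.25`.
#' @param seed master seed.
#' @return Object of class `"cohort_recipe"`.
#' @export
cohort_recipe <- function(control = list(), case = list(), n_axons = 20,
                          L = 300, dl = 0.1, A0 = pi * 0.25, seed = 1) {
  defaults <- list(A1 = c(0.1, 2.5), sigma1 = c(3, 7), a_bar = c(3, 7),
                   sigma_a_rel = c(0.8, 1.2))
  fill <- function(ranges) {
    out <- utils::modifyList(defaults, ranges)
    for (nm in names(out)) {
      r <- out[[nm]]
      if (length(r) != 2L || r[1L] > r[2L] || any(r < 0))
        stop("range '", nm, "' must be a nonnegative c(lo, hi)")
    }
    out
  }
  if (n_axons < 1L) stop("each group needs at least one axon")
  structure(list(control = fill(control), case = fill(case),
                 n_axons = as.integer(n_axons), L = L, dl = dl, A0 = A0,
                 seed = as.integer(seed)),
            class = "cohort_recipe")
}

#' Generate a labeled two-group cohort of bead profiles
#'
#' Draws per-axon generator parameters from the recipe's group ranges
#' (seeded from the master seed) and builds every profile with
#' [generate_bead_profile()]. Same recipe and seed give an identical
#' cohort. The full set of drawn parameters is returned as a manifest.
#'
#' @param recipe a `cohort_recipe`.
#' @return List with `profiles` (list of `axon_profile`), `group`
#'   (character vector, `"control"`/`"case"`), `manifest` (data.frame of
#'   every parameter draw, including each profile's seed).
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  set.seed(recipe$seed)
  groups <- c(rep("control", recipe$n_axons), rep("case", recipe$n_axons))
  draws <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    rg <- recipe[[groups[i]]]
    a_bar <- stats::runif(1, rg$a_bar[1L], rg$a_bar[2L])
    draws[[i]] <- list(
      A1 = stats::runif(1, rg$A1[1L], rg$A1[2L]),
      sigma1 = stats::runif(1, rg$sigma1[1L], rg$sigma1[2L]),
      a_bar = a_bar,
      sigma_a = a_bar * stats::runif(1, rg$sigma_a_rel[1L],
                                     rg$sigma_a_rel[2L]),
      seed = sample.int(.Machine$integer.max, 1L))
  }
  profiles <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    d <- draws[[i]]
    profiles[[i]] <- generate_bead_profile(
      A0 = recipe$A0, A1 = d$A1, sigma1 = d$sigma1, a_bar = d$a_bar,
      sigma_a = d$sigma_a, L = recipe$L, dl = recipe$dl, seed = d$seed,
      axon_id = sprintf("%s-%03d", groups[i], i))
  }
  manifest <- data.frame(
    axon_id = vapply(profiles, `[[`, character(1), "axon_id"),
    group = groups,
    A1 = vapply(draws, `[[`, numeric(1), "A1"),
    sigma1 = vapply(draws, `[[`, numeric(1), "sigma1"),
    a_bar = vapply(draws, `[[`, numeric(1), "a_bar"),
    sigma_a = vapply(draws, `[[`, numeric(1), "sigma_a"),
    seed = vapply(draws, `[[`, numeric(1), "seed"))
  list(profiles = profiles, group = groups, manifest = manifest)
}

#' Geometric and diffusion parameters for a cohort
#'
#' Runs the forward pipeline on every profile: tortuosity, spectral
#' plateau, predicted `(Dinf, cD)` (at sinuosity 1 unless skeletons are
#' attached), and normalized volume weights. The result is a cohort table
#' suitable for [effect_size()] and [max_margin_projection()].
#'
#' @param profiles list of `axon_profile`s.
#' @param group character vector of group labels (recycled if length 1).
#' @param D0 intrinsic diffusivity, default 2 um^2/ms.
#' @param beta_grid plateau sweep fractions, see [plateau()].
#' @return data.frame with columns `axon_id`, `group`, `tortuosity`,
#'   `gamma0_um`, `Dinf`, `cD`, `weight`, `xi`.
#' @export
cohort_parameters <- function(profiles, group, D0 = 2,
                              beta_grid = seq(0.92, 0.97, by = 0.01)) {
  if (length(group) == 1L) group <- rep(group, length(profiles))
  if (length(group) != length(profiles))
    stop("one group label per profile required")
  w <- volume_weights(profiles)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    rel <- relative_profile(p)
    xi <- if (!is.null(p$skeleton)) sinuosity(p$skeleton) else 1
    tort <- tortuosity(rel)
    g0 <- plateau(psd_eta(rel), beta_grid = beta_grid)$gamma0
    Dinf <- D0 / (tort * xi^2)
    data.frame(axon_id = p$axon_id, group = group[i], tortuosity = tort,
               gamma0_um = g0, Dinf = Dinf,
               cD = predict_cd(g0, D0 / tort, xi = xi), weight = w[i],
               xi = xi)
  })
  do.call(rbind, rows)
}
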