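#' Simulate a potentiometric redox titration
#'
#' Evaluates the multi-couple Nernst model on a potential grid and adds
#' i.i.d. Gaussian noise per replicate, emulating optically monitored
#' thin-layer potentiometry (fraction reduced vs applied potential, CHES
#' buffer pH 8.6 conditions). The generating truth is returned alongside the
#' data for closed-loop recovery tests. Pure function of its arguments:
#' identical seeds give identical tables.
#'
#' @param midpoints True couple midpoints (mV vs NHE).
#' @param weights Couple weights (default equal).
#' @param grid Potential grid (mV; default -400 to +100 in 5 mV steps).
#' @param noise_sd Gaussian noise SD on the fraction (default 0.02).
#' @param n_replicates Number of replicates (default 3, matching triplicate
#'   recording).
#' @param seed Mandatory RNG seed.
#' @return List with `data` (data frame: `potential_mV`, `fraction`,
#'   `replicate`) and `truth`.
#' @export
gen_redox_titration <- function(midpoints, weights = NULL,
                                grid = seq(-400, 100, by = 5),
                                noise_sd = 0.02, n_replicates = 3, seed) {
  if (missing(seed) || is.null(seed))
    stop("gen_redox_titration: a seed is required", call. = FALSE)
  if (noise_sd < 0)
    stop("gen_redox_titration: noise_sd must be >= 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(midpoints),
                                       length(midpoints))
  set.seed(seed)
  clean <- nernst_model(grid, midpoints, weights)
  data <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    data.frame(potential_mV = grid,
               fraction = clean + rnorm(length(grid), 0, noise_sd),
               replicate = r)))
  list(data = data,
       truth = list(midpoints = midpoints, weights = weights,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate a tight-binding ligand isotherm
#'
#' Evaluates the Morrison bound fraction on a ligand grid with a linear
#' signal model and adds i.i.d. Gaussian noise per replicate, emulating a
#' hemin-into-apoprotein titration in the tight-binding regime.
#'
#' @param kd True dissociation constant (same units as concentrations).
#' @param site_conc Total site concentration.
#' @param grid Ligand concentrations; default 24 points from 0 to
#'   `2 * site_conc`.
#' @param scale,offset Linear signal model (defaults 1 and 0).
#' @param noise_sd Gaussian noise SD on the signal (default 0.02).
#' @param n_replicates Number of replicates (default 3).
#' @param seed Mandatory RNG seed.
#' @return List with `data` (data frame: `ligand`, `signal`, `replicate`)
#'   and `truth`.
#' @export
gen_binding_isotherm <- function(kd, site_conc,
                                 grid = seq(0, 2 * site_conc,
                                            length.out = 24),
                                 scale = 1, offset = 0,
                                 noise_sd = 0.02, n_replicates = 3, seed) {
  if (missing(seed) || is.null(seed))
    stop("gen_binding_isotherm: a seed is required", call. = FALSE)
  if (noise_sd < 0)
    stop("gen_binding_isotherm: noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  clean <- offset + scale * morrison_bound_fraction(site_conc, grid, kd)
  data <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    data.frame(ligand = grid,
               signal = clean + rnorm(length(grid), 0, noise_sd),
               replicate = r)))
  list(data = data,
       truth = list(kd = kd, site_conc = site_conc, scale = scale,
                    offset = offset, noise_sd = noise_sd, seed = seed))
}

#' Generate charge-perturbation variants of a site system
#'
#' Emulates charge-altering mutations (e.g. Thr-to-Asp substitutions near a
#' redox center) as point charges placed at given distances from the heme
#' Fe, either as non-titrating fixed charges or as titratable acid/base
#' sites with a supplied pKa. Multiple charges within one variant are spread
#' at equal angles around the Fe in the plane normal to the bundle axis
#' (two charges sit on opposite sides, mirroring the pseudo-symmetric
#' double-mutant geometry). All variants share the redox site(s) of the
#' base system.
#'
#' @param base A [site_system()] containing at least one redox site.
#' @param specs A data frame with columns `distance` (Angstrom, >= 3),
#'   `charge` (elementary charges), `titratable` (logical) and `pka`
#'   (used when titratable), describing one variant; or a list of such data
#'   frames describing several variants.
#' @return A list of [site_system()] variants (one per spec set; an empty
#'   spec reproduces the base system).
#' @export
gen_charge_variants <- function(base, specs) {
  stopifnot(inherits(base, "site_system"))
  if (is.data.frame(specs)) specs <- list(specs)
  kinds <- vapply(base$sites, `[[`, character(1), "kind")
  if (!any(kinds == "redox"))
    stop("gen_charge_variants: base system has no redox site", call. = FALSE)
  fe <- base$sites[[which(kinds == "redox")[1]]]$center

  lapply(specs, function(sp) {
    sp <- as.data.frame(sp)
    if (nrow(sp) == 0) return(base)
    stopifnot(all(c("distance", "charge") %in% names(sp)))
    if (!"titratable" %in% names(sp)) sp$titratable <- FALSE
    if (!"pka" %in% names(sp)) sp$pka <- NA_real_
    if (any(sp$distance < 3))
      stop("gen_charge_variants: distances must be >= 3 A", call. = FALSE)
    angles <- 2 * pi * (seq_len(nrow(sp)) - 1) / nrow(sp)
    centers <- t(vapply(seq_len(nrow(sp)), function(i)
      fe + sp$distance[i] * c(cos(angles[i]), sin(angles[i]), 0),
      numeric(3)))

    sites <- base$sites
    fixed <- base$fixed_charges
    for (i in seq_len(nrow(sp))) {
      if (isTRUE(sp$titratable[i])) {
        if (is.na(sp$pka[i]))
          stop("gen_charge_variants: titratable charges need a pKa",
               call. = FALSE)
        kind <- if (sp$charge[i] < 0) "acid" else "base"
        sites[[length(sites) + 1]] <- titratable_site(
          id = sprintf("pert%d", i), kind = kind, intrinsic = sp$pka[i],
          center = centers[i, ], charge_delta = sp$charge[i])
      } else {
        fixed <- rbind(fixed, data.frame(x = centers[i, 1],
                                         y = centers[i, 2],
                                         z = centers[i, 3],
                                         q = sp$charge[i]))
      }
    }
    site_system(sites, base$model, fixed_charges = fixed)
  })
}
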