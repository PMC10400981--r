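#' Titration curve object
#'
#' @param grid Ordered solution-potential (mV) or pH values.
#' @param occupancy Matrix (length(grid) x n_sites) of mean occupancies.
#' @param se Matrix of per-point Monte-Carlo standard errors (0 for exact
#'   enumeration).
#' @param site_ids Character vector of site labels.
#' @param pH pH at which the curve was computed.
#' @param method `"exact"` or `"mc"`.
#' @return An object of class `titration_curve`.
#' @keywords internal
titration_curve <- function(grid, occupancy, se, site_ids, pH, method) {
  structure(list(grid = grid, occupancy = occupancy, se = se,
                 site_ids = site_ids, pH = pH, method = method),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve (%s): %d grid points, %d site(s), pH %.2f\n",
              x$method, length(x$grid), length(x$site_ids), x$pH))
  invisible(x)
}

#' Exact titration by enumeration of all microstates
#'
#' Boltzmann average of per-site occupancy over all 2^N microstates of a
#' [site_system()] at each grid potential, at fixed pH. Serves as the
#' brute-force oracle for the Monte-Carlo engine; limited to 20 sites.
#'
#' @param system A [site_system()].
#' @param grid Solution potentials (mV vs NHE).
#' @param pH Fixed pH (default 8.6, the potentiometry buffer).
#' @return A `titration_curve` with zero `se`.
#' @export
exact_titrate <- function(system, grid = seq(-400, 100, by = 5), pH = 8.6) {
  n <- length(system$sites)
  if (n > 20)
    stop("exact_titrate: enumeration limited to 20 sites", call. = FALSE)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(states) <- site_ids(system)

  g0 <- site_g(system, pH, e_solution = 0)   # energies at E = 0
  kinds <- vapply(system$sites, `[[`, character(1), "kind")
  n_elec <- as.numeric(states %*% (kinds == "redox"))  # electrons per state
  base_e <- as.numeric(states %*% g0) +
    0.5 * rowSums((states %*% system$W) * states)

  occ <- matrix(NA_real_, length(grid), n)
  for (k in seq_along(grid)) {
    G <- base_e + n_elec * grid[k]
    w <- exp(-(G - min(G)) / .kT_meV)
    occ[k, ] <- as.numeric(t(states) %*% w) / sum(w)
  }
  titration_curve(grid, occ, matrix(0, length(grid), n),
                  site_ids(system), pH, "exact")
}

#' Metropolis Monte-Carlo titration
#'
#' Single-site-flip Metropolis sampling of the joint proton/electron binding
#' equilibrium at 298 K, run independently at each grid potential. The first
#' 20% of each chain is discarded as burn-in and mean occupancies are
#' reported with batch-mean standard errors (10 batches).
#'
#' @param system A [site_system()].
#' @param grid Solution potentials (mV vs NHE).
#' @param pH Fixed pH (default 8.6).
#' @param n_steps Monte-Carlo steps per grid point (default 1e5; fewer than
#'   1000 is refused as unreliable).
#' @param seed Mandatory RNG seed; identical seeds give bitwise-identical
#'   output.
#' @param burn_in Burn-in fraction (default 0.2).
#' @param n_batches Number of batches for the standard error (default 10).
#' @return A `titration_curve` with Monte-Carlo standard errors.
#' @export
mc_titrate <- function(system, grid = seq(-400, 100, by = 5), pH = 8.6,
                       n_steps = 100000, seed, burn_in = 0.2,
                       n_batches = 10) {
  if (missing(seed) || is.null(seed))
    stop("mc_titrate: a seed is required (no implicit randomness)",
         call. = FALSE)
  if (n_steps < 1000)
    stop("mc_titrate: fewer than 1000 steps refused (unreliable averages)",
         call. = FALSE)
  n <- length(system$sites)
  set.seed(seed)
  occ <- se <- matrix(NA_real_, length(grid), n)
  for (k in seq_along(grid)) {
    g <- site_g(system, pH, e_solution = grid[k])
    res <- mc_chain(g, system$W, .kT_meV, as.integer(n_steps), burn_in,
                    as.integer(n_batches))
    occ[k, ] <- res$mean
    se[k, ] <- res$se
  }
  titration_curve(grid, occ, se, site_ids(system), pH, "mc")
}

#' Extract a midpoint potential from a titration curve
#'
#' Monotone (isotonic-regression smoothed) interpolation of the
#' half-occupancy crossing of a redox site. Orientation of the grid is
#' immaterial.
#'
#' @param curve A `titration_curve`.
#' @param site_id Site label or index (default: first site).
#' @return Midpoint potential E_m (mV vs NHE).
#' @export
extract_em <- function(curve, site_id = 1) {
  if (is.character(site_id)) {
    idx <- match(site_id, curve$site_ids)
    if (is.na(idx)) stop(sprintf("extract_em: unknown site '%s'", site_id),
                         call. = FALSE)
  } else idx <- site_id
  ord <- order(curve$grid)
  e <- curve$grid[ord]
  occ <- curve$occupancy[ord, idx]
  # enforce monotone decrease in E (within MC error) via isotonic regression
  iso <- isoreg(e, 1 - occ)
  f <- iso$yf  # non-decreasing fit of 1 - occupancy
  if (f[1] > 0.5 || f[length(f)] < 0.5)
    stop(paste0("extract_em: occupancy does not cross 0.5 within the grid; ",
                "extend the potential range"), call. = FALSE)
  i <- max(which(f <= 0.5))
  if (i == length(f) || f[i] == 0.5) {
    j <- range(which(abs(f - 0.5) < 1e-12))
    if (all(is.finite(j))) return(mean(e[j]))
    return(e[i])
  }
  e[i] + (0.5 - f[i]) / (f[i + 1] - f[i]) * (e[i + 1] - e[i])
}

#' Predict a mutational midpoint-potential shift
#'
#' Difference in the extracted midpoint of the redox site of interest
#' between a variant and a reference system, both titrated with the same
#' engine, grid and pH.
#'
#' @param variant,reference [site_system()] objects sharing the redox site
#'   of interest.
#' @param grid Solution potentials (mV vs NHE).
#' @param pH Fixed pH (default 8.6).
#' @param site_id Redox site label (default: the first redox site of the
#'   reference).
#' @param method `"exact"` (default) or `"mc"`.
#' @param seed RNG seed (required for `method = "mc"`).
#' @param ... Passed to the titration engine.
#' @return The shift dE_m = E_m(variant) - E_m(reference), in mV.
#' @export
predict_shift <- function(variant, reference, grid = seq(-400, 100, by = 5),
                          pH = 8.6, site_id = NULL,
                          method = c("exact", "mc"), seed = NULL, ...) {
  method <- match.arg(method)
  kinds_ref <- vapply(reference$sites, `[[`, character(1), "kind")
  if (!any(kinds_ref == "redox"))
    stop("predict_shift: reference has no redox site", call. = FALSE)
  if (is.null(site_id))
    site_id <- site_ids(reference)[which(kinds_ref == "redox")[1]]
  if (!site_id %in% site_ids(variant))
    stop(sprintf("predict_shift: variant lacks redox site '%s'", site_id),
         call. = FALSE)
  titr <- function(sys, sd) {
    if (method == "exact") exact_titrate(sys, grid, pH)
    else mc_titrate(sys, grid, pH, seed = sd, ...)
  }
  em_ref <- extract_em(titr(reference, seed), site_id)
  em_var <- extract_em(titr(variant, if (is.null(seed)) NULL else seed + 1),
                       site_id)
  em_var - em_ref
}
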