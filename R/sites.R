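#' Titratable site
#'
#' A redox or acid/base site of the microstate energy model. "Occupancy"
#' denotes the bound-particle state: an added electron for a redox site
#' (charge delta -1, i.e. the reduced state), the deprotonated state for an
#' acid (charge delta -1) and the protonated state for a base (charge
#' delta +1).
#'
#' @param id Site label.
#' @param kind One of `"redox"`, `"acid"`, `"base"`.
#' @param intrinsic Intrinsic midpoint potential E_m,int (mV vs NHE) for
#'   redox sites; intrinsic pKa otherwise.
#' @param center Charge-center coordinate (length-3, Angstrom).
#' @param charge_delta Elementary charge carried by the occupied state;
#'   defaults to -1 (redox, acid) or +1 (base).
#'
#' @return An object of class `titratable_site`.
#' @export
titratable_site <- function(id, kind = c("redox", "acid", "base"),
                            intrinsic, center, charge_delta = NULL) {
  kind <- match.arg(kind)
  if (is.null(charge_delta))
    charge_delta <- if (kind == "base") 1 else -1
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("titratable_site: center must be a finite length-3 coordinate",
         call. = FALSE)
  structure(list(id = as.character(id), kind = kind,
                 intrinsic = intrinsic, center = center,
                 charge_delta = charge_delta),
            class = "titratable_site")
}

#' Interaction model for site-site electrostatics
#'
#' Uniform-dielectric screened-Coulomb interaction model. The protein
#' dielectric applies to all pairwise terms; the solvent dielectric is
#' carried as metadata (a molecular-surface two-dielectric treatment can be
#' substituted by supplying an external `W` matrix to [site_system()]).
#' Optional Debye screening uses the 298 K aqueous screening length.
#'
#' @param dielectric Protein dielectric constant (default 20).
#' @param solvent_dielectric Solvent dielectric constant (metadata,
#'   default 80).
#' @param temperature Temperature (K, default 298; informational).
#' @param ionic_strength Ionic strength (mol/L, default 0 = no screening).
#'
#' @return An object of class `interaction_model`.
#' @export
interaction_model <- function(dielectric = 20, solvent_dielectric = 80,
                              temperature = 298, ionic_strength = 0) {
  structure(list(dielectric = dielectric,
                 solvent_dielectric = solvent_dielectric,
                 temperature = temperature,
                 ionic_strength = ionic_strength),
            class = "interaction_model")
}

#' Pairwise interaction energy between two occupied sites
#'
#' Screened-Coulomb energy of the occupancy charges:
#' \deqn{W_{ij} = 14399.6 \, q_i q_j / (\epsilon r_{ij}) \; \mathrm{meV}}
#' (q in elementary charges, r in Angstrom), multiplied by
#' \eqn{\exp(-\kappa r_{ij})} when the model carries a non-zero ionic
#' strength. Distances below 2 Angstrom are floored with a warning.
#'
#' @param site_i,site_j `titratable_site` objects.
#' @param model An [interaction_model()].
#' @return Energy in meV.
#' @export
pairwise_interaction <- function(site_i, site_j, model = interaction_model()) {
  r <- sqrt(sum((site_i$center - site_j$center)^2))
  if (r < 2) {
    warning(sprintf(
      "pairwise_interaction: site separation %.2f A floored to 2 A", r))
    r <- 2
  }
  w <- .coulomb_meV_A * site_i$charge_delta * site_j$charge_delta /
    (model$dielectric * r)
  if (model$ionic_strength > 0) {
    kappa <- sqrt(model$ionic_strength) / 3.04  # 1/Angstrom at 298 K
    w <- w * exp(-kappa * r)
  }
  w
}

#' Site system: sites, intrinsic energies and interaction matrix
#'
#' Bundles titratable sites with their pairwise interaction matrix `W`
#' (meV, symmetric, zero diagonal) and optional fixed background charges.
#' `W` is computed from the screened-Coulomb [pairwise_interaction()] unless
#' supplied externally (e.g. from a Poisson-Boltzmann backend); per-site
#' intrinsic-energy offsets `g_offsets` (meV, added to the occupied state)
#' can likewise be supplied externally. Fixed charges contribute to each
#' site's offset as non-titrating Coulomb terms.
#'
#' @param sites List of [titratable_site()] objects.
#' @param model An [interaction_model()].
#' @param W Optional externally computed interaction matrix (meV).
#' @param g_offsets Optional per-site energy offsets (meV).
#' @param fixed_charges Optional data frame with columns `x`, `y`, `z`, `q`
#'   of non-titrating point charges.
#' @return An object of class `site_system`.
#' @export
site_system <- function(sites, model = interaction_model(), W = NULL,
                        g_offsets = NULL, fixed_charges = NULL) {
  if (length(sites) < 1 ||
      !all(vapply(sites, inherits, logical(1), "titratable_site")))
    stop("site_system: need a list of titratable_site objects", call. = FALSE)
  n <- length(sites)
  ids <- vapply(sites, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("site_system: site ids must be unique", call. = FALSE)
  if (is.null(W)) {
    W <- matrix(0, n, n)
    if (n > 1)
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        W[i, j] <- W[j, i] <- pairwise_interaction(sites[[i]], sites[[j]],
                                                   model)
  } else {
    W <- as.matrix(W)
    if (!all(dim(W) == n) || any(abs(W - t(W)) > 1e-9) ||
        any(diag(W) != 0) || any(!is.finite(W)))
      stop("site_system: W must be a finite symmetric matrix, zero diagonal",
           call. = FALSE)
  }
  if (is.null(g_offsets)) g_offsets <- numeric(n)
  if (length(g_offsets) != n)
    stop("site_system: g_offsets length must match sites", call. = FALSE)
  if (!is.null(fixed_charges)) {
    fixed_charges <- as.data.frame(fixed_charges)
    stopifnot(all(c("x", "y", "z", "q") %in% names(fixed_charges)))
    for (i in seq_len(n)) {
      r <- sqrt((fixed_charges$x - sites[[i]]$center[1])^2 +
                  (fixed_charges$y - sites[[i]]$center[2])^2 +
                  (fixed_charges$z - sites[[i]]$center[3])^2)
      r <- pmax(r, 2)
      w <- .coulomb_meV_A * fixed_charges$q * sites[[i]]$charge_delta /
        (model$dielectric * r)
      if (model$ionic_strength > 0)
        w <- w * exp(-sqrt(model$ionic_strength) / 3.04 * r)
      g_offsets[i] <- g_offsets[i] + sum(w)
    }
  }
  dimnames(W) <- list(ids, ids)
  structure(list(sites = sites, model = model, W = W,
                 g_offsets = as.numeric(g_offsets),
                 fixed_charges = fixed_charges),
            class = "site_system")
}

#' @export
print.site_system <- function(x, ...) {
  kinds <- vapply(x$sites, `[[`, character(1), "kind")
  cat(sprintf("Site system: %d sites (%s), dielectric %.0f\n",
              length(x$sites),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", "),
              x$model$dielectric))
  invisible(x)
}

#' Site labels of a site system
#'
#' @param system A [site_system()].
#' @return Character vector of site ids, in system order.
#' @export
site_ids <- function(system) vapply(system$sites, `[[`, character(1), "id")

# intrinsic occupied-state energies (meV) at given solution conditions;
# redox term excludes e_solution (added separately as a linear term)
site_g <- function(system, pH, e_solution = 0) {
  vapply(seq_along(system$sites), function(i) {
    s <- system$sites[[i]]
    g <- switch(s$kind,
                redox = e_solution - s$intrinsic,
                acid = .nernst_mV * (s$intrinsic - pH),
                base = .nernst_mV * (pH - s$intrinsic))
    g + system$g_offsets[i]
  }, numeric(1))
}

#' Microstate energy
#'
#' Energy (meV) of a binary occupancy vector `x` relative to the all-empty
#' reference state:
#' \deqn{G(x) = \sum_i x_i g_i + \sum_{i<j} x_i x_j W_{ij}}
#' where for redox sites \eqn{g_i = E_{sol} - E_{m,int,i}} (meV, one
#' electron) and for acid/base sites
#' \eqn{g_i = \pm \ln(10) kT (\mathrm{pH} - \mathrm{p}K_{a,int,i})}.
#'
#' @param x Binary occupancy vector, one entry per site.
#' @param system A [site_system()].
#' @param pH Solution pH.
#' @param e_solution Solution redox potential (mV vs NHE).
#' @return Energy in meV.
#' @export
microstate_energy <- function(x, system, pH = 8.6, e_solution = 0) {
  x <- as.numeric(x)
  if (length(x) != length(system$sites) || any(!x %in% c(0, 1)))
    stop("microstate_energy: x must be binary with one entry per site",
         call. = FALSE)
  g <- site_g(system, pH, e_solution)
  sum(x * g) + 0.5 * as.numeric(t(x) %*% system$W %*% x)
}

standard_pka <- function(aa) {
  switch(aa,
         D = 4.0, E = 4.4, R = 12.0, K = 10.4, H = 6.3,
         stop(sprintf("no intrinsic pKa for residue type '%s'", aa),
              call. = FALSE))
}

#' Build a site system from a maquette design
#'
#' Converts each heme into a redox site (charge center at Fe) and each
#' mutation into an acid (Asp/Glu) or base (Arg/Lys/His) site. For the
#' C-alpha-level models the side-chain charge center is estimated as the
#' C-alpha displaced 2.5 Angstrom toward the bundle axis. The heme intrinsic
#' potential defaults to the measured midpoint of the monoheme reference
#' variant (-118 mV vs NHE), a calibration choice: only potential shifts
#' between systems sharing this calibration are claimed predictive.
#'
#' @param design A `maquette_design` from [design_bundle()].
#' @param mutations Character vector of substitutions in global numbering,
#'   e.g. `c("T19D", "T77D")`.
#' @param heme_em_int Intrinsic heme midpoint potential (mV vs NHE).
#' @param model An [interaction_model()].
#' @return A [site_system()].
#' @export
build_site_system <- function(design, mutations = character(),
                              heme_em_int = -118,
                              model = interaction_model()) {
  stopifnot(inherits(design, "maquette_design"))
  sites <- list()
  for (j in seq_along(design$hemes))
    sites[[length(sites) + 1]] <- titratable_site(
      id = paste0("heme", j), kind = "redox", intrinsic = heme_em_int,
      center = design$hemes[[j]]$fe_position)

  map <- design$bundle$residue_map
  for (m in mutations) {
    mm <- regmatches(m, regexec("^([A-Z])(\\d+)([A-Z])$", m))[[1]]
    if (length(mm) != 4)
      stop(sprintf("build_site_system: cannot parse mutation '%s'", m),
           call. = FALSE)
    wt <- mm[2]; pos <- as.integer(mm[3]); to <- mm[4]
    row <- map[map$global == pos, ]
    if (nrow(row) != 1 || is.na(row$helix))
      stop(sprintf(
        "build_site_system: position %d does not exist on a helix", pos),
        call. = FALSE)
    if (row$aa != wt)
      stop(sprintf(
        "build_site_system: position %d is %s, not %s", pos, row$aa, wt),
        call. = FALSE)
    kind <- if (to %in% c("D", "E")) "acid"
    else if (to %in% c("R", "K", "H")) "base"
    else stop(sprintf(
      "build_site_system: residue type '%s' is not titratable", to),
      call. = FALSE)
    ca <- helix_ca(design$bundle, row$helix, row$pos)
    radial <- c(ca[1], ca[2], 0)
    radial <- radial / sqrt(sum(radial^2))
    center <- ca - 2.5 * radial
    sites[[length(sites) + 1]] <- titratable_site(
      id = m, kind = kind, intrinsic = standard_pka(to), center = center)
  }
  site_system(sites, model)
}

#' Export a site system to TSV tables
#'
#' Writes a site table (id, kind, intrinsic, x, y, z, q_delta, g_offset) and
#' a square interaction matrix, both tab-separated, so that energies from an
#' external Poisson-Boltzmann backend can be edited in and re-imported with
#' [read_site_system()].
#'
#' @param system A [site_system()].
#' @param sites_file,w_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_site_system <- function(system, sites_file, w_file) {
  df <- data.frame(
    id = site_ids(system),
    kind = vapply(system$sites, `[[`, character(1), "kind"),
    intrinsic = vapply(system$sites, `[[`, numeric(1), "intrinsic"),
    x = vapply(system$sites, function(s) s$center[1], numeric(1)),
    y = vapply(system$sites, function(s) s$center[2], numeric(1)),
    z = vapply(system$sites, function(s) s$center[3], numeric(1)),
    q_delta = vapply(system$sites, `[[`, numeric(1), "charge_delta"),
    g_offset = system$g_offsets)
  write.table(df, sites_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(system$W, w_file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(c(sites_file, w_file))
}

#' Import a site system from TSV tables
#'
#' @param sites_file,w_file Paths written by [write_site_system()] (or by an
#'   external electrostatics backend following the same layout).
#' @param model An [interaction_model()] recorded with the system.
#' @return A [site_system()] using the imported `W` and offsets verbatim.
#' @export
read_site_system <- function(sites_file, w_file,
                             model = interaction_model()) {
  df <- read.table(sites_file, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  sites <- lapply(seq_len(nrow(df)), function(i)
    titratable_site(df$id[i], df$kind[i], df$intrinsic[i],
                    c(df$x[i], df$y[i], df$z[i]), df$q_delta[i]))
  W <- as.matrix(read.table(w_file, sep = "\t", header = TRUE))
  dimnames(W) <- NULL
  site_system(sites, model, W = W, g_offsets = df$g_offset)
}
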