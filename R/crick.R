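#' Crick coiled-coil parameter set
#'
#' Container for the geometric parameters of an ideal coiled-coil helix:
#' a minor (alpha) helix wound about a superhelical path around the bundle
#' axis (z). Angular frequencies are per residue and signed; a left-handed
#' superhelix (the default for heptad-based coiled coils) has negative
#' `superhelix_frequency`.
#'
#' @param superhelix_radius Superhelix radius r0 (Angstrom).
#' @param superhelix_frequency Superhelix angular frequency (deg/residue,
#'   signed; negative = left-handed).
#' @param minor_radius Minor helix radius r1 (Angstrom); must lie in
#'   \[1.5, 3.0\] for alpha-helical backbones.
#' @param minor_frequency Minor helix angular frequency (deg/residue);
#'   absolute value must lie in \[95, 110\].
#' @param superhelix_phase Superhelix phase at residue 1 (deg).
#' @param minor_phase Minor helix phase at residue 1 (deg); 180 deg points
#'   the C-alpha toward the bundle axis.
#' @param rise_per_residue Axial rise per residue (Angstrom), in \[1.0, 1.6\].
#' @param axial_offset Axial translation of residue 1 (Angstrom).
#'
#' @return An object of class `crick_params`.
#' @export
crick_params <- function(superhelix_radius = 7.6,
                         superhelix_frequency = -2.85,
                         minor_radius = 2.26,
                         minor_frequency = 102.857,
                         superhelix_phase = 0,
                         minor_phase = 180,
                         rise_per_residue = 1.51,
                         axial_offset = 0) {
  p <- list(
    superhelix_radius = superhelix_radius,
    superhelix_frequency = superhelix_frequency,
    minor_radius = minor_radius,
    minor_frequency = minor_frequency,
    superhelix_phase = superhelix_phase,
    minor_phase = minor_phase,
    rise_per_residue = rise_per_residue,
    axial_offset = axial_offset
  )
  class(p) <- "crick_params"
  validate_crick_params(p)
  p
}

validate_crick_params <- function(p) {
  vals <- unlist(p[c("superhelix_radius", "superhelix_frequency",
                     "minor_radius", "minor_frequency", "superhelix_phase",
                     "minor_phase", "rise_per_residue", "axial_offset")])
  if (any(!is.finite(vals)))
    stop("crick_params: all parameters must be finite", call. = FALSE)
  if (p$minor_radius < 1.5 || p$minor_radius > 3.0)
    stop("crick_params: minor_radius must lie in [1.5, 3.0] Angstrom",
         call. = FALSE)
  if (abs(p$minor_frequency) < 95 || abs(p$minor_frequency) > 110)
    stop("crick_params: |minor_frequency| must lie in [95, 110] deg/residue",
         call. = FALSE)
  if (p$rise_per_residue < 1.0 || p$rise_per_residue > 1.6)
    stop("crick_params: rise_per_residue must lie in [1.0, 1.6] Angstrom",
         call. = FALSE)
  if (p$superhelix_radius < 0)
    stop("crick_params: superhelix_radius must be non-negative", call. = FALSE)
  invisible(p)
}

#' @export
print.crick_params <- function(x, ...) {
  cat("Crick coiled-coil parameters\n")
  cat(sprintf("  superhelix: radius %.3f A, frequency %.3f deg/res, phase %.1f deg\n",
              x$superhelix_radius, x$superhelix_frequency, x$superhelix_phase))
  cat(sprintf("  minor helix: radius %.3f A, frequency %.3f deg/res, phase %.1f deg\n",
              x$minor_radius, x$minor_frequency, x$minor_phase))
  cat(sprintf("  rise %.3f A/res, axial offset %.2f A\n",
              x$rise_per_residue, x$axial_offset))
  if (!is.null(attr(x, "rmsd")))
    cat(sprintf("  fit residual RMSD %.4f A\n", attr(x, "rmsd")))
  if (isTRUE(attr(x, "ill_determined")))
    cat("  note: superhelix radius ill-determined (near-zero supercoiling)\n")
  invisible(x)
}

crick_coords <- function(p, n_res, phase_offset = 0) {
  n <- seq_len(n_res) - 1
  w0 <- p$superhelix_frequency * pi / 180
  w1 <- p$minor_frequency * pi / 180
  ph0 <- (p$superhelix_phase + phase_offset) * pi / 180 + w0 * n
  ph1 <- p$minor_phase * pi / 180 + w1 * n
  # pitch angle of the superhelical path
  alpha <- atan2(w0 * p$superhelix_radius, p$rise_per_residue)
  r0 <- p$superhelix_radius
  r1 <- p$minor_radius
  x <- r0 * cos(ph0) + r1 * cos(ph0) * cos(ph1) -
    r1 * cos(alpha) * sin(ph0) * sin(ph1)
  y <- r0 * sin(ph0) + r1 * sin(ph0) * cos(ph1) +
    r1 * cos(alpha) * cos(ph0) * sin(ph1)
  z <- p$rise_per_residue * n + p$axial_offset - r1 * sin(alpha) * sin(ph1)
  cbind(x = x, y = y, z = z)
}

#' Build C-alpha coordinates of a parametric coiled-coil helix
#'
#' Generates `n_res` C-alpha positions on a minor helix wound about the
#' superhelical path defined by a [crick_params()] set. Deterministic.
#'
#' @param params A `crick_params` object.
#' @param n_res Number of residues (>= 4).
#' @param phase_offset Additional superhelix phase (deg), e.g. to place a
#'   second helix of a bundle.
#'
#' @return A numeric `n_res` x 3 matrix of C-alpha coordinates (Angstrom).
#' @export
build_helix <- function(params, n_res, phase_offset = 0) {
  if (!inherits(params, "crick_params"))
    stop("build_helix: 'params' must be a crick_params object", call. = FALSE)
  validate_crick_params(params)
  if (!is.numeric(n_res) || length(n_res) != 1 || n_res < 4)
    stop("build_helix: n_res must be a single integer >= 4", call. = FALSE)
  crick_coords(params, as.integer(n_res), phase_offset)
}

#' Fit Crick coiled-coil parameters to C-alpha coordinates
#'
#' Least-squares estimation of the eight Crick parameters from approximately
#' helical C-alpha coordinates expressed in the canonical frame (bundle axis
#' along z). Reports the residual coordinate RMSD as attribute `"rmsd"`.
#' When the fitted supercoiling is negligible the superhelix radius is
#' geometrically confounded with a lateral offset and is flagged
#' ill-determined (attribute `"ill_determined"`).
#'
#' @param ca_coords Numeric n x 3 matrix of C-alpha coordinates, n >= 8.
#' @param max_rmsd Residual RMSD (Angstrom) above which the input is deemed
#'   non-helical and an error is raised (default 1.5).
#'
#' @return A `crick_params` object with attributes `rmsd` and
#'   `ill_determined`.
#' @export
fit_crick_params <- function(ca_coords, max_rmsd = 1.5) {
  ca <- as.matrix(ca_coords)
  if (ncol(ca) != 3 || nrow(ca) < 8)
    stop("fit_crick_params: need an n x 3 coordinate matrix with n >= 8",
         call. = FALSE)
  if (any(!is.finite(ca)))
    stop("fit_crick_params: coordinates must be finite", call. = FALSE)
  n <- nrow(ca)

  # initial estimates
  rise0 <- mean(diff(ca[, 3]))
  rho <- sqrt(ca[, 1]^2 + ca[, 2]^2)
  r0_0 <- mean(rho)
  r1_0 <- max(min(sd(rho) * sqrt(2), 2.9), 1.6)
  theta <- atan2(ca[, 2], ca[, 1])
  theta_un <- theta[1] + c(0, cumsum(wrap_angle(diff(theta))))
  fit0 <- lm(theta_un ~ seq_len(n))
  w0_0 <- unname(coef(fit0)[2]) * 180 / pi
  ph0_0 <- (unname(coef(fit0)[1]) + unname(coef(fit0)[2])) * 180 / pi

  resid_fun <- function(par) {
    p <- list(superhelix_radius = abs(par[1]),
              superhelix_frequency = par[2],
              minor_radius = abs(par[3]),
              minor_frequency = par[4],
              superhelix_phase = par[5],
              minor_phase = par[6],
              rise_per_residue = par[7],
              axial_offset = par[8])
    as.vector(crick_coords(p, n) - ca)
  }

  best <- NULL
  for (ph1_try in c(0, 90, 180, 270)) {
    start <- c(r0_0, w0_0, r1_0, 102.857, ph0_0, ph1_try, rise0, ca[1, 3])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit_crick_params: optimisation failed on this input", call. = FALSE)

  par <- unname(best$par)
  rmsd <- sqrt(best$deviance / n)
  if (rmsd > max_rmsd)
    stop(sprintf(paste0("fit_crick_params: input is not well described by a ",
                        "coiled-coil model (residual RMSD %.2f A > %.2f A); ",
                        "fitted rise %.2f A/res, minor radius %.2f A"),
                 rmsd, max_rmsd, par[7], abs(par[3])), call. = FALSE)

  out <- list(
    superhelix_radius = abs(par[1]),
    superhelix_frequency = par[2],
    minor_radius = abs(par[3]),
    minor_frequency = par[4],
    superhelix_phase = wrap_deg(par[5]),
    minor_phase = wrap_deg(par[6]),
    rise_per_residue = par[7],
    axial_offset = par[8]
  )
  class(out) <- "crick_params"
  attr(out, "rmsd") <- rmsd
  attr(out, "ill_determined") <- abs(out$superhelix_frequency) < 0.05
  out
}

wrap_angle <- function(a) {
  (a + pi) %% (2 * pi) - pi
}

wrap_deg <- function(a) {
  a %% 360
}
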