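#' Multi-couple Nernst model
#'
#' Fraction reduced at applied potential E for a sum of independent
#' one-electron couples at 298 K:
#' \deqn{f(E) = \sum_c w_c / (1 + 10^{(E - E_{m,c})/59.16})}
#'
#' @param E Potential grid (mV vs NHE).
#' @param midpoints Couple midpoint potentials (mV vs NHE).
#' @param weights Fractional amplitudes (>= 0; default equal weights).
#' @return Fraction reduced at each potential.
#' @export
nernst_model <- function(E, midpoints, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / length(midpoints),
                                       length(midpoints))
  if (length(weights) != length(midpoints) || any(weights < 0))
    stop("nernst_model: weights must be non-negative, one per couple",
         call. = FALSE)
  f <- numeric(length(E))
  for (c in seq_along(midpoints))
    f <- f + weights[c] / (1 + 10^((E - midpoints[c]) / .nernst_mV))
  f
}

#' Fit a potentiometric redox titration
#'
#' Nonlinear least-squares fit of one or two one-electron Nernst couples to
#' fraction-reduced data (oxidative and reductive branches, if present, are
#' fit jointly). The Nernst slope is fixed at 59.16 mV/decade (298 K, n = 1).
#' In `pairs` mode the two couple weights are fixed at 0.5/0.5, the
#' parsimonious treatment of a four-heme chain as two spectroscopically
#' degenerate pairs.
#'
#' @param data Data frame with columns `potential_mV` (or `E`), `fraction`
#'   and optionally `replicate`.
#' @param n_couples 1 or 2.
#' @param pairs If `TRUE` (only with `n_couples = 2`), fix weights at
#'   0.5/0.5.
#' @return An object of class `redox_fit`: `midpoints` (sorted descending),
#'   `weights`, `delta_em` (for two couples), `midpoint_se`, `residual_rms`,
#'   `fitted`, `data`.
#' @export
fit_redox <- function(data, n_couples = 1, pairs = FALSE) {
  data <- as.data.frame(data)
  if (!"potential_mV" %in% names(data) && "E" %in% names(data))
    names(data)[names(data) == "E"] <- "potential_mV"
  stopifnot(all(c("potential_mV", "fraction") %in% names(data)))
  if (!n_couples %in% c(1, 2))
    stop("fit_redox: n_couples must be 1 or 2", call. = FALSE)
  if (pairs && n_couples != 2)
    stop("fit_redox: pairs mode requires n_couples = 2", call. = FALSE)
  E <- data$potential_mV
  y <- data$fraction
  if (length(y) < 8)
    stop("fit_redox: need at least 8 points spanning both asymptotes",
         call. = FALSE)
  if (min(y) > 0.2 || max(y) < 0.8)
    warning(paste0("fit_redox: data do not span both asymptotes; ",
                   "midpoints may be poorly identified"))

  # crude half-reduction estimate for starting values
  o <- order(E)
  e_half <- E[o][which.min(abs(y[o] - 0.5))]
  free_w <- n_couples == 2 && !pairs

  par0 <- if (n_couples == 1) e_half
  else c(e_half + 30, e_half - 30, if (free_w) 0 else NULL)
  resid_fun <- function(par) {
    mids <- par[1:n_couples]
    w <- if (n_couples == 1) 1
    else if (free_w) {
      w1 <- stats::plogis(par[3]); c(w1, 1 - w1)
    } else c(0.5, 0.5)
    y - nernst_model(E, mids, w)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  par <- fit$par
  mids <- par[1:n_couples]
  w <- if (n_couples == 1) 1
  else if (free_w) c(stats::plogis(par[3]), 1 - stats::plogis(par[3]))
  else c(0.5, 0.5)

  dof <- length(y) - length(par)
  sigma2 <- fit$deviance / dof
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se_all <- if (is.null(covm)) rep(NA_real_, length(par))
  else sqrt(pmax(diag(covm), 0))
  mid_se <- se_all[1:n_couples]

  # replicate spread, when replicates exist, supersedes the covariance SEs
  if ("replicate" %in% names(data) &&
      length(unique(data$replicate)) >= 2) {
    reps <- unique(data$replicate)
    rep_mids <- matrix(NA_real_, length(reps), n_couples)
    for (r in seq_along(reps)) {
      sub <- data[data$replicate == reps[r], ]
      rf <- tryCatch(
        minpack.lm::nls.lm(par = par, fn = function(p) {
          mids_r <- p[1:n_couples]
          w_r <- if (n_couples == 1) 1
          else if (free_w) {
            w1 <- stats::plogis(p[3]); c(w1, 1 - w1)
          } else c(0.5, 0.5)
          sub$fraction - nernst_model(sub$potential_mV, mids_r, w_r)
        }), error = function(e) NULL)
      if (!is.null(rf)) rep_mids[r, ] <- sort(rf$par[1:n_couples],
                                              decreasing = TRUE)
    }
    if (sum(stats::complete.cases(rep_mids)) >= 2)
      mid_se <- apply(rep_mids, 2, sd, na.rm = TRUE) /
        sqrt(sum(stats::complete.cases(rep_mids)))
  }

  ord <- order(mids, decreasing = TRUE)
  mids <- mids[ord]; w <- w[ord]; mid_se <- mid_se[ord]
  structure(list(
    midpoints = mids,
    weights = w / sum(w),
    delta_em = if (n_couples == 2) abs(mids[1] - mids[2]) else NA_real_,
    midpoint_se = mid_se,
    residual_rms = sqrt(fit$deviance / length(y)),
    n_couples = n_couples, pairs = pairs,
    fitted = nernst_model(E, mids, w),
    data = data),
    class = "redox_fit")
}

#' @export
print.redox_fit <- function(x, ...) {
  cat(sprintf("Nernst fit (%d couple%s%s)\n", x$n_couples,
              if (x$n_couples > 1) "s" else "",
              if (x$pairs) ", paired weights 0.5/0.5" else ""))
  for (i in seq_along(x$midpoints))
    cat(sprintf("  E_m%d = %.1f +/- %.1f mV vs NHE (weight %.2f)\n",
                i, x$midpoints[i], x$midpoint_se[i], x$weights[i]))
  if (!is.na(x$delta_em))
    cat(sprintf("  dE_m = %.1f mV\n", x$delta_em))
  cat(sprintf("  residual RMS %.4f\n", x$residual_rms))
  invisible(x)
}

#' Morrison tight-binding bound fraction
#'
#' Fraction of sites occupied when ligand depletion is significant (the
#' quadratic solution of the binding equilibrium, required when K_D is
#' comparable to or below the site concentration):
#' \deqn{\theta = \frac{P + L + K_D - \sqrt{(P + L + K_D)^2 - 4 P L}}{2P}}
#'
#' @param site_conc Total site concentration P (> 0).
#' @param ligand_conc Total ligand concentration L (>= 0); vectorised.
#' @param kd Dissociation constant (> 0). All three in the same units.
#' @return Bound fraction in \[0, 1\].
#' @export
morrison_bound_fraction <- function(site_conc, ligand_conc, kd) {
  if (site_conc <= 0 || kd <= 0 || any(ligand_conc < 0))
    stop("morrison_bound_fraction: need P > 0, Kd > 0, L >= 0", call. = FALSE)
  s <- site_conc + ligand_conc + kd
  (s - sqrt(pmax(s^2 - 4 * site_conc * ligand_conc, 0))) / (2 * site_conc)
}

#' Fit a tight-binding isotherm
#'
#' Least-squares fit of the Morrison bound fraction to titration data with a
#' linear signal model (scale and offset as nuisance parameters). K_D is
#' fitted on the log scale; a profile-likelihood confidence interval is
#' computed, and a fit whose profile remains flat toward K_D = 0 (the
#' affinity exceeds what the data can resolve) is reported as an upper
#' limit. Multiple binding sites are treated as independent and identical
#' (total sites = `n_sites * site_conc`).
#'
#' @param data Data frame with columns `ligand` (or `L`, `ligand_nM`) and
#'   `signal`; optional `replicate`.
#' @param site_conc Protein concentration, same units as the ligand axis.
#' @param n_sites Binding sites per protein (1, 2 or 4).
#' @return An object of class `kd_fit`: `kd`, `kd_se`, `kd_ci` (95%),
#'   `is_upper_limit`, `upper_limit`, `site_concentration`, `scale`,
#'   `offset`, `residual_rms`.
#' @export
fit_kd <- function(data, site_conc, n_sites = 1) {
  data <- as.data.frame(data)
  for (alias in c("L", "ligand_nM", "ligand_uM"))
    if (!"ligand" %in% names(data) && alias %in% names(data))
      names(data)[names(data) == alias] <- "ligand"
  stopifnot(all(c("ligand", "signal") %in% names(data)))
  if (!n_sites %in% c(1, 2, 4))
    stop("fit_kd: n_sites must be 1, 2 or 4", call. = FALSE)
  P <- n_sites * site_conc
  L <- data$ligand
  y <- data$signal

  theta_fun <- function(lnkd) morrison_bound_fraction(P, L, exp(lnkd))
  # profile RSS over ln Kd: scale/offset solve linearly for fixed Kd
  prof_rss <- function(lnkd) {
    th <- theta_fun(lnkd)
    f <- lm(y ~ th)
    sum(f$residuals^2)
  }
  lnkd_grid <- log(P) + seq(log(1e-6), log(10), length.out = 121)
  rss <- vapply(lnkd_grid, prof_rss, numeric(1))
  lnkd0 <- lnkd_grid[which.min(rss)]

  resid_fun <- function(par) {
    th <- theta_fun(par[1])
    y - (par[3] + par[2] * th)
  }
  f0 <- lm(y ~ theta_fun(lnkd0))
  fit <- minpack.lm::nls.lm(
    par = c(lnkd0, unname(coef(f0)[2]), unname(coef(f0)[1])),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  lnkd <- fit$par[1]
  kd <- exp(lnkd)
  dof <- length(y) - 3
  sigma2 <- fit$deviance / dof
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se_lnkd <- if (is.null(covm)) NA_real_ else sqrt(max(covm[1, 1], 0))

  # profile-likelihood 95% CI for ln Kd
  thresh <- fit$deviance * (1 + qf(0.95, 1, dof) / dof)
  fine <- seq(min(lnkd_grid), max(lnkd_grid), length.out = 601)
  rss_fine <- vapply(fine, prof_rss, numeric(1))
  inside <- fine[rss_fine <= thresh + 1e-12]
  if (length(inside) == 0) inside <- lnkd
  ci <- exp(range(inside))
  # flat profile down to the lower edge of the search range: the lower
  # bound is unresolved and only an upper limit can be quoted
  is_upper <- min(inside) <= min(fine) + 1e-9
  upper <- ci[2]

  structure(list(
    kd = kd, kd_se = if (is.na(se_lnkd)) NA_real_ else kd * se_lnkd,
    kd_ci = ci, se_lnkd = se_lnkd,
    is_upper_limit = is_upper, upper_limit = if (is_upper) upper else NA_real_,
    site_concentration = site_conc, n_sites = n_sites,
    scale = fit$par[2], offset = fit$par[3],
    residual_rms = sqrt(fit$deviance / length(y)),
    data = data),
    class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (x$is_upper_limit) {
    cat(sprintf("Tight-binding fit: K_D < %.3g (upper limit; affinity below data resolution)\n",
                x$upper_limit))
  } else {
    cat(sprintf("Tight-binding fit: K_D = %.3g +/- %.3g (95%% CI %.3g-%.3g)\n",
                x$kd, x$kd_se, x$kd_ci[1], x$kd_ci[2]))
  }
  cat(sprintf("  sites %.3g (x%d), scale %.3f, offset %.3f, residual RMS %.4f\n",
              x$site_concentration, x$n_sites, x$scale, x$offset,
              x$residual_rms))
  invisible(x)
}
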