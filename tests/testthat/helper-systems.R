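# Shared fixtures, built in code at test time.

# Single redox site (a heme Fe charge center at the origin).
make_single_heme_system <- function(em = -118, model = interaction_model()) {
  site_system(list(titratable_site("heme1", "redox", em, c(0, 0, 0))), model)
}

# One heme coupled to an acid and a base at realistic protein distances.
make_three_site_system <- function(model = interaction_model()) {
  site_system(list(
    titratable_site("heme1", "redox", -118, c(0, 0, 0)),
    titratable_site("d1", "acid", 5.5, c(8, 0, 0)),
    titratable_site("k1", "base", 10.4, c(0, 9, 0))), model)
}

# Random n-site system with one guaranteed redox site; all centers at least
# 4 A apart so couplings stay in a physically sensible range.
make_random_system <- function(n, seed, model = interaction_model()) {
  stopifnot(n >= 1, n <= 20)
  set.seed(seed)
  centers <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    cand <- runif(3, -14, 14)
    if (k == 0 ||
        min(sqrt(rowSums(sweep(centers[seq_len(k), , drop = FALSE], 2,
                               cand)^2))) >= 4) {
      k <- k + 1
      centers[k, ] <- cand
    }
  }
  sites <- vector("list", n)
  sites[[1]] <- titratable_site("heme1", "redox", round(runif(1, -200, -50)),
                                centers[1, ])
  if (n > 1) for (i in 2:n) {
    kind <- sample(c("acid", "base"), 1)
    pka <- if (kind == "acid") runif(1, 4, 7) else runif(1, 9, 12)
    sites[[i]] <- titratable_site(paste0("s", i), kind, round(pka, 2),
                                  centers[i, ])
  }
  site_system(sites, model)
}

# Guard-band comparison of an MC curve against the exact oracle.
#
# Batch-mean standard errors can underestimate for rarely-flipping sites, so
# they are floored at the binomial SE computed with n_kept / n_sites
# effective samples -- a single-site-flip chain updates each site on at most
# 1/n_sites of its steps, so per-site information cannot exceed that bound --
# and at an absolute occupancy resolution of 3e-4 (occupancy differences
# below ~1e-3 are beneath both physical relevance and the
# midpoint-extraction sensitivity). Deviations are then summarised as the
# fraction exceeding 3 floored-SE and the maximum ratio. Because the SE is
# itself estimated from B batch means, deviation/SE ratios follow a
# t(B - 1) distribution, not a normal one; callers run the chains with
# B = 25 batches and apply thresholds sized from t(24) tail probabilities
# and the total comparison count (see the vignette).
mc_exact_summary <- function(mc, ex, n_kept, n_sites = ncol(ex$occupancy)) {
  p <- ex$occupancy
  floor_se <- pmax(sqrt(p * (1 - p) / (n_kept / n_sites)), 3e-4)
  se <- pmax(mc$se, floor_se)
  ratio <- abs(mc$occupancy - ex$occupancy) / se
  list(frac_over_3 = mean(ratio > 3), max_ratio = max(ratio))
}

# Minimal full-atom PDB fixture for keystone geometry: one His whose ND1 is
# 2.9 A from a Thr OG1 (with a decoy Asp OD1 further away) and one His with
# no acceptor within reach.
write_keystone_fixture <- function(path) {
  xyz <- rbind(
    c(0.0, 0.0, 0.0),    # HIS 8 ND1
    c(-1.5, 1.0, 0.0),   # HIS 8 CA (context)
    c(2.9, 0.0, 0.0),    # THR 19 OG1
    c(4.5, 0.0, 0.0),    # ASP 30 OD1
    c(4.5, 1.4, 0.0),    # ASP 30 OD2
    c(50.0, 0.0, 0.0),   # HIS 90 ND1 (isolated)
    c(48.5, 1.0, 0.0))   # HIS 90 CA
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    type = rep("ATOM", 7),
    resno = c(8, 8, 19, 30, 30, 90, 90),
    resid = c("HIS", "HIS", "THR", "ASP", "ASP", "HIS", "HIS"),
    elety = c("ND1", "CA", "OG1", "OD1", "OD2", "ND1", "CA"),
    chain = rep("A", 7),
    elesy = c("N", "C", "O", "O", "O", "N", "C"))
  invisible(path)
}
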