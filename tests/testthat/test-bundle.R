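test_that("base helix sequence carries the designed motif positions", {
  s <- base_helix_sequence()
  expect_identical(nchar(s), 25L)
  expect_identical(substr(s, 8, 8), "H")
  expect_identical(substr(s, 19, 19), "T")
  expect_false(grepl("H", base_helix_sequence(packing = TRUE)))
})

test_that("helix_spec enforces register consistency", {
  expect_error(helix_spec("LEEL", heptad_register = "abc"), "lengths differ")
  expect_error(helix_spec("LEEL", heptad_register = "abcz"), "a-g")
  # His at positions 1 and 9 fall on different heptad positions
  expect_error(helix_spec("HEELLRQKHEELAKQ"), "different heptad")
  sp <- helix_spec(base_helix_sequence())
  expect_s3_class(sp, "helix_spec")
})

test_that("splicing obeys the length and histidine-registry rules", {
  sp <- splice_helix(base_helix_sequence(), 2, junction_trim = 2)
  expect_identical(nchar(sp$sequence), 46L)
  his <- which(strsplit(sp$sequence, "")[[1]] == "H")
  expect_identical(diff(his), 21L)  # three heptads

  sp3 <- splice_helix(base_helix_sequence(), 3, junction_trim = 2)
  expect_identical(nchar(sp3$sequence), 3L * 25L - 2L * 2L * 2L)
  expect_identical(diff(which(strsplit(sp3$sequence, "")[[1]] == "H")),
                   c(21L, 21L))

  expect_identical(splice_helix(base_helix_sequence(), 1)$sequence,
                   base_helix_sequence())
  # trim 1 gives a 23-residue repeat period: breaks the heptad registry
  expect_error(splice_helix(base_helix_sequence(), 2, junction_trim = 1),
               "registry")
  expect_error(splice_helix("LEEL", 2), "25 residues")
})

test_that("assemble_bundle builds the antiparallel lattice and residue map", {
  sp <- helix_spec(base_helix_sequence())
  b <- assemble_bundle(list(sp, sp, sp, sp))
  expect_s3_class(b, "bundle_model")
  map <- b$residue_map
  # 4 x 25 helix residues + loops of 3/5/3 = 111 global positions
  expect_identical(nrow(map), 111L)
  expect_identical(map$global, 1:111)
  expect_identical(map$global[map$helix == 4 & !is.na(map$helix)], 87:111)
  expect_true(all(is.na(map$helix[map$global %in% c(26:28, 54:58, 84:86)])))
  # helices sit at 90-degree phases: centroids of opposing helices cancel
  cents <- t(vapply(b$helices, function(h) colMeans(h$xyz), numeric(3)))
  expect_equal(unname(cents[1, 1:2] + cents[3, 1:2]), c(0, 0),
               tolerance = 1e-9)
  expect_equal(unname(cents[2, 1:2] + cents[4, 1:2]), c(0, 0),
               tolerance = 1e-9)

  expect_error(assemble_bundle(list(sp, sp, sp)), "four helix_spec")
  expect_error(assemble_bundle(list(sp, sp, sp, sp),
                               topology = c(1, 1, -1, -1)), "alternate")
  short <- helix_spec(substr(base_helix_sequence(), 1, 21))
  expect_error(assemble_bundle(list(sp, sp, sp, short)), "mismatched")
})

test_that("place_hemes produces bis-His geometry within specification", {
  d <- design_bundle("4D2")
  expect_length(d$hemes, 2)
  for (hm in d$hemes) {
    fe <- hm$fe_position
    # Fe-N(epsilon) model distances exactly 2.1 A on both sides
    dne <- apply(hm$ne_model, 1, function(p) sqrt(sum((p - fe)^2)))
    expect_equal(unname(dne), c(2.1, 2.1), tolerance = 1e-9)
    # Fe at the midpoint of the two ligating C-alphas
    ca <- t(vapply(hm$ligating, function(p)
      d$bundle$helices[[p[1]]]$xyz[p[2], ], numeric(3)))
    expect_equal(fe, unname(colMeans(ca)), tolerance = 1e-9)
    # inter-His axis is the heme normal and is perpendicular to the bundle
    # axis, so the heme plane contains z
    u <- (ca[2, ] - ca[1, ]) / sqrt(sum((ca[2, ] - ca[1, ])^2))
    expect_lt(abs(u[3]), 1e-6)
    # conjugated atoms are coplanar with normal u
    dev <- (hm$conjugated - matrix(fe, nrow(hm$conjugated), 3,
                                   byrow = TRUE)) %*% u
    expect_lt(max(abs(dev)), 1e-9)
  }
  expect_identical(sort(rownames(d$hemes[[1]]$conjugated)),
                   sort(heme_conjugated_atoms()))
  expect_length(heme_conjugated_atoms(), 28)

  # designated residues must be histidine and at matching registry
  expect_error(place_hemes(d$bundle, list(list(c(1, 9), c(3, 9)))),
               "not histidine")
  e <- design_bundle("e4D2")
  expect_error(place_hemes(e$bundle, list(list(c(1, 8), c(3, 29)))),
               "registry")
})

test_that("heme_site rejects Fe displaced from the pyrrole cage", {
  d <- design_bundle("m4D2")
  hm <- d$hemes[[1]]
  expect_error(heme_site(hm$fe_position + c(1, 0, 0), hm$conjugated),
               "centroid")
  expect_error(heme_site(hm$fe_position, hm$conjugated[0, , drop = FALSE]),
               "non-empty")
})

test_that("the three reference designs have the expected composition", {
  m <- design_bundle("m4D2")
  expect_length(m$hemes, 1)
  expect_false(grepl("H", m$bundle$helices[[1]]$spec$sequence))
  expect_true(grepl("H", m$bundle$helices[[2]]$spec$sequence))

  d <- design_bundle("4D2")
  expect_length(d$hemes, 2)
  expect_identical(nrow(d$bundle$helices[[1]]$xyz), 25L)

  e <- design_bundle("e4D2")
  expect_length(e$hemes, 4)
  expect_identical(nrow(e$bundle$helices[[1]]$xyz), 46L)
  # heme chain runs bottom-to-top with roughly uniform spacing
  z <- vapply(e$hemes, function(h) h$fe_position[3], numeric(1))
  expect_true(all(diff(z) > 0))
  expect_lt(diff(range(diff(z))), 3)
})

test_that("design geometry matches the measured family dimensions", {
  d <- design_bundle("4D2")
  # diheme edge-to-edge in the 6 +/- 1 A window
  expect_gt(edge_to_edge(d$hemes[[1]], d$hemes[[2]]), 5)
  expect_lt(edge_to_edge(d$hemes[[1]], d$hemes[[2]]), 7)

  e <- design_bundle("e4D2")
  expect_gt(chain_span(e$hemes), 48)
  expect_lt(chain_span(e$hemes), 60)
  expect_gt(bundle_span(e$bundle), 65)
  # every adjacent pair transfers at >= 10^8 /s at the default driving force
  expect_true(all(chain_rates(e$hemes)$log10k >= 8))
})
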