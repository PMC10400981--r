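#' Helix specification
#'
#' A sequence plus heptad register plus starting Crick parameters. Any
#' heme-ligating histidines must occupy the same heptad position so that a
#' bis-His pair can form across the bundle core.
#'
#' @param sequence One-letter amino-acid string.
#' @param heptad_register String over \{a..g\} of the same length; if `NULL`,
#'   an `a`-starting register is assigned.
#' @param start_params A [crick_params()] object (default parameters if
#'   `NULL`).
#'
#' @return An object of class `helix_spec`.
#' @export
helix_spec <- function(sequence, heptad_register = NULL, start_params = NULL) {
  sequence <- toupper(sequence)
  nres <- nchar(sequence)
  if (is.null(heptad_register))
    heptad_register <- default_register(nres)
  if (nchar(heptad_register) != nres)
    stop("helix_spec: sequence and heptad_register lengths differ",
         call. = FALSE)
  if (!grepl("^[a-g]+$", heptad_register))
    stop("helix_spec: heptad_register must use letters a-g", call. = FALSE)
  if (is.null(start_params)) start_params <- crick_params()
  his <- his_positions(sequence)
  if (length(his) > 1) {
    reg <- substring(heptad_register, his, his)
    if (length(unique(reg)) > 1)
      stop(sprintf(paste0("helix_spec: histidines at positions %s occupy ",
                          "different heptad positions (%s)"),
                   paste(his, collapse = ", "),
                   paste(reg, collapse = ", ")), call. = FALSE)
  }
  structure(list(sequence = sequence, heptad_register = heptad_register,
                 start_params = start_params),
            class = "helix_spec")
}

default_register <- function(n, start = "a") {
  offs <- match(start, letters[1:7]) - 1
  paste(letters[1:7][((seq_len(n) - 1 + offs) %% 7) + 1], collapse = "")
}

his_positions <- function(sequence) {
  which(strsplit(sequence, "")[[1]] == "H")
}

#' Reference 25-residue maquette helix sequence
#'
#' An idealised, synthetic 25-residue helix in the style of the diheme
#' maquette family: heptad register starting at `a`, a core-facing
#' heme-ligating histidine at position 8 (heptad `a`), the keystone
#' threonine at position 19, a propionate-pairing arginine at position 6
#' and a core methionine at position 23. This is a package-internal
#' idealisation, not a published sequence.
#'
#' @param packing If `TRUE`, return the packing-module variant in which the
#'   ligating histidine is replaced by leucine (used for monoheme designs).
#' @return A 25-character string.
#' @export
base_helix_sequence <- function(packing = FALSE) {
  s <- "LEELLRQHEELAKQLEELTKQLMEF"
  if (packing) s <- sub("H", "L", s, fixed = TRUE)
  s
}

#' Splice repeats of a helix into an extended helix
#'
#' Extends a 25-residue maquette helix by sequence repetition, removing
#' `junction_trim` residues from each side of every junction so that
#' equivalent histidines are separated by an integral number of heptads
#' (21 residues for the default trim of 2, i.e. three heptad cycles).
#'
#' @param base_sequence 25-residue string containing the ligating histidine.
#' @param n_repeats Number of sequence repeats (>= 1).
#' @param junction_trim Residues removed from each side of each junction
#'   (default 2).
#' @param start_params Optional [crick_params()] for the resulting spec.
#'
#' @return A [helix_spec()] of length
#'   `n_repeats * 25 - 2 * junction_trim * (n_repeats - 1)`.
#' @export
splice_helix <- function(base_sequence, n_repeats, junction_trim = 2,
                         start_params = NULL) {
  base_sequence <- toupper(base_sequence)
  if (nchar(base_sequence) != 25)
    stop("splice_helix: base_sequence must be 25 residues", call. = FALSE)
  if (n_repeats < 1) stop("splice_helix: n_repeats must be >= 1", call. = FALSE)
  n_repeats <- as.integer(n_repeats)
  junction_trim <- as.integer(junction_trim)

  if (n_repeats == 1) {
    seq_out <- base_sequence
  } else {
    period <- 25 - 2 * junction_trim
    pieces <- character(n_repeats)
    pieces[1] <- substr(base_sequence, 1, 25 - junction_trim)
    if (n_repeats > 2)
      for (k in 2:(n_repeats - 1))
        pieces[k] <- substr(base_sequence, junction_trim + 1,
                            25 - junction_trim)
    pieces[n_repeats] <- substr(base_sequence, junction_trim + 1, 25)
    seq_out <- paste(pieces, collapse = "")
    his <- his_positions(seq_out)
    if (length(his) > 1 && any(diff(his) %% 7 != 0))
      stop(sprintf(paste0("splice_helix: histidine registry violated with ",
                          "junction_trim = %d; His at positions %s are not ",
                          "separated by a multiple of 7 (repeat period %d)"),
                   junction_trim, paste(his, collapse = ", "), period),
           call. = FALSE)
  }
  helix_spec(seq_out, default_register(nchar(seq_out)), start_params)
}

#' Assemble an antiparallel four-helix bundle
#'
#' Places four equal-length helices on the superhelical lattice with phases
#' 0/90/180/270 deg and alternating up/down orientation (pseudo-D2
#' arrangement). Loop sequences are carried as annotations only; loop
#' coordinates are not modelled. The bundle axis is z; helix 1 defines the
#' x phase.
#'
#' @param helix_specs List of four [helix_spec()] objects of equal length.
#' @param loop_set Character vector of three loop sequences joining helices
#'   1-2, 2-3 and 3-4 (default `c("TSN", "GSVSP", "TSN")`).
#' @param topology Orientation flags per helix, `+1` up / `-1` down; must
#'   alternate (default `c(1, -1, 1, -1)`).
#'
#' @return An object of class `bundle_model` with per-helix C-alpha
#'   coordinates, the loop annotations, topology and a global residue map.
#' @export
assemble_bundle <- function(helix_specs,
                            loop_set = c("TSN", "GSVSP", "TSN"),
                            topology = c(1, -1, 1, -1)) {
  if (length(helix_specs) != 4 ||
      !all(vapply(helix_specs, inherits, logical(1), "helix_spec")))
    stop("assemble_bundle: need a list of four helix_spec objects",
         call. = FALSE)
  lens <- vapply(helix_specs, function(s) nchar(s$sequence), integer(1))
  if (length(unique(lens)) != 1)
    stop(sprintf("assemble_bundle: mismatched helix lengths (%s)",
                 paste(lens, collapse = ", ")), call. = FALSE)
  if (length(topology) != 4 || any(abs(topology) != 1) ||
      any(topology[-1] * topology[-4] != -1))
    stop("assemble_bundle: topology must alternate up/down (e.g. 1,-1,1,-1)",
         call. = FALSE)
  if (length(loop_set) != 3)
    stop("assemble_bundle: loop_set must contain three loop sequences",
         call. = FALSE)

  n <- lens[1]
  helices <- vector("list", 4)
  for (i in 1:4) {
    p <- helix_specs[[i]]$start_params
    xyz <- crick_coords(p, n)
    if (topology[i] < 0) {
      # proper rotation by 180 deg about x: antiparallel partner
      xyz[, 2] <- -xyz[, 2]
      xyz[, 3] <- -xyz[, 3]
      xyz[, 3] <- xyz[, 3] - min(xyz[, 3])  # restore z range [0, span]
    }
    phase <- (i - 1) * 90 * pi / 180
    rot <- matrix(c(cos(phase), sin(phase), 0,
                    -sin(phase), cos(phase), 0,
                    0, 0, 1), 3, 3)
    xyz <- xyz %*% rot  # rotate about z by the helix phase
    colnames(xyz) <- c("x", "y", "z")
    helices[[i]] <- list(spec = helix_specs[[i]], xyz = xyz)
  }

  # global residue numbering: helix1, loop1, helix2, loop2, helix3, loop3, helix4
  map <- data.frame(global = integer(0), helix = integer(0),
                    pos = integer(0), aa = character(0))
  g <- 0L
  for (i in 1:4) {
    aa <- strsplit(helix_specs[[i]]$sequence, "")[[1]]
    map <- rbind(map, data.frame(global = g + seq_len(n), helix = i,
                                 pos = seq_len(n), aa = aa))
    g <- g + n
    if (i < 4) {
      la <- strsplit(toupper(loop_set[i]), "")[[1]]
      map <- rbind(map, data.frame(global = g + seq_along(la),
                                   helix = NA_integer_, pos = NA_integer_,
                                   aa = la))
      g <- g + length(la)
    }
  }

  structure(list(helices = helices, loops = loop_set, topology = topology,
                 residue_map = map),
            class = "bundle_model")
}

#' @export
print.bundle_model <- function(x, ...) {
  n <- nrow(x$helices[[1]]$xyz)
  cat(sprintf("Four-helix bundle model: 4 x %d residues, loops %s\n",
              n, paste(x$loops, collapse = "/")))
  cat(sprintf("  topology: %s; axial span %.1f A\n",
              paste(ifelse(x$topology > 0, "up", "down"), collapse = "-"),
              bundle_span(x)))
  invisible(x)
}

#' Axial C-alpha span of a bundle
#'
#' @param bundle A `bundle_model`.
#' @return Extent (Angstrom) of the C-alpha coordinates along the bundle
#'   (z) axis.
#' @export
bundle_span <- function(bundle) {
  z <- unlist(lapply(bundle$helices, function(h) h$xyz[, 3]))
  max(z) - min(z)
}

helix_ca <- function(bundle, helix, pos) {
  xyz <- bundle$helices[[helix]]$xyz
  if (pos < 1 || pos > nrow(xyz))
    stop("residue position outside helix", call. = FALSE)
  xyz[pos, ]
}

# Idealised planar heme template: conjugated set only (4 pyrrole N, 16 ring
# C, 4 meso C, 2 vinyl C pairs) plus Fe at the origin. Propionates and
# methyls are excluded from the conjugated set. 2D coordinates (a, b) in the
# heme plane, Angstrom; PDB HEM atom names (vinyls on rings B and C).
heme_template <- function() {
  m <- rbind(
    FE  = c(0, 0),
    "NA" = c(-2.052, 0),
    C1A = c(-2.866, 1.113), C2A = c(-4.238, 0.675),
    C3A = c(-4.238, -0.675), C4A = c(-2.866, -1.113),
    NB  = c(0, -2.052),
    C1B = c(-1.113, -2.866), C2B = c(-0.675, -4.238),
    C3B = c(0.675, -4.238), C4B = c(1.113, -2.866),
    CAB = c(1.35, -5.35), CBB = c(2.30, -6.20),
    NC  = c(2.052, 0),
    C1C = c(2.866, -1.113), C2C = c(4.238, -0.675),
    C3C = c(4.238, 0.675), C4C = c(2.866, 1.113),
    CAC = c(5.35, -1.35), CBC = c(6.20, -2.30),
    ND  = c(0, 2.052),
    C1D = c(1.113, 2.866), C2D = c(0.675, 4.238),
    C3D = c(-0.675, 4.238), C4D = c(-1.113, 2.866),
    CHA = c(-2.418, 2.418), CHB = c(-2.418, -2.418),
    CHC = c(2.418, -2.418), CHD = c(2.418, 2.418))
  colnames(m) <- c("a", "b")
  m
}

#' Conjugated-atom name whitelist for heme
#'
#' PDB atom names of the conjugated tetrapyrrole ring system of heme B:
#' pyrrole nitrogens, the 16 ring carbons, the 4 meso carbons and the vinyl
#' carbons. Propionate and methyl atoms and Fe are excluded.
#'
#' @return Character vector of atom names.
#' @export
heme_conjugated_atoms <- function() {
  c("NA", "NB", "NC", "ND",
    paste0("C", rep(1:4, 4), rep(c("A", "B", "C", "D"), each = 4)),
    "CHA", "CHB", "CHC", "CHD",
    "CAB", "CBB", "CAC", "CBC")
}

#' Place bis-histidine ligated heme cofactors in a bundle
#'
#' Rigid-body placement of the idealised planar heme template for each
#' histidine pair. The heme normal is the inter-His axis; Fe sits at its
#' midpoint with model N-epsilon positions 2.1 Angstrom from Fe on either
#' side (the bis-His coordination distance), and the heme plane contains
#' the bundle axis.
#'
#' @param bundle A `bundle_model`.
#' @param his_pairs List of pairs; each element is a list/matrix of two
#'   `(helix, residue)` integer vectors on opposing helices at matching
#'   registry.
#'
#' @return List of `heme_site` objects ordered as given.
#' @export
place_hemes <- function(bundle, his_pairs) {
  lapply(his_pairs, function(pair) {
    p1 <- as.integer(pair[[1]]); p2 <- as.integer(pair[[2]])
    map <- bundle$residue_map
    aa1 <- map$aa[which(map$helix == p1[1] & map$pos == p1[2])]
    aa2 <- map$aa[which(map$helix == p2[1] & map$pos == p2[2])]
    if (!identical(aa1, "H") || !identical(aa2, "H"))
      stop("place_hemes: designated ligating residues are not histidine",
           call. = FALSE)
    ca1 <- helix_ca(bundle, p1[1], p1[2])
    ca2 <- helix_ca(bundle, p2[1], p2[2])
    if (abs(ca1[3] - ca2[3]) > 2.5)
      stop("place_hemes: His pair not at matching registry (z offset > 2.5 A)",
           call. = FALSE)
    # pseudo-C-beta: C-alpha displaced 1.0 A toward the bundle axis
    # (projection of the 1.53 A C-alpha/C-beta bond for a core-facing rotamer)
    cb1 <- ca1 - c(ca1[1], ca1[2], 0) / sqrt(sum(ca1[1:2]^2)) * 1.0
    cb2 <- ca2 - c(ca2[1], ca2[2], 0) / sqrt(sum(ca2[1:2]^2)) * 1.0
    dcb <- sqrt(sum((cb1 - cb2)^2))
    if (dcb < 8 || dcb > 14)
      stop(sprintf(paste0("place_hemes: His C-beta separation %.1f A outside ",
                          "[8, 14] A; site cannot host a bis-His heme"), dcb),
           call. = FALSE)
    fe <- (ca1 + ca2) / 2
    u <- (ca2 - ca1) / sqrt(sum((ca2 - ca1)^2))  # inter-His axis = heme normal
    ne <- rbind(fe + 2.1 * u, fe - 2.1 * u)
    rownames(ne) <- c("NE2_1", "NE2_2")
    # in-plane axes: b along the bundle axis, a completing the frame
    bhat <- c(0, 0, 1) - sum(u * c(0, 0, 1)) * u
    bhat <- bhat / sqrt(sum(bhat^2))
    ahat <- c(u[2] * bhat[3] - u[3] * bhat[2],
              u[3] * bhat[1] - u[1] * bhat[3],
              u[1] * bhat[2] - u[2] * bhat[1])
    tmpl <- heme_template()
    coords <- t(apply(tmpl, 1, function(ab) fe + ab[1] * ahat + ab[2] * bhat))
    colnames(coords) <- c("x", "y", "z")
    heme_site(fe_position = coords["FE", ],
              conjugated = coords[heme_conjugated_atoms(), ],
              ne_model = ne,
              ligating = list(p1, p2))
  })
}

#' Heme site object
#'
#' @param fe_position Fe coordinate (length-3).
#' @param conjugated Matrix of conjugated heavy-atom coordinates with atom
#'   names as rownames.
#' @param ne_model Optional 2 x 3 matrix of (model) ligating N-epsilon
#'   positions.
#' @param ligating List of two `(chain/helix, residue)` references (may be
#'   `NULL` when unknown).
#' @param redox_state `"oxidized"` or `"reduced"`.
#'
#' @return An object of class `heme_site`.
#' @export
heme_site <- function(fe_position, conjugated, ne_model = NULL,
                      ligating = NULL, redox_state = "oxidized") {
  conjugated <- as.matrix(conjugated)
  if (nrow(conjugated) < 1)
    stop("heme_site: conjugated atom set must be non-empty", call. = FALSE)
  nn <- rownames(conjugated) %in% c("NA", "NB", "NC", "ND")
  if (sum(nn) == 4) {
    cen <- colMeans(conjugated[nn, , drop = FALSE])
    if (sqrt(sum((cen - fe_position)^2)) > 0.5)
      stop("heme_site: Fe more than 0.5 A from the pyrrole N4 centroid",
           call. = FALSE)
  }
  structure(list(fe_position = as.numeric(fe_position),
                 conjugated = conjugated, ne_model = ne_model,
                 ligating = ligating, redox_state = redox_state),
            class = "heme_site")
}

#' @export
print.heme_site <- function(x, ...) {
  cat(sprintf("Heme site: Fe at (%.2f, %.2f, %.2f), %d conjugated atoms, %s\n",
              x$fe_position[1], x$fe_position[2], x$fe_position[3],
              nrow(x$conjugated), x$redox_state))
  if (!is.null(x$ligating))
    cat(sprintf("  bis-His ligation: %s\n",
                paste(vapply(x$ligating, function(p)
                  paste(p, collapse = ":"), character(1)), collapse = ", ")))
  invisible(x)
}

#' Build a maquette design (bundle plus hemes)
#'
#' Convenience constructor for the three reference designs of the family:
#' the diheme bundle (`"4D2"`), its monoheme derivative (`"m4D2"`, two
#' packing helices with the histidine removed) and the extended tetraheme
#' molecular wire (`"e4D2"`, helices spliced from two 25-residue repeats).
#'
#' @param design One of `"4D2"`, `"m4D2"`, `"e4D2"`.
#' @param params Optional [crick_params()] used for all helices.
#'
#' @return A list of class `maquette_design` with elements `bundle`,
#'   `hemes` (list of `heme_site`), `his_pairs` and `design`.
#' @export
design_bundle <- function(design = c("4D2", "m4D2", "e4D2"), params = NULL) {
  design <- match.arg(design)
  if (is.null(params)) params <- crick_params()
  base <- base_helix_sequence()
  pack <- base_helix_sequence(packing = TRUE)
  if (design == "4D2") {
    specs <- lapply(1:4, function(i) helix_spec(base, start_params = params))
    pairs <- list(list(c(1, 8), c(3, 8)), list(c(2, 8), c(4, 8)))
  } else if (design == "m4D2") {
    specs <- list(helix_spec(pack, start_params = params),
                  helix_spec(base, start_params = params),
                  helix_spec(pack, start_params = params),
                  helix_spec(base, start_params = params))
    pairs <- list(list(c(2, 8), c(4, 8)))
  } else {
    sp <- splice_helix(base, n_repeats = 2, junction_trim = 2,
                       start_params = params)
    specs <- lapply(1:4, function(i) sp)
    pairs <- list(list(c(1, 8), c(3, 8)),   # z ~ 7 rises
                  list(c(2, 29), c(4, 29)), # z ~ 17 rises
                  list(c(1, 29), c(3, 29)), # z ~ 28 rises
                  list(c(2, 8), c(4, 8)))   # z ~ 38 rises
  }
  bundle <- assemble_bundle(specs)
  hemes <- place_hemes(bundle, pairs)
  structure(list(bundle = bundle, hemes = hemes, his_pairs = pairs,
                 design = design),
            class = "maquette_design")
}

#' @export
print.maquette_design <- function(x, ...) {
  cat(sprintf("Maquette design %s: %d heme(s)\n", x$design, length(x$hemes)))
  print(x$bundle)
  invisible(x)
}
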