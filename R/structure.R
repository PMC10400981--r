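#' Write a maquette model to PDB
#'
#' Writes the C-alpha bundle model as ATOM records (chains A-D, residue
#' numbers following the global numbering that includes the loop
#' annotations) and each heme as a HETATM residue named `HEM` (Fe plus the
#' conjugated atom set of the idealised template). Model N-epsilon positions
#' of the ligating histidines are written as `NE2` pseudo-atoms so that
#' bis-His ligation is recoverable on re-reading.
#'
#' @param design A `maquette_design` from [design_bundle()], or a
#'   `bundle_model` (then `hemes` must be given).
#' @param file Output PDB path.
#' @param hemes Optional list of `heme_site` objects when `design` is a bare
#'   `bundle_model`.
#' @return Invisibly, the file path.
#' @export
write_structure <- function(design, file, hemes = NULL) {
  if (inherits(design, "maquette_design")) {
    bundle <- design$bundle
    hemes <- design$hemes
  } else {
    bundle <- design
    if (is.null(hemes)) hemes <- list()
  }
  map <- bundle$residue_map
  chains <- c("A", "B", "C", "D")

  xyz <- NULL
  type <- resno <- resid <- elety <- chain <- elesy <- character(0)
  for (i in 1:4) {
    h <- bundle$helices[[i]]
    sub <- map[!is.na(map$helix) & map$helix == i, ]
    aa3 <- bio3d::aa123(sub$aa)
    for (k in seq_len(nrow(h$xyz))) {
      xyz <- rbind(xyz, h$xyz[k, ])
      type <- c(type, "ATOM"); resno <- c(resno, sub$global[k])
      resid <- c(resid, aa3[k]); elety <- c(elety, "CA")
      chain <- c(chain, chains[i]); elesy <- c(elesy, "C")
    }
  }
  # NE2 pseudo-atoms of ligating histidines
  for (hm in hemes) {
    if (is.null(hm$ne_model) || is.null(hm$ligating)) next
    for (j in 1:2) {
      ref <- hm$ligating[[j]]
      ca <- helix_ca(bundle, ref[1], ref[2])
      d <- apply(hm$ne_model, 1, function(p) sqrt(sum((p - ca)^2)))
      ne <- hm$ne_model[which.min(d), ]
      glob <- map$global[!is.na(map$helix) & map$helix == ref[1] &
                           map$pos == ref[2]]
      xyz <- rbind(xyz, ne)
      type <- c(type, "ATOM"); resno <- c(resno, glob)
      resid <- c(resid, "HIS"); elety <- c(elety, "NE2")
      chain <- c(chain, chains[ref[1]]); elesy <- c(elesy, "N")
    }
  }
  # hemes as HETATM
  for (j in seq_along(hemes)) {
    hm <- hemes[[j]]
    atoms <- rbind(FE = hm$fe_position, hm$conjugated)
    for (k in seq_len(nrow(atoms))) {
      xyz <- rbind(xyz, atoms[k, ])
      type <- c(type, "HETATM"); resno <- c(resno, 200 + j)
      resid <- c(resid, "HEM"); elety <- c(elety, rownames(atoms)[k])
      chain <- c(chain, "E")
      elesy <- c(elesy, if (rownames(atoms)[k] == "FE") "FE" else
        substr(rownames(atoms)[k], 1, 1))
    }
  }
  bio3d::write.pdb(file = file, xyz = as.vector(t(xyz)), type = type,
                   resno = as.numeric(resno), resid = resid, elety = elety,
                   chain = chain, elesy = elesy)
  invisible(file)
}

#' Read a structure and extract heme sites
#'
#' Parses a PDB file, extracts heme cofactors (residues named `HEM` or
#' `HEC`) with the conjugated-atom whitelist of [heme_conjugated_atoms()],
#' and detects bis-His ligation by His N-epsilon atoms within 3.0 Angstrom
#' of the heme Fe. Author chain identifiers and 1-based residue numbers are
#' preserved.
#'
#' @param path PDB file path.
#' @return A list with elements `ca` (data frame of C-alpha records),
#'   `hemes` (list of `heme_site`), `ligation_complete` (logical per heme)
#'   and `pdb` (the underlying `bio3d` object). If no heme is present the
#'   heme list is empty and a warning is raised.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("read_structure: cannot parse '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA",
           c("chain", "resno", "resid", "x", "y", "z")]

  hem_rows <- at[at$resid %in% c("HEM", "HEC"), ]
  hemes <- list()
  complete <- logical(0)
  if (nrow(hem_rows) == 0) {
    warning("read_structure: no heme (HEM/HEC) residues found")
  } else {
    keys <- unique(hem_rows[, c("chain", "resno")])
    ne2 <- at[at$resid == "HIS" & at$elety == "NE2", ]
    for (k in seq_len(nrow(keys))) {
      grp <- hem_rows[hem_rows$chain == keys$chain[k] &
                        hem_rows$resno == keys$resno[k], ]
      fe_row <- grp[toupper(grp$elety) == "FE", ]
      if (nrow(fe_row) == 0) next
      fe <- as.numeric(fe_row[1, c("x", "y", "z")])
      conj <- grp[grp$elety %in% heme_conjugated_atoms(), ]
      coords <- as.matrix(conj[, c("x", "y", "z")])
      rownames(coords) <- conj$elety
      lig <- list()
      if (nrow(ne2) > 0) {
        d <- sqrt((ne2$x - fe[1])^2 + (ne2$y - fe[2])^2 + (ne2$z - fe[3])^2)
        hits <- ne2[d < 3.0, ]
        lig <- lapply(seq_len(nrow(hits)), function(i)
          c(chain = hits$chain[i], resno = hits$resno[i]))
      }
      complete <- c(complete, length(lig) >= 2)
      if (length(lig) < 2)
        warning(sprintf(
          "read_structure: heme %s:%s has incomplete bis-His ligation (%d His)",
          keys$chain[k], keys$resno[k], length(lig)))
      hemes[[length(hemes) + 1]] <- heme_site(
        fe_position = fe, conjugated = coords,
        ligating = if (length(lig)) lig else NULL)
    }
  }
  list(ca = ca, hemes = hemes, ligation_complete = complete, pdb = pdb)
}

cross_dist <- function(a, b) {
  # pairwise Euclidean distances between rows of a and rows of b
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Edge-to-edge distance between two heme conjugated systems
#'
#' Minimum pairwise heavy-atom distance between the conjugated tetrapyrrole
#' atom sets of two hemes.
#'
#' @param a,b `heme_site` objects.
#' @return Distance in Angstrom.
#' @export
edge_to_edge <- function(a, b) {
  stopifnot(inherits(a, "heme_site"), inherits(b, "heme_site"))
  min(cross_dist(a$conjugated, b$conjugated))
}

#' Span of a heme chain
#'
#' Maximum distance between conjugated atoms of the first and last heme of
#' an ordered chain; for a single heme, the diameter of its own conjugated
#' system.
#'
#' @param hemes Ordered list of `heme_site` objects (>= 1).
#' @return Length in Angstrom.
#' @export
chain_span <- function(hemes) {
  if (length(hemes) < 1) stop("chain_span: need at least one heme",
                              call. = FALSE)
  if (length(hemes) == 1)
    return(max(cross_dist(hemes[[1]]$conjugated, hemes[[1]]$conjugated)))
  max(cross_dist(hemes[[1]]$conjugated,
                 hemes[[length(hemes)]]$conjugated))
}

#' Per-pair distances and rates along a heme chain
#'
#' @param hemes Ordered list of `heme_site` objects (>= 2).
#' @param driving_force Exergonic driving force magnitude (eV), default 0.06.
#' @param lambda Reorganization energy (eV), default 0.7.
#' @return Data frame with one row per adjacent pair: `pair`, `edge_distance`
#'   (Angstrom), `log10k` and `k_s` (per second).
#' @export
chain_rates <- function(hemes, driving_force = 0.06, lambda = 0.7) {
  if (length(hemes) < 2)
    stop("chain_rates: need at least two hemes", call. = FALSE)
  n <- length(hemes) - 1
  out <- data.frame(pair = paste0(seq_len(n), "-", seq_len(n) + 1),
                    edge_distance = NA_real_, log10k = NA_real_,
                    k_s = NA_real_)
  for (i in seq_len(n)) {
    r <- edge_to_edge(hemes[[i]], hemes[[i + 1]])
    kt <- ket(r, driving_force, lambda)
    out$edge_distance[i] <- r
    out$log10k[i] <- kt$log10k
    out$k_s[i] <- kt$k
  }
  out
}

#' Keystone hydrogen-bond distances
#'
#' For each histidine in a full-atom structure, the distance from the His
#' N-delta (ND1) to the nearest threonine OG1 or aspartate OD1/OD2
#' side-chain oxygen within `cutoff` Angstrom. C-alpha-only models carry no
#' side-chain atoms and raise a capability error.
#'
#' @param x A `bio3d` pdb object, a path to a PDB file, or the list returned
#'   by [read_structure()].
#' @param cutoff Search radius in Angstrom (default 5).
#' @return Data frame with columns `his_chain`, `his_resno`,
#'   `partner_resid`, `partner_resno`, `distance` (NA and flagged when no
#'   partner is within the cutoff).
#' @export
keystone_distances <- function(x, cutoff = 5) {
  if (is.character(x)) x <- bio3d::read.pdb(x, verbose = FALSE)
  if (is.list(x) && !is.null(x$pdb) && !inherits(x, "pdb")) x <- x$pdb
  if (!inherits(x, "pdb"))
    stop("keystone_distances: need a pdb object or file path", call. = FALSE)
  at <- x$atom
  nd1 <- at[at$resid == "HIS" & at$elety == "ND1", ]
  his_any <- at[at$resid == "HIS", ]
  if (nrow(his_any) > 0 && nrow(nd1) == 0)
    stop(paste0("keystone_distances: no His side-chain atoms present ",
                "(C-alpha-only model?); a full-atom structure is required"),
         call. = FALSE)
  acc <- at[(at$resid == "THR" & at$elety == "OG1") |
              (at$resid == "ASP" & at$elety %in% c("OD1", "OD2")), ]
  out <- data.frame(his_chain = character(0), his_resno = integer(0),
                    partner_resid = character(0), partner_resno = integer(0),
                    distance = numeric(0))
  for (i in seq_len(nrow(nd1))) {
    p <- as.numeric(nd1[i, c("x", "y", "z")])
    if (nrow(acc) > 0) {
      d <- sqrt((acc$x - p[1])^2 + (acc$y - p[2])^2 + (acc$z - p[3])^2)
      j <- which.min(d)
    }
    if (nrow(acc) > 0 && d[j] <= cutoff) {
      out <- rbind(out, data.frame(his_chain = nd1$chain[i],
                                   his_resno = nd1$resno[i],
                                   partner_resid = acc$resid[j],
                                   partner_resno = acc$resno[j],
                                   distance = d[j]))
    } else {
      out <- rbind(out, data.frame(his_chain = nd1$chain[i],
                                   his_resno = nd1$resno[i],
                                   partner_resid = NA_character_,
                                   partner_resno = NA_integer_,
                                   distance = NA_real_))
    }
  }
  out
}
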