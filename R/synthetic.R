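#' @section Synthetic complexes:
#' The synthetic-complex generator builds toy peptide-receptor complexes and
#' trajectories with planted, quantitatively known interaction structure
#' (hydrogen-bond occupancies, salt-bridge distances, per-residue fluctuation
#' amplitudes) so that every downstream analysis can be validated against
#' ground truth without a simulation engine.
#' @name synthetic
NULL

# NeRF atom placement: place D given A-B-C with bond |C-D|, angle B-C-D (deg)
# and torsion A-B-C-D (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# terminal side-chain atoms of the coarse representation: charged residues
# carry their interaction-bearing terminal atoms explicitly, everything else
# one neutral pseudo-atom in the C-beta direction (Gly none)
side_chain_spec <- function(code) {
  switch(code,
    D = list(names = c("OD1", "OD2"), element = "O", length = 3.7, split = 1.1),
    E = list(names = c("OE1", "OE2"), element = "O", length = 4.9, split = 1.1),
    K = list(names = "NZ", element = "N", length = 6.4, split = 0),
    R = list(names = c("NH1", "NH2"), element = "N", length = 7.0, split = 1.1),
    H = list(names = "NE2", element = "N", length = 4.5, split = 0),
    G = NULL,
    list(names = "CB", element = "C", length = 1.53, split = 0)
  )
}

#' Build an ideal alpha-helical peptide structure
#'
#' Places backbone N, H, CA, C, O atoms on canonical alpha-helix internal
#' coordinates (phi = -57 deg, psi = -47 deg, omega = 180 deg; rise 1.5 A per
#' residue, 3.6 residues per turn follow from these). Charged residues
#' (D/E/K/R/H) receive explicit terminal side-chain atoms (carboxylate oxygen
#' pair, NZ, NH1/NH2, NE2); all other residues except Gly get one neutral
#' pseudo-atom in the C-beta direction. The helix axis is aligned to z and
#' centred on the origin.
#'
#' @param seq A [peptide_seq()] of length >= 4.
#' @param chain Chain identifier for the peptide (default `"P"`).
#' @return A [pep_structure()] with placeholder parameters.
#' @export
build_ideal_helix <- function(seq, chain = "P") {
  if (!inherits(seq, "peptide_seq")) seq <- peptide_seq(seq)
  nres <- length(seq$residues)
  if (nres < 4) {
    abort("a helical peptide needs at least 4 residues",
          class = "coag_validation_error")
  }
  phi <- -57; psi <- -47; omega <- 180
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7

  N <- matrix(0, nres, 3); CA <- matrix(0, nres, 3); C <- matrix(0, nres, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_nca, 0, 0)
  ang <- a_ncac * pi / 180
  C[1, ] <- CA[1, ] + b_cac * c(-cos(ang), sin(ang), 0)
  for (i in 2:nres) {
    N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_cn, a_cacn, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], b_nca, a_cnca, omega)
    C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ], b_cac, a_ncac, phi)
  }
  O <- matrix(0, nres, 3); Hn <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi + 180)
    if (i > 1) {
      # amide H in the peptide plane, cis to the previous CA (trans to O)
      Hn[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.010, 119.2, 0)
    }
  }
  Hn[1, ] <- N[1, ] + 1.01 * unit(N[1, ] - (CA[1, ] + C[1, ]) / 2)

  rows <- list(); coords <- list()
  add <- function(name, elem, i) {
    rows[[length(rows) + 1]] <<- tibble(
      atom_name = name, element = elem, resno = i,
      resname = unname(AA3[seq$residues[i]]), chain = chain)
  }
  for (i in seq_len(nres)) {
    add("N", "N", i);  coords[[length(coords) + 1]] <- N[i, ]
    add("H", "H", i);  coords[[length(coords) + 1]] <- Hn[i, ]
    add("CA", "C", i); coords[[length(coords) + 1]] <- CA[i, ]
    add("C", "C", i);  coords[[length(coords) + 1]] <- C[i, ]
    add("O", "O", i);  coords[[length(coords) + 1]] <- O[i, ]
    sc <- side_chain_spec(seq$residues[i])
    if (!is.null(sc)) {
      # C-beta direction from the local backbone frame
      b <- CA[i, ] - N[i, ]; cvec <- C[i, ] - CA[i, ]
      avec <- pracma_cross(b, cvec)
      cb_dir <- unit(-0.58273431 * avec + 0.56802827 * b - 0.54067466 * cvec)
      perp <- unit(pracma_cross(cb_dir, cvec))
      for (k in seq_along(sc$names)) {
        off <- if (length(sc$names) == 2) (k - 1.5) * sc$split else 0
        add(sc$names[k], sc$element, i)
        coords[[length(coords) + 1]] <-
          CA[i, ] + sc$length * cb_dir + off * perp
      }
    }
  }
  atoms <- bind_rows(rows)
  xyz <- do.call(rbind, coords)
  # align the helix axis (principal axis of CA trace) to z, centre on origin
  cam <- CA
  cam_c <- scale(cam, scale = FALSE)
  axis <- svd(cam_c)$v[, 1]
  rot <- rotation_to_z(axis)
  xyz <- (xyz - matrix(colMeans(cam), nrow(xyz), 3, byrow = TRUE)) %*% t(rot)
  pep_structure(atoms, xyz)
}

rotation_to_z <- function(v) {
  v <- unit(v)
  z <- c(0, 0, 1)
  if (abs(sum(v * z)) > 1 - 1e-9) return(diag(3))
  ax <- unit(pracma_cross(v, z))
  ang <- acos(sum(v * z))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Build a toy receptor pocket around the z axis
#'
#' Places pocket residues on a ring (cylinder) of given radius around the
#' z axis, side chains pointing inward so they can reach a helical peptide
#' built by [build_ideal_helix()]. This is deliberately not a receptor fold:
#' it provides labelled, charge-bearing interaction sites at controlled
#' positions for planting contacts.
#'
#' @param n_pocket_residues Number of pocket residues (ignored when
#'   `residues` is given).
#' @param residues Optional named character vector of one-letter codes; names
#'   are residue numbers (e.g. `c("146" = "R", "225" = "D")`). Defaults to
#'   `n_pocket_residues` residues cycling D,K,S,E,R,Q numbered from 1.
#' @param annotation Optional [receptor_annotation()]; stored as an attribute.
#' @param radius Ring radius, Angstrom.
#' @param z_span Vertical extent of the ring, Angstrom.
#' @param chain Chain identifier (default `"R"`).
#' @return A [pep_structure()].
#' @export
build_toy_receptor <- function(n_pocket_residues = 12, residues = NULL,
                               annotation = NULL, radius = 12,
                               z_span = 20, chain = "R") {
  if (is.null(residues)) {
    if (n_pocket_residues < 1) {
      abort("need at least one pocket residue", class = "coag_validation_error")
    }
    codes <- rep(c("D", "K", "S", "E", "R", "Q"),
                 length.out = n_pocket_residues)
    residues <- setNames(codes, as.character(seq_len(n_pocket_residues)))
  }
  if (length(residues) < 1) {
    abort("need at least one pocket residue", class = "coag_validation_error")
  }
  resno <- as.integer(names(residues))
  nres <- length(residues)
  theta <- 2 * pi * (seq_len(nres) - 1) / nres
  zpos <- seq(-z_span / 2, z_span / 2, length.out = max(nres, 2))[seq_len(nres)]
  rows <- list(); coords <- list()
  add <- function(name, elem, i, xyz) {
    rows[[length(rows) + 1]] <<- tibble(
      atom_name = name, element = elem, resno = resno[i],
      resname = unname(AA3[residues[[i]]]), chain = chain)
    coords[[length(coords) + 1]] <<- xyz
  }
  for (i in seq_len(nres)) {
    u <- c(cos(theta[i]), sin(theta[i]), 0)       # outward radial direction
    ca <- radius * u + c(0, 0, zpos[i])
    tangent <- c(-sin(theta[i]), cos(theta[i]), 0)
    add("N", "N", i, ca + 1.46 * tangent)
    add("H", "H", i, ca + 1.46 * tangent + c(0, 0, 1.01))
    add("CA", "C", i, ca)
    add("C", "C", i, ca - 1.52 * tangent)
    add("O", "O", i, ca - 1.52 * tangent + c(0, 0, 1.23))
    sc <- side_chain_spec(residues[[i]])
    if (!is.null(sc)) {
      perp <- c(0, 0, 1)
      for (k in seq_along(sc$names)) {
        off <- if (length(sc$names) == 2) (k - 1.5) * sc$split else 0
        add(sc$names[k], sc$element, i, ca - sc$length * u + off * perp)
      }
    }
  }
  out <- pep_structure(bind_rows(rows), do.call(rbind, coords))
  if (!is.null(annotation)) attr(out, "annotation") <- annotation
  out
}

#' Combine peptide and receptor structures into one complex
#'
#' @param peptide,receptor [pep_structure()] objects (distinct chains).
#' @return A [pep_structure()] with concatenated atoms.
#' @export
combine_structures <- function(peptide, receptor) {
  pep_structure(bind_rows(peptide$atoms, receptor$atoms),
                rbind(peptide$xyz, receptor$xyz))
}

#' Interaction plans for synthetic trajectories
#'
#' An interaction plan is the ground truth planted into a synthetic
#' trajectory: hydrogen-bond pairs with a per-frame Bernoulli contact
#' occupancy, salt-bridge pairs with a contact distance and occupancy, and a
#' per-residue isotropic fluctuation profile.
#'
#' @param hbonds Tibble with columns `donor_chain`, `donor_resno`,
#'   `donor_atom`, `acceptor_chain`, `acceptor_resno`, `acceptor_atom`,
#'   `occupancy` (may be empty/NULL).
#' @param saltbridges Tibble with columns `acid_chain`, `acid_resno`,
#'   `base_chain`, `base_resno`, `distance` (Angstrom), `occupancy`.
#' @param fluctuation Tibble with columns `chain`, `resno`, `sigma`
#'   (Angstrom, per coordinate), or NULL for rigid residues.
#' @param seed Integer seed; the generator is reproducible.
#' @return An `interaction_plan` object.
#' @export
interaction_plan <- function(hbonds = NULL, saltbridges = NULL,
                             fluctuation = NULL, seed = 1L) {
  hb <- if (is.null(hbonds)) tibble() else as_tibble(hbonds)
  sb <- if (is.null(saltbridges)) tibble() else as_tibble(saltbridges)
  fl <- if (is.null(fluctuation)) tibble() else as_tibble(fluctuation)
  for (tab in list(hb, sb)) {
    if (nrow(tab) && !is.null(tab$occupancy) &&
        any(tab$occupancy < 0 | tab$occupancy > 1)) {
      abort("occupancies must lie in [0, 1]", class = "coag_validation_error")
    }
  }
  if (nrow(sb) && any(sb$distance <= 0)) {
    abort("salt-bridge contact distances must be positive",
          class = "coag_validation_error")
  }
  if (nrow(fl) && any(fl$sigma < 0)) {
    abort("fluctuation sigma must be non-negative",
          class = "coag_validation_error")
  }
  structure(list(hbonds = hb, saltbridges = sb, fluctuation = fl,
                 seed = as.integer(seed)),
            class = "interaction_plan")
}

atom_row <- function(atoms, chain, resno, atom_name = NULL) {
  hit <- which(atoms$chain == chain & atoms$resno == resno &
               (if (is.null(atom_name)) TRUE else atoms$atom_name == atom_name))
  if (!length(hit)) {
    abort(sprintf("no atom %s in residue %s:%s of the complex",
                  atom_name %||% "(any)", chain, resno),
          class = "coag_validation_error")
  }
  hit
}

#' Generate a synthetic trajectory with planted interactions
#'
#' Starting from the complex coordinates, each frame places every planted
#' pair either in its contact geometry (independent Bernoulli draw with the
#' pair's target occupancy) or displaced to 8 Angstrom. Hydrogen-bond
#' contacts place the acceptor on the donor-H axis at 2.9 Angstrom from the
#' donor (so the D-H...A angle is 180 deg); salt-bridge contacts place the
#' basic nitrogen(s) so the minimum N-O distance equals the planted contact
#' distance. Every atom of residue i is then perturbed by iid isotropic
#' Gaussian noise with the profile's sigma_i. Seeded and bit-reproducible.
#'
#' @param complex A [pep_structure()] of the bound complex.
#' @param plan An [interaction_plan()].
#' @param n_frames Number of frames.
#' @param frame_interval Metadata, ps.
#' @return A [pep_trajectory()].
#' @export
generate_trajectory <- function(complex, plan, n_frames,
                                frame_interval = 2) {
  stopifnot(inherits(plan, "interaction_plan"))
  atoms <- complex$atoms
  base <- complex$xyz
  hb <- plan$hbonds; sb <- plan$saltbridges; fl <- plan$fluctuation

  # resolve atom indices up front (errors early on unknown residues)
  hb_idx <- NULL
  if (nrow(hb)) {
    hb_idx <- lapply(seq_len(nrow(hb)), function(k) {
      d <- atom_row(atoms, hb$donor_chain[k], hb$donor_resno[k],
                    hb$donor_atom[k])
      hres <- which(atoms$chain == hb$donor_chain[k] &
                    atoms$resno == hb$donor_resno[k] &
                    atoms$element == "H")
      if (!length(hres)) {
        abort(sprintf("donor %s:%d has no hydrogen in the topology",
                      hb$donor_chain[k], hb$donor_resno[k]),
              class = "coag_validation_error")
      }
      # nearest hydrogen of the donor residue
      hh <- hres[which.min(sqrt(rowSums(
        (base[hres, , drop = FALSE] -
         matrix(base[d, ], length(hres), 3, byrow = TRUE))^2)))]
      a <- atom_row(atoms, hb$acceptor_chain[k], hb$acceptor_resno[k],
                    hb$acceptor_atom[k])
      list(d = d, h = hh, a = a, occ = hb$occupancy[k])
    })
  }
  sb_idx <- NULL
  if (nrow(sb)) {
    sb_idx <- lapply(seq_len(nrow(sb)), function(k) {
      acid_res <- atom_row(atoms, sb$acid_chain[k], sb$acid_resno[k])
      o <- acid_res[atoms$atom_name[acid_res] %in% c("OD1", "OD2", "OE1", "OE2")]
      base_res <- atom_row(atoms, sb$base_chain[k], sb$base_resno[k])
      nn <- base_res[atoms$atom_name[base_res] %in% c("NZ", "NH1", "NH2", "NE2")]
      if (!length(o) || !length(nn)) {
        abort(sprintf("salt-bridge pair %s:%d / %s:%d lacks charged terminal atoms",
                      sb$acid_chain[k], sb$acid_resno[k],
                      sb$base_chain[k], sb$base_resno[k]),
              class = "coag_validation_error")
      }
      ca <- acid_res[atoms$atom_name[acid_res] == "CA"]
      anchor <- if (length(ca)) ca[1] else acid_res[1]
      list(o = o, nn = nn, anchor = anchor, dist = sb$distance[k],
           occ = sb$occupancy[k])
    })
  }
  sigma <- numeric(nrow(atoms))
  if (nrow(fl)) {
    for (k in seq_len(nrow(fl))) {
      hit <- atoms$chain == fl$chain[k] & atoms$resno == fl$resno[k]
      sigma[hit] <- fl$sigma[k]
    }
  }

  frames <- withr::with_seed(plan$seed, {
    arr <- array(0, dim = c(nrow(atoms), 3, n_frames))
    for (f in seq_len(n_frames)) {
      xyz <- base
      for (p in hb_idx %||% list()) {
        contact <- stats::runif(1) < p$occ
        u <- unit(xyz[p$h, ] - xyz[p$d, ])
        xyz[p$a, ] <- xyz[p$d, ] + (if (contact) 2.9 else 8.0) * u
      }
      for (p in sb_idx %||% list()) {
        contact <- stats::runif(1) < p$occ
        d <- if (contact) p$dist else 8.0
        o1 <- p$o[1]
        # move the basic nitrogen(s) along the acid side chain's outward
        # direction, which cannot sweep through the acid's own chain
        u <- unit(xyz[o1, ] - xyz[p$anchor, ])
        xyz[p$nn[1], ] <- xyz[o1, ] + d * u
        if (length(p$nn) > 1) {
          for (j in seq_along(p$nn)[-1]) {
            xyz[p$nn[j], ] <- xyz[o1, ] + (d + 1.5 * (j - 1)) * u
          }
        }
      }
      noisy <- sigma > 0
      if (any(noisy)) {
        xyz[noisy, ] <- xyz[noisy, ] +
          matrix(rnorm(3 * sum(noisy), sd = rep(sigma[noisy], 3)),
                 ncol = 3)
      }
      arr[, , f] <- xyz
    }
    arr
  })
  pep_trajectory(atoms, frames, frame_interval = frame_interval)
}

#' Write a synthetic fixture (multi-model PDB + ground-truth sidecar)
#'
#' @param traj A [pep_trajectory()].
#' @param plan The [interaction_plan()] that generated it.
#' @param dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return Named list of the two paths, invisibly.
#' @export
write_complex_fixture <- function(traj, plan, dir, name = "synthetic_complex") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  json_path <- file.path(dir, paste0(name, "_plan.json"))
  write_pdb(traj, pdb_path)
  jsonlite::write_json(
    list(seed = plan$seed, hbonds = plan$hbonds,
         saltbridges = plan$saltbridges, fluctuation = plan$fluctuation),
    json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(pdb = pdb_path, plan = json_path))
}
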