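#' Energetics configuration
#'
#' Parameters of the MM-GB/SA style end-point binding free energy:
#' solute/solvent relative dielectrics, the SASA nonpolar model
#' (gamma * SASA + offset), the solvent probe radius and the frame stride
#' used when averaging over a trajectory.
#'
#' @param eps_in Solute (protein) relative dielectric, default 2.
#' @param eps_out Solvent relative dielectric, default 80.
#' @param gamma_sasa Nonpolar surface coefficient, kJ/mol/A^2, default 0.0227.
#' @param sasa_offset Nonpolar model offset, kJ/mol, default 0.
#' @param probe_radius Solvent probe radius, Angstrom, default 1.4.
#' @param frame_stride Evaluate every k-th frame, default 1.
#' @param sasa_points Sphere points per atom for Shrake-Rupley, default 960.
#' @return An `energetics_config` list.
#' @export
energetics_config <- function(eps_in = 2, eps_out = 80, gamma_sasa = 0.0227,
                              sasa_offset = 0, probe_radius = 1.4,
                              frame_stride = 1, sasa_points = 960) {
  if (eps_in < 1) abort("eps_in must be >= 1", class = "coag_validation_error")
  if (eps_out <= eps_in) {
    abort("eps_out must exceed eps_in", class = "coag_validation_error")
  }
  if (gamma_sasa < 0) {
    abort("gamma_sasa must be >= 0", class = "coag_validation_error")
  }
  structure(list(eps_in = eps_in, eps_out = eps_out,
                 gamma_sasa = gamma_sasa, sasa_offset = sasa_offset,
                 probe_radius = probe_radius,
                 frame_stride = as.integer(frame_stride),
                 sasa_points = as.integer(sasa_points)),
            class = "energetics_config")
}

check_pairs <- function(pairs, n) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) {
    abort("pair set must be a 2-column matrix of atom indices",
          class = "coag_validation_error")
  }
  storage.mode(pairs) <- "integer"
  if (any(pairs < 1 | pairs > n)) {
    abort("pair indices out of range", class = "coag_validation_error")
  }
  pairs
}

pair_distances <- function(xyz, pairs) {
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                     xyz[pairs[, 2], , drop = FALSE])^2))
  if (any(d < 1e-9)) {
    abort("coincident atoms in pair set (r = 0)", class = "coag_numeric_error")
  }
  d
}

#' Coulomb energy over an atom-pair set
#'
#' Sum over pairs of f q_i q_j / (eps_in r_ij) with
#' f = 1389.35458 kJ mol^-1 A e^-2; no cutoff (interface pair sums are
#' evaluated in full).
#'
#' @param structure A `pep_structure` with charges assigned, or an xyz/charge
#'   pair via `xyz=`/`charge=` internally.
#' @param pairs Two-column matrix of atom indices.
#' @param eps_in Relative dielectric.
#' @return Scalar energy, kJ/mol.
#' @export
coulomb_energy <- function(structure, pairs, eps_in = 2) {
  pairs <- check_pairs(pairs, nrow(structure$atoms))
  d <- pair_distances(structure$xyz, pairs)
  q <- structure$atoms$charge
  sum(COULOMB_KJ * q[pairs[, 1]] * q[pairs[, 2]] / (eps_in * d))
}

#' Lennard-Jones energy over an atom-pair set
#'
#' Sum of 4 eps [(sigma/r)^12 - (sigma/r)^6] with Lorentz-Berthelot
#' combination (arithmetic sigma, geometric epsilon).
#'
#' @inheritParams coulomb_energy
#' @return Scalar energy, kJ/mol.
#' @export
lj_energy <- function(structure, pairs) {
  pairs <- check_pairs(pairs, nrow(structure$atoms))
  d <- pair_distances(structure$xyz, pairs)
  at <- structure$atoms
  sig <- (at$lj_sigma[pairs[, 1]] + at$lj_sigma[pairs[, 2]]) / 2
  eps <- sqrt(at$lj_epsilon[pairs[, 1]] * at$lj_epsilon[pairs[, 2]])
  sr6 <- (sig / d)^6
  sum(4 * eps * (sr6^2 - sr6))
}

# intrinsic (HCT) radii: element vdW radius minus the standard 0.09 A offset
intrinsic_radii <- function(atoms) {
  unname(ELEMENT_VDW[atoms$element]) - 0.09
}

#' Effective Born radii by pairwise descreening
#'
#' Hawkins-Cramer-Truhlar style pairwise descreening over intrinsic radii
#' (element van der Waals radius minus 0.09 Angstrom, scaled by `scale`).
#'
#' @param structure A `pep_structure`.
#' @param radii Optional per-atom intrinsic radii, Angstrom.
#' @param scale Descreening scale factor applied to neighbour radii.
#' @return Per-atom effective Born radii, Angstrom.
#' @export
born_radii <- function(structure, radii = NULL, scale = 0.8) {
  rho <- radii %||% intrinsic_radii(structure$atoms)
  n <- length(rho)
  if (n == 1) return(rho)
  xyz <- structure$xyz
  dmat <- pairwise_dist(xyz, xyz)
  inv_b <- 1 / rho
  for (i in seq_len(n)) {
    r <- dmat[i, -i]
    sr <- scale * rho[-i]
    keep <- r + sr > rho[i]  # neighbours not buried inside atom i
    r <- r[keep]; sr <- sr[keep]
    L <- pmax(rho[i], r - sr)
    U <- r + sr
    s <- sum(0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                      (1 / (2 * r)) * log(L / U) +
                      (sr^2 / (4 * r)) * (1 / L^2 - 1 / U^2)))
    inv_b[i] <- 1 / rho[i] - s
  }
  if (any(inv_b <= 0)) {
    abort("nonpositive effective Born radius (overlapping descreening)",
          class = "coag_numeric_error")
  }
  1 / inv_b
}

#' Generalized-Born polar solvation energy
#'
#' Still-type generalized Born:
#' `-1/2 (1/eps_in - 1/eps_out) sum_ij f q_i q_j / f_GB(r_ij, B_i, B_j)` with
#' `f_GB = sqrt(r^2 + B_i B_j exp(-r^2 / (4 B_i B_j)))`, self terms included
#' (`f_GB(0) = B_i`). Vanishes in the eps_in = eps_out limit and for
#' uncharged solutes.
#'
#' @param structure A `pep_structure` with charges assigned.
#' @param config An [energetics_config()].
#' @param radii Optional explicit intrinsic radii (Angstrom).
#' @param per_atom Return the per-atom energy vector instead of the total.
#' @return kJ/mol (scalar, or per-atom vector summing to it).
#' @export
gb_polar_energy <- function(structure, config = energetics_config(),
                            radii = NULL, per_atom = FALSE) {
  q <- structure$atoms$charge
  n <- length(q)
  tau <- 1 / config$eps_in - 1 / config$eps_out
  if (all(q == 0)) {
    return(if (per_atom) numeric(n) else 0)
  }
  B <- born_radii(structure, radii = radii)
  xyz <- structure$xyz
  r2 <- pairwise_dist(xyz, xyz)^2
  BB <- outer(B, B)
  fgb <- sqrt(r2 + BB * exp(-r2 / (4 * BB)))
  qq <- outer(q, q)
  e_atom <- -0.5 * tau * COULOMB_KJ * rowSums(qq / fgb)
  if (per_atom) e_atom else sum(e_atom)
}

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA with deterministic golden-spiral sphere points (default
#' 960 per atom) over element van der Waals radii expanded by the probe.
#'
#' @param structure A `pep_structure`.
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere points per atom (>= 960 recommended).
#' @param radii Optional explicit atomic radii (Angstrom, without probe).
#' @return Numeric vector of per-atom areas, A^2.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, radii = NULL) {
  at_r <- (radii %||% unname(ELEMENT_VDW[structure$atoms$element])) + probe
  xyz <- structure$xyz
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  dmat <- pairwise_dist(xyz, xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- which(dmat[i, ] < at_r[i] + at_r & seq_len(n) != i)
    surf <- pts * at_r[i] +
      matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    if (length(neigh)) {
      d2 <- pairwise_dist(surf, xyz[neigh, , drop = FALSE])
      # a point is buried inside a strictly covering neighbour; exact ties
      # (degenerate coincident atoms) are broken by atom order so that a
      # duplicated sphere contributes its area exactly once
      tol <- 1e-8
      buried <- matrix(FALSE, n_points, length(neigh))
      for (k in seq_along(neigh)) {
        buried[, k] <- d2[, k] < at_r[neigh[k]] - tol |
          (abs(d2[, k] - at_r[neigh[k]]) <= tol & neigh[k] < i)
      }
      frac <- mean(rowSums(buried) == 0)
    } else {
      frac <- 1
    }
    out[i] <- frac * 4 * pi * at_r[i]^2
  }
  out
}

# per-frame, per-residue interface energetics for one frame's coordinates
frame_decomposition <- function(atoms, xyz, lig, rec, cross, config,
                                rho) {
  n <- nrow(atoms)
  res_key <- paste(atoms$chain, atoms$resno, sep = ":")
  res_levels <- unique(res_key)
  res_f <- factor(res_key, levels = res_levels)

  elec_atom <- numeric(n); vdw_atom <- numeric(n)
  if (nrow(cross)) {
    d <- sqrt(rowSums((xyz[cross[, 1], , drop = FALSE] -
                       xyz[cross[, 2], , drop = FALSE])^2))
    if (any(d < 1e-9)) {
      abort("coincident interface atoms (r = 0)", class = "coag_numeric_error")
    }
    q <- atoms$charge
    e_pair <- COULOMB_KJ * q[cross[, 1]] * q[cross[, 2]] / (config$eps_in * d)
    sig <- (atoms$lj_sigma[cross[, 1]] + atoms$lj_sigma[cross[, 2]]) / 2
    eps <- sqrt(atoms$lj_epsilon[cross[, 1]] * atoms$lj_epsilon[cross[, 2]])
    sr6 <- (sig / d)^6
    v_pair <- 4 * eps * (sr6^2 - sr6)
    # half of each pair term to each partner atom
    for (col in 1:2) {
      idx <- cross[, col]
      elec_atom <- elec_atom + 0.5 * unname(tapply_add(e_pair, idx, n))
      vdw_atom <- vdw_atom + 0.5 * unname(tapply_add(v_pair, idx, n))
    }
  }

  sub_structure <- function(sel) {
    structure(list(atoms = atoms[sel, ], xyz = xyz[sel, , drop = FALSE]),
              class = "pep_structure")
  }
  cplx <- structure(list(atoms = atoms, xyz = xyz), class = "pep_structure")
  gb_c <- gb_polar_energy(cplx, config, radii = rho, per_atom = TRUE)
  gb_l <- gb_polar_energy(sub_structure(lig), config, radii = rho[lig],
                          per_atom = TRUE)
  gb_r <- gb_polar_energy(sub_structure(rec), config, radii = rho[rec],
                          per_atom = TRUE)
  polar_atom <- gb_c
  polar_atom[lig] <- polar_atom[lig] - gb_l
  polar_atom[rec] <- polar_atom[rec] - gb_r

  sasa_c <- sasa(cplx, probe = config$probe_radius,
                 n_points = config$sasa_points)
  sasa_l <- sasa(sub_structure(lig), probe = config$probe_radius,
                 n_points = config$sasa_points)
  sasa_r <- sasa(sub_structure(rec), probe = config$probe_radius,
                 n_points = config$sasa_points)
  d_sasa <- sasa_c
  d_sasa[lig] <- d_sasa[lig] - sasa_l
  d_sasa[rec] <- d_sasa[rec] - sasa_r
  nonpolar_atom <- config$gamma_sasa * d_sasa
  # the offset enters each state once: complex - receptor - ligand = -offset,
  # spread evenly over residues to keep the decomposition conservative
  offset_net <- -config$sasa_offset

  per_res <- tibble(key = res_key, elec = elec_atom, vdw = vdw_atom,
                    polar = polar_atom, nonpolar = nonpolar_atom) |>
    group_by(.data$key) |>
    summarise(across(c("elec", "vdw", "polar", "nonpolar"), sum),
              .groups = "drop")
  per_res <- per_res[match(res_levels, per_res$key), ]
  per_res$nonpolar <- per_res$nonpolar + offset_net / nrow(per_res)
  per_res
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- tapply(vals, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Per-residue MM-GB/SA binding free energy decomposition
#'
#' Single-trajectory end-point estimate: on every (strided) frame, each
#' component's difference complex - receptor - ligand is evaluated on the
#' same coordinates. The molecular-mechanics electrostatic and van der Waals
#' differences reduce to interface (cross-pair) sums, split half/half between
#' the partner residues; the generalized-Born polar and SASA nonpolar
#' differences are computed per atom and summed per residue. Components are
#' averaged over frames. No entropy term.
#'
#' @param traj A `pep_trajectory` of the bound complex, parameters assigned.
#' @param ligand_chains,receptor_chains Chain ids of the two disjoint
#'   selections (together they must cover the complex).
#' @param config An [energetics_config()].
#' @return An `energy_decomposition`: per-residue tibble (`chain`, `resno`,
#'   `resname`, `elec`, `vdw`, `polar`, `nonpolar`, `total`, kJ/mol) with a
#'   `totals` attribute and `frame_count`.
#' @export
per_residue_decomposition <- function(traj, ligand_chains = "P",
                                      receptor_chains = NULL,
                                      config = energetics_config()) {
  atoms <- traj$atoms
  receptor_chains <- receptor_chains %||%
    setdiff(unique(atoms$chain), ligand_chains)
  lig <- which(atoms$chain %in% ligand_chains)
  rec <- which(atoms$chain %in% receptor_chains)
  if (!length(lig) || !length(rec)) {
    abort("ligand and receptor selections must both be non-empty",
          class = "coag_validation_error")
  }
  if (length(intersect(lig, rec)) || length(lig) + length(rec) != nrow(atoms)) {
    abort("selections must be disjoint and cover the complex",
          class = "coag_validation_error")
  }
  cross <- as.matrix(expand.grid(lig, rec))
  rho <- intrinsic_radii(atoms)
  frames <- seq(1, n_frames(traj), by = config$frame_stride)
  acc <- NULL
  for (f in frames) {
    pr <- frame_decomposition(atoms, frame_xyz(traj, f), lig, rec, cross,
                              config, rho)
    if (is.null(acc)) {
      acc <- pr
    } else {
      acc$elec <- acc$elec + pr$elec; acc$vdw <- acc$vdw + pr$vdw
      acc$polar <- acc$polar + pr$polar; acc$nonpolar <- acc$nonpolar + pr$nonpolar
    }
  }
  nfr <- length(frames)
  res_tab <- residue_table(atoms)
  out <- tibble(chain = res_tab$chain, resno = res_tab$resno,
                resname = res_tab$resname,
                elec = acc$elec / nfr, vdw = acc$vdw / nfr,
                polar = acc$polar / nfr, nonpolar = acc$nonpolar / nfr)
  out$total <- out$elec + out$vdw + out$polar + out$nonpolar
  attr(out, "totals") <- c(elec = sum(out$elec), vdw = sum(out$vdw),
                           polar = sum(out$polar),
                           nonpolar = sum(out$nonpolar),
                           total = sum(out$total))
  attr(out, "frame_count") <- nfr
  attr(out, "ligand_chains") <- ligand_chains
  class(out) <- c("energy_decomposition", class(out))
  out
}

#' Binding free energy of a peptide-receptor complex
#'
#' Convenience wrapper over [per_residue_decomposition()] returning the same
#' object; use [glance()] for the component totals and [tidy()] for the
#' per-residue table.
#'
#' @inheritParams per_residue_decomposition
#' @return An `energy_decomposition`.
#' @export
binding_free_energy <- function(traj, ligand_chains = "P",
                                receptor_chains = NULL,
                                config = energetics_config()) {
  per_residue_decomposition(traj, ligand_chains, receptor_chains, config)
}

#' @method tidy energy_decomposition
#' @export
tidy.energy_decomposition <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @method glance energy_decomposition
#' @export
glance.energy_decomposition <- function(x, ...) {
  tot <- attr(x, "totals")
  tibble(elec = tot[["elec"]], vdw = tot[["vdw"]], polar = tot[["polar"]],
         nonpolar = tot[["nonpolar"]], dg_bind = tot[["total"]],
         frame_count = attr(x, "frame_count"))
}

#' @export
print.energy_decomposition <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf(
    "<energy_decomposition> dG_bind = %.2f kJ/mol over %d frame(s)\n",
    tot[["total"]], attr(x, "frame_count")))
  cat(sprintf("  elec %.2f | vdw %.2f | polar %.2f | nonpolar %.2f\n",
              tot[["elec"]], tot[["vdw"]], tot[["polar"]],
              tot[["nonpolar"]]))
  print(tidy(x))
  invisible(x)
}

#' @method autoplot energy_decomposition
#' @export
autoplot.energy_decomposition <- function(object, chain = NULL, ...) {
  dat <- tidy(object)
  if (!is.null(chain)) dat <- filter(dat, .data$chain %in% !!chain)
  dat <- tidyr::pivot_longer(dat, c("elec", "vdw", "polar", "nonpolar"),
                             names_to = "component", values_to = "energy")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$resno),
                                    y = .data$energy,
                                    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "contribution (kJ/mol)")
}

#' Per-position difference map between two decompositions
#'
#' Positions (chain:resno) present in both inputs report
#' `delta = total_a - total_b`; positions present in only one input are
#' reported with `delta = NA` (absent, not zero).
#'
#' @param a,b `energy_decomposition` objects aligned by position.
#' @return Tibble `chain`, `resno`, `total_a`, `total_b`, `delta` (kJ/mol).
#' @export
difference_map <- function(a, b) {
  ta <- select(tidy(a), "chain", "resno", total_a = "total")
  tb <- select(tidy(b), "chain", "resno", total_b = "total")
  if (!nrow(inner_join(ta, tb, by = c("chain", "resno")))) {
    abort("decompositions share no positions", class = "coag_validation_error")
  }
  out <- dplyr::full_join(ta, tb, by = c("chain", "resno"))
  out$delta <- out$total_a - out$total_b
  arrange(out, .data$chain, .data$resno)
}
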