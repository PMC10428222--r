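#' Two-dimensional free-energy surface over order parameters
#'
#' Bins the joint distribution of two per-frame order parameters (e.g. RMSD
#' vs radius of gyration, or interface interaction energy vs windowed TM6
#' RMSF), converts bin probabilities to free energies
#' `F = -kT ln(P / P_max)` (global minimum 0) and masks empty bins.
#' kT = 0.0083144621 T kJ/mol (2.478 at 298 K). No kernel smoothing.
#'
#' @param x,y Numeric vectors of equal length, or `metric_series` tibbles.
#' @param bins Bin counts `c(nx, ny)` (default 50 x 50).
#' @param temperature Kelvin (default 298).
#' @param x_edges,y_edges Optional explicit bin edges; required when a
#'   series is constant (degenerate range).
#' @return A `fes_grid`: list with `x_edges`, `y_edges`, `probability`,
#'   `free_energy` (kJ/mol), `empty_mask`, `kT`.
#' @export
free_energy_surface <- function(x, y, bins = c(50, 50), temperature = 298,
                                x_edges = NULL, y_edges = NULL) {
  if (is.data.frame(x)) x <- x$value
  if (is.data.frame(y)) y <- y$value
  if (length(x) != length(y) || length(x) < 1) {
    abort("order parameter series must be equal-length and non-empty",
          class = "coag_validation_error")
  }
  bins <- rep(as.integer(bins), length.out = 2)
  if (any(bins < 1)) {
    abort("bin counts must be >= 1", class = "coag_validation_error")
  }
  edges_for <- function(v, edges, nb, axis) {
    if (!is.null(edges)) return(edges)
    rng <- range(v)
    if (diff(rng) <= 0) {
      if (nb == 1) return(c(rng[1] - 0.5, rng[1] + 0.5))
      abort(sprintf("constant %s series: degenerate range (supply explicit edges)",
                    axis), class = "coag_degenerate_error")
    }
    seq(rng[1], rng[2], length.out = nb + 1)
  }
  xe <- edges_for(x, x_edges, bins[1], "x")
  ye <- edges_for(y, y_edges, bins[2], "y")
  bx <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1),
             length(xe) - 1)
  by <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1),
             length(ye) - 1)
  counts <- matrix(0, length(xe) - 1, length(ye) - 1)
  for (k in seq_along(bx)) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1
  prob <- counts / sum(counts)
  kT <- KB_KJ * temperature
  fe <- matrix(NA_real_, nrow(prob), ncol(prob))
  nz <- prob > 0
  fe[nz] <- -kT * log(prob[nz] / max(prob))
  structure(list(x_edges = xe, y_edges = ye, probability = prob,
                 free_energy = fe, empty_mask = !nz, kT = kT,
                 temperature = temperature),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("<fes_grid> %d x %d bins, kT = %.4f kJ/mol, %d occupied\n",
              nrow(x$probability), ncol(x$probability), x$kT,
              sum(!x$empty_mask)))
  invisible(x)
}

#' @method tidy fes_grid
#' @export
tidy.fes_grid <- function(x, ...) {
  xm <- (head(x$x_edges, -1) + tail(x$x_edges, -1)) / 2
  ym <- (head(x$y_edges, -1) + tail(x$y_edges, -1)) / 2
  grid <- expand.grid(ix = seq_along(xm), iy = seq_along(ym))
  prob <- x$probability[cbind(grid$ix, grid$iy)]
  fe <- x$free_energy[cbind(grid$ix, grid$iy)]
  tibble(x = xm[grid$ix], y = ym[grid$iy],
         probability = prob, free_energy = fe)
}

#' @method autoplot fes_grid
#' @export
autoplot.fes_grid <- function(object, ...) {
  dat <- filter(tidy(object), !is.na(.data$free_energy))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(fill = "F (kJ/mol)")
}

#' Locate minima basins on a free-energy surface
#'
#' Non-empty bins that are local minima in their 4-neighbourhood (masked
#' neighbours ignored) and lie within `depth` of the global minimum, sorted
#' by free energy (ties broken by bin indices, deterministic).
#'
#' @param grid A `fes_grid`.
#' @param depth Energy window above the global minimum, kJ/mol
#'   (default Inf).
#' @return Tibble `ix`, `iy`, `x`, `y`, `free_energy`.
#' @export
locate_minima <- function(grid, depth = Inf) {
  fe <- grid$free_energy
  nx <- nrow(fe); ny <- ncol(fe)
  xm <- (head(grid$x_edges, -1) + tail(grid$x_edges, -1)) / 2
  ym <- (head(grid$y_edges, -1) + tail(grid$y_edges, -1)) / 2
  out <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (is.na(fe[i, j])) next
      neigh <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      neigh <- neigh[neigh[, 1] >= 1 & neigh[, 1] <= nx &
                     neigh[, 2] >= 1 & neigh[, 2] <= ny, , drop = FALSE]
      vals <- fe[neigh]
      if (all(is.na(vals) | fe[i, j] <= vals) && fe[i, j] <= depth) {
        out[[length(out) + 1]] <- tibble(ix = i, iy = j, x = xm[i],
                                         y = ym[j],
                                         free_energy = fe[i, j])
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(ix = integer(), iy = integer(), x = numeric(), y = numeric(),
           free_energy = numeric())
  arrange(res, .data$free_energy, .data$ix, .data$iy)
}

#' Per-frame interface interaction energy series
#'
#' Per frame, the interface (electrostatic + van der Waals) molecular
#' mechanics energy between ligand and receptor chains — the interaction
#' energy order parameter of the free-energy surfaces.
#'
#' @inheritParams per_residue_decomposition
#' @return A `metric_series` tibble, kJ/mol.
#' @export
interaction_energy_series <- function(traj, ligand_chains = "P",
                                      receptor_chains = NULL,
                                      config = energetics_config()) {
  atoms <- traj$atoms
  receptor_chains <- receptor_chains %||%
    setdiff(unique(atoms$chain), ligand_chains)
  lig <- which(atoms$chain %in% ligand_chains)
  rec <- which(atoms$chain %in% receptor_chains)
  cross <- as.matrix(expand.grid(lig, rec))
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    s <- structure(list(atoms = atoms, xyz = frame_xyz(traj, f)),
                   class = "pep_structure")
    out[f] <- coulomb_energy(s, cross, eps_in = config$eps_in) +
      lj_energy(s, cross)
  }
  metric_series("interaction_energy", out, units = "kJ/mol")
}

#' Windowed per-frame RMSF series
#'
#' RMSF is a time-average, not a per-frame observable; to use it as an
#' order parameter each frame is assigned the RMSF of the window of
#' `window` frames centred on it (truncated at the edges), averaged over
#' the selection's residues.
#'
#' @param traj A `pep_trajectory`.
#' @param selection Atom indices (see [select_atoms()]).
#' @param window Window width in frames (default 21, >= 2).
#' @return A `metric_series` tibble, Angstrom.
#' @export
windowed_rmsf_series <- function(traj, selection = NULL, window = 21) {
  nf <- n_frames(traj)
  if (window < 2) abort("window must be >= 2", class = "coag_validation_error")
  selection <- selection %||% seq_len(nrow(traj$atoms))
  half <- floor(window / 2)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    lo <- max(1, f - half); hi <- min(nf, f + half)
    sub <- pep_trajectory(traj$atoms,
                          traj$frames[, , lo:hi, drop = FALSE])
    out[f] <- mean(traj_rmsf(sub, selection = selection)$rmsf)
  }
  metric_series("windowed_RMSF", out, units = "Angstrom")
}
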