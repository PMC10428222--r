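#' Select atom indices from a structure or trajectory
#'
#' @param x A `pep_structure` or `pep_trajectory`.
#' @param chain,resno,atom_name Optional filters (vectors allowed).
#' @param heavy Keep heavy atoms only (drop hydrogens).
#' @return Integer atom indices, in atom order.
#' @export
select_atoms <- function(x, chain = NULL, resno = NULL, atom_name = NULL,
                         heavy = FALSE) {
  atoms <- x$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  if (!is.null(atom_name)) keep <- keep & atoms$atom_name %in% atom_name
  if (heavy) keep <- keep & atoms$element != "H"
  which(keep)
}

# residue ids as "chain:resno" strings, and per-residue heavy atom index lists
residue_atom_index <- function(atoms, heavy = TRUE) {
  keep <- if (heavy) atoms$element != "H" else rep(TRUE, nrow(atoms))
  idx <- which(keep)
  key <- paste(atoms$chain[idx], atoms$resno[idx], sep = ":")
  split(idx, factor(key, levels = unique(key)))
}

#' Native contacts of a reference structure
#'
#' A native contact exists between two nonconsecutive residues (|i - j| >
#' `min_seq_sep` within a chain; inter-chain pairs are always eligible) when
#' any pair of their heavy atoms lies within `cutoff`. Hydrogens are
#' excluded.
#'
#' @param reference A `pep_structure` with >= 3 residues.
#' @param cutoff Heavy-atom distance cutoff, Angstrom (default 5).
#' @param min_seq_sep Minimum intra-chain sequence separation; the default 1
#'   excludes self and consecutive pairs (|i - j| > 1).
#' @return A `contact_set`: tibble with columns `chain_i`, `resno_i`,
#'   `chain_j`, `resno_j`, `min_dist`, plus `cutoff` and `reference_id`
#'   attributes.
#' @export
native_contacts <- function(reference, cutoff = 5, min_seq_sep = 1,
                            reference_id = "reference") {
  atoms <- reference$atoms
  res <- residue_table(atoms)
  if (nrow(res) < 3) {
    abort("native contact analysis needs at least 3 residues",
          class = "coag_validation_error")
  }
  ridx <- residue_atom_index(atoms)
  keys <- names(ridx)
  rchain <- sub(":.*", "", keys)
  rresno <- as.integer(sub(".*:", "", keys))
  out <- list()
  nr <- length(ridx)
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      if (rchain[i] == rchain[j] &&
          abs(rresno[i] - rresno[j]) <= min_seq_sep) next
      d <- min(pairwise_dist(reference$xyz[ridx[[i]], , drop = FALSE],
                             reference$xyz[ridx[[j]], , drop = FALSE]))
      if (d <= cutoff) {
        out[[length(out) + 1]] <- tibble(
          chain_i = rchain[i], resno_i = rresno[i],
          chain_j = rchain[j], resno_j = rresno[j], min_dist = d)
      }
    }
  }
  cs <- if (length(out)) bind_rows(out) else
    tibble(chain_i = character(), resno_i = integer(),
           chain_j = character(), resno_j = integer(), min_dist = numeric())
  attr(cs, "cutoff") <- cutoff
  attr(cs, "min_seq_sep") <- min_seq_sep
  attr(cs, "reference_id") <- reference_id
  class(cs) <- c("contact_set", class(cs))
  cs
}

#' Fraction of native contacts Q per frame
#'
#' Per frame, Q = (number of native pairs whose minimum heavy-atom distance
#' is still within the contact cutoff) / (number of native pairs). Hard
#' count, no switching function.
#'
#' @param traj A `pep_trajectory` sharing the reference topology.
#' @param contacts A `contact_set` from [native_contacts()].
#' @param cutoff Cutoff, Angstrom; defaults to the contact set's own.
#' @return Tibble with columns `frame`, `value` (class `metric_series`,
#'   name "Q", dimensionless).
#' @export
fraction_native_contacts <- function(traj, contacts, cutoff = NULL) {
  if (nrow(contacts) == 0) {
    abort("empty contact set: Q is undefined", class = "coag_validation_error")
  }
  cutoff <- cutoff %||% attr(contacts, "cutoff")
  atoms <- traj$atoms
  ridx <- residue_atom_index(atoms)
  pair_idx <- lapply(seq_len(nrow(contacts)), function(k) {
    list(i = ridx[[paste(contacts$chain_i[k], contacts$resno_i[k], sep = ":")]],
         j = ridx[[paste(contacts$chain_j[k], contacts$resno_j[k], sep = ":")]])
  })
  nf <- n_frames(traj)
  q <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(traj, f)
    present <- vapply(pair_idx, function(p) {
      min(pairwise_dist(xyz[p$i, , drop = FALSE],
                        xyz[p$j, , drop = FALSE])) <= cutoff
    }, logical(1))
    q[f] <- mean(present)
  }
  metric_series("Q", q, units = "dimensionless")
}

metric_series <- function(name, values, units) {
  out <- tibble(frame = seq_along(values), value = values)
  attr(out, "metric") <- name
  attr(out, "units") <- units
  class(out) <- c("metric_series", class(out))
  out
}

# Kabsch: rotation + translation superposing mobile onto fixed (n x 3 each);
# returns the transformed mobile coordinates
kabsch_fit <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A %*% t(R), 2, cf, "+")
}

#' RMSD per frame after optimal superposition
#'
#' Each frame's selected atoms are rigid-body superposed (Kabsch rotation +
#' translation) onto the reference before the root-mean-square deviation is
#' taken, so global translation/rotation contributes nothing.
#'
#' @param traj A `pep_trajectory`.
#' @param reference A `pep_structure` with the same selected atoms.
#' @param selection Integer atom indices (see [select_atoms()]); default all.
#' @param fit Superpose before measuring (default TRUE).
#' @return A `metric_series` tibble (`frame`, `value`), Angstrom.
#' @export
traj_rmsd <- function(traj, reference, selection = NULL, fit = TRUE) {
  selection <- selection %||% seq_len(nrow(traj$atoms))
  if (!length(selection)) {
    abort("empty selection", class = "coag_validation_error")
  }
  if (max(selection) > nrow(reference$atoms)) {
    abort("selection does not match the reference atoms",
          class = "coag_validation_error")
  }
  ref <- reference$xyz[selection, , drop = FALSE]
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    mob <- frame_xyz(traj, f)[selection, , drop = FALSE]
    if (fit) mob <- kabsch_fit(ref, mob)
    out[f] <- sqrt(mean(rowSums((mob - ref)^2)))
  }
  metric_series("RMSD", out, units = "Angstrom")
}

#' Per-residue RMSF
#'
#' Frames are superposed on the trajectory mean of the selection (two-pass:
#' fit to the first frame, recompute the mean, refit), then per-atom RMSF =
#' sqrt(mean squared displacement from the time-averaged position) is
#' averaged over each residue's selected atoms.
#'
#' @inheritParams traj_rmsd
#' @param fit Superpose frames on the trajectory mean first (default TRUE);
#'   set FALSE for pre-aligned trajectories, where the direct formula
#'   applies without redistribution of motion by the superposition.
#' @return Tibble `chain`, `resno`, `resname`, `rmsf` (Angstrom), class
#'   `residue_profile`.
#' @export
traj_rmsf <- function(traj, selection = NULL, fit = TRUE) {
  if (n_frames(traj) < 2) {
    abort("RMSF needs at least 2 frames", class = "coag_validation_error")
  }
  selection <- selection %||% seq_len(nrow(traj$atoms))
  nf <- n_frames(traj)
  sel_xyz <- lapply(seq_len(nf), function(f)
    frame_xyz(traj, f)[selection, , drop = FALSE])
  if (fit) {
    fitted <- lapply(sel_xyz, function(m) kabsch_fit(sel_xyz[[1]], m))
    mean_xyz <- Reduce("+", fitted) / nf
    fitted <- lapply(sel_xyz, function(m) kabsch_fit(mean_xyz, m))
  } else {
    fitted <- sel_xyz
  }
  mean_xyz <- Reduce("+", fitted) / nf
  msd <- Reduce("+", lapply(fitted, function(m)
    rowSums((m - mean_xyz)^2))) / nf
  atom_rmsf <- sqrt(msd)
  atoms <- traj$atoms[selection, ]
  out <- tibble(chain = atoms$chain, resno = atoms$resno,
                resname = atoms$resname, rmsf = atom_rmsf) |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(rmsf = mean(.data$rmsf), .groups = "drop") |>
    arrange(.data$chain, .data$resno)
  attr(out, "units") <- "Angstrom"
  class(out) <- c("residue_profile", class(out))
  out
}

#' Mass-weighted radius of gyration per frame
#'
#' @inheritParams traj_rmsd
#' @return A `metric_series` tibble, Angstrom.
#' @export
radius_of_gyration <- function(traj, selection = NULL) {
  selection <- selection %||% seq_len(nrow(traj$atoms))
  if (!length(selection)) {
    abort("empty selection", class = "coag_validation_error")
  }
  m <- traj$atoms$mass[selection]
  if (sum(m) <= 0) {
    abort("zero total mass in selection", class = "coag_numeric_error")
  }
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(traj, f)[selection, , drop = FALSE]
    com <- colSums(xyz * m) / sum(m)
    out[f] <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  }
  metric_series("Rg", out, units = "Angstrom")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A frame counts toward a donor-acceptor pair when the heavy-atom distance
#' is within `d_max` and the D-H...A angle (at the hydrogen) is at least
#' `angle_min`. One record is returned per pair with nonzero occupancy;
#' `strong` flags populations above `strong_threshold`.
#'
#' @param traj A `pep_trajectory`.
#' @param donors,acceptors Tibbles with columns `chain`, `resno`,
#'   `atom_name`. Every donor must have a hydrogen in its residue.
#' @param d_max Donor-acceptor heavy-atom cutoff, Angstrom (default 3.5).
#' @param angle_min Minimum D-H...A angle, degrees (default 120).
#' @param strong_threshold Occupancy above which a bond is "strong"
#'   (default 0.80).
#' @return Tibble of `hbond_record` rows: donor/acceptor identity,
#'   `occupancy`, `mean_distance` (over contact frames), `strong`.
#' @export
hbond_occupancy <- function(traj, donors, acceptors, d_max = 3.5,
                            angle_min = 120, strong_threshold = 0.80) {
  atoms <- traj$atoms
  donors <- as_tibble(donors); acceptors <- as_tibble(acceptors)
  d_idx <- integer(nrow(donors)); h_idx <- integer(nrow(donors))
  for (k in seq_len(nrow(donors))) {
    d_idx[k] <- atom_row(atoms, donors$chain[k], donors$resno[k],
                         donors$atom_name[k])
    hres <- which(atoms$chain == donors$chain[k] &
                  atoms$resno == donors$resno[k] & atoms$element == "H")
    if (!length(hres)) {
      abort(sprintf("donor atom %s of %s:%d has no attached hydrogen",
                    donors$atom_name[k], donors$chain[k], donors$resno[k]),
            class = "coag_validation_error")
    }
    x0 <- frame_xyz(traj, 1)
    h_idx[k] <- hres[which.min(sqrt(rowSums(
      (x0[hres, , drop = FALSE] -
       matrix(x0[d_idx[k], ], length(hres), 3, byrow = TRUE))^2)))]
  }
  a_idx <- vapply(seq_len(nrow(acceptors)), function(k)
    atom_row(atoms, acceptors$chain[k], acceptors$resno[k],
             acceptors$atom_name[k]), integer(1))
  nf <- n_frames(traj)
  nd <- length(d_idx); na <- length(a_idx)
  hits <- matrix(0, nd, na)
  dist_sum <- matrix(0, nd, na)
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(traj, f)
    dmat <- pairwise_dist(xyz[d_idx, , drop = FALSE],
                          xyz[a_idx, , drop = FALSE])
    cand <- which(dmat <= d_max, arr.ind = TRUE)
    for (k in seq_len(nrow(cand))) {
      di <- cand[k, 1]; ai <- cand[k, 2]
      if (d_idx[di] == a_idx[ai]) next
      v1 <- xyz[d_idx[di], ] - xyz[h_idx[di], ]
      v2 <- xyz[a_idx[ai], ] - xyz[h_idx[di], ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) *
        180 / pi
      if (ang >= angle_min) {
        hits[di, ai] <- hits[di, ai] + 1
        dist_sum[di, ai] <- dist_sum[di, ai] + dmat[di, ai]
      }
    }
  }
  out <- list()
  for (di in seq_len(nd)) {
    for (ai in seq_len(na)) {
      if (hits[di, ai] == 0) next
      occ <- hits[di, ai] / nf
      out[[length(out) + 1]] <- tibble(
        donor_chain = donors$chain[di], donor_resno = donors$resno[di],
        donor_atom = donors$atom_name[di],
        acceptor_chain = acceptors$chain[ai],
        acceptor_resno = acceptors$resno[ai],
        acceptor_atom = acceptors$atom_name[ai],
        occupancy = occ, mean_distance = dist_sum[di, ai] / hits[di, ai],
        strong = occ > strong_threshold)
    }
  }
  res <- if (length(out)) bind_rows(out) else tibble(
    donor_chain = character(), donor_resno = integer(),
    donor_atom = character(), acceptor_chain = character(),
    acceptor_resno = integer(), acceptor_atom = character(),
    occupancy = numeric(), mean_distance = numeric(), strong = logical())
  class(res) <- c("hbond_table", class(res))
  res
}

salt_bridge_tier <- function(occ, strong = 0.80, moderate = 0.50) {
  ifelse(occ >= strong, "strong", ifelse(occ >= moderate, "moderate", "weak"))
}

#' Salt bridges across the peptide-receptor interface
#'
#' Candidate pairs are all acidic (Asp/Glu carboxylate oxygens) x basic
#' (Lys NZ, Arg NH1/NH2, His NE2) residue pairs across chains (all pairs
#' when the topology has a single chain). A record is emitted when the mean
#' over frames of the minimum side-chain N-O distance is below `d_cut`;
#' occupancy is the fraction of frames below `d_cut`, tiered strong
#' (>= 0.80) / moderate ([0.50, 0.80)) / weak (< 0.50).
#'
#' @param traj A `pep_trajectory` with identifiable charged side chains.
#' @param d_cut Contact distance criterion, Angstrom (default 4).
#' @param strong,moderate Tier boundaries on occupancy.
#' @param across_chains_only Restrict candidates to inter-chain pairs
#'   (default TRUE; ignored for single-chain topologies).
#' @return Tibble of `salt_bridge_record` rows.
#' @export
salt_bridges <- function(traj, d_cut = 4, strong = 0.80, moderate = 0.50,
                         across_chains_only = TRUE) {
  atoms <- traj$atoms
  acid <- which(atoms$resname %in% c("ASP", "GLU") &
                atoms$atom_name %in% c("OD1", "OD2", "OE1", "OE2"))
  base <- which((atoms$resname == "LYS" & atoms$atom_name == "NZ") |
                (atoms$resname == "ARG" & atoms$atom_name %in% c("NH1", "NH2")) |
                (atoms$resname == "HIS" & atoms$atom_name == "NE2"))
  empty <- tibble(acid_chain = character(), acid_resno = integer(),
                  acid_resname = character(), base_chain = character(),
                  base_resno = integer(), base_resname = character(),
                  mean_min_NO_distance = numeric(), occupancy = numeric(),
                  tier = character())
  if (!length(acid) || !length(base)) {
    class(empty) <- c("salt_bridge_table", class(empty)); return(empty)
  }
  acid_res <- split(acid, paste(atoms$chain[acid], atoms$resno[acid], sep = ":"))
  base_res <- split(base, paste(atoms$chain[base], atoms$resno[base], sep = ":"))
  single_chain <- length(unique(atoms$chain)) == 1
  nf <- n_frames(traj)
  out <- list()
  for (ak in names(acid_res)) {
    for (bk in names(base_res)) {
      a_chain <- sub(":.*", "", ak); b_chain <- sub(":.*", "", bk)
      if (across_chains_only && !single_chain && a_chain == b_chain) next
      mins <- numeric(nf)
      for (f in seq_len(nf)) {
        xyz <- frame_xyz(traj, f)
        mins[f] <- min(pairwise_dist(
          xyz[acid_res[[ak]], , drop = FALSE],
          xyz[base_res[[bk]], , drop = FALSE]))
      }
      if (mean(mins) < d_cut) {
        occ <- mean(mins < d_cut)
        ai <- acid_res[[ak]][1]; bi <- base_res[[bk]][1]
        out[[length(out) + 1]] <- tibble(
          acid_chain = a_chain, acid_resno = atoms$resno[ai],
          acid_resname = atoms$resname[ai],
          base_chain = b_chain, base_resno = atoms$resno[bi],
          base_resname = atoms$resname[bi],
          mean_min_NO_distance = mean(mins), occupancy = occ,
          tier = salt_bridge_tier(occ, strong, moderate))
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else empty
  res <- arrange(res, .data$acid_chain, .data$acid_resno, .data$base_resno)
  class(res) <- c("salt_bridge_table", class(res))
  res
}

#' Peptide-residue x receptor-domain interaction map
#'
#' Entry (p, dom) is the fraction of frames in which peptide residue p has
#' any heavy atom within `cutoff` of any heavy atom of a receptor residue
#' labelled dom.
#'
#' @param traj A `pep_trajectory`.
#' @param annotation A [receptor_annotation()] covering the receptor.
#' @param peptide_chain Peptide chain id (default `"P"`); all other chains
#'   are the receptor.
#' @param cutoff Heavy-atom distance cutoff, Angstrom (default 5).
#' @return Long tibble `resno`, `domain`, `frequency` in [0,1], class
#'   `interaction_map`.
#' @export
interaction_map <- function(traj, annotation, peptide_chain = "P",
                            cutoff = 5) {
  atoms <- traj$atoms
  heavy <- atoms$element != "H"
  pep <- which(atoms$chain == peptide_chain & heavy)
  rec <- which(atoms$chain != peptide_chain & heavy)
  if (!length(pep) || !length(rec)) {
    abort("interaction map needs both peptide and receptor atoms",
          class = "coag_validation_error")
  }
  rec_dom <- annotate_residues(annotation, atoms$resno[rec])
  pep_res <- split(pep, atoms$resno[pep])
  rec_by_dom <- split(rec, rec_dom)
  doms <- names(rec_by_dom)
  nf <- n_frames(traj)
  counts <- matrix(0, length(pep_res), length(doms),
                   dimnames = list(names(pep_res), doms))
  for (f in seq_len(nf)) {
    xyz <- frame_xyz(traj, f)
    for (p in seq_along(pep_res)) {
      pd <- pairwise_dist(xyz[pep_res[[p]], , drop = FALSE],
                          xyz[rec, , drop = FALSE])
      mins <- apply(pd, 2, min)
      for (d in seq_along(doms)) {
        sel <- rec_dom == doms[d]
        if (any(mins[sel] <= cutoff)) counts[p, d] <- counts[p, d] + 1
      }
    }
  }
  out <- as_tibble(as.data.frame.table(counts / nf,
                                       stringsAsFactors = FALSE))
  names(out) <- c("resno", "domain", "frequency")
  out$resno <- as.integer(out$resno)
  out <- arrange(out, .data$resno, .data$domain)
  class(out) <- c("interaction_map", class(out))
  out
}

#' @method autoplot interaction_map
#' @export
autoplot.interaction_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$domain,
                                       y = factor(.data$resno),
                                       fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "receptor domain", y = "peptide residue",
                  fill = "contact\nfrequency")
}

#' @method autoplot metric_series
#' @export
autoplot.metric_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame",
                  y = sprintf("%s (%s)", attr(object, "metric"),
                              attr(object, "units")))
}
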