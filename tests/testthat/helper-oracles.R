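# Independent brute-force oracles. These are written as plain double loops
# over the definitions, deliberately sharing no code with the package
# internals they check.

oracle_native_contacts <- function(structure, cutoff = 5, min_seq_sep = 1) {
  at <- structure$atoms
  xyz <- structure$xyz
  heavy <- which(at$element != "H")
  res <- unique(paste(at$chain, at$resno, sep = ":"))
  found <- character()
  for (ri in res) {
    for (rj in res) {
      if (ri >= rj) next
      ci <- sub(":.*", "", ri); cj <- sub(":.*", "", rj)
      ni <- as.integer(sub(".*:", "", ri)); nj <- as.integer(sub(".*:", "", rj))
      if (ci == cj && abs(ni - nj) <= min_seq_sep) next
      ai <- heavy[at$chain[heavy] == ci & at$resno[heavy] == ni]
      aj <- heavy[at$chain[heavy] == cj & at$resno[heavy] == nj]
      hit <- FALSE
      for (a in ai) for (b in aj) {
        if (sqrt(sum((xyz[a, ] - xyz[b, ])^2)) <= cutoff) hit <- TRUE
      }
      if (hit) found <- c(found, paste(ri, rj))
    }
  }
  sort(found)
}

contact_set_keys <- function(cs) {
  sort(paste(paste(cs$chain_i, cs$resno_i, sep = ":"),
             paste(cs$chain_j, cs$resno_j, sep = ":")))
}

oracle_q <- function(traj, contacts, cutoff) {
  at <- traj$atoms
  heavy <- which(at$element != "H")
  nf <- dim(traj$frames)[3]
  q <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$frames[, , f]
    present <- 0
    for (k in seq_len(nrow(contacts))) {
      ai <- heavy[at$chain[heavy] == contacts$chain_i[k] &
                  at$resno[heavy] == contacts$resno_i[k]]
      aj <- heavy[at$chain[heavy] == contacts$chain_j[k] &
                  at$resno[heavy] == contacts$resno_j[k]]
      hit <- FALSE
      for (a in ai) for (b in aj) {
        if (sqrt(sum((xyz[a, ] - xyz[b, ])^2)) <= cutoff) hit <- TRUE
      }
      if (hit) present <- present + 1
    }
    q[f] <- present / nrow(contacts)
  }
  q
}

# independent Kabsch RMSD cross-check via bio3d's superposition
oracle_rmsd_bio3d <- function(traj, reference, selection) {
  ref_flat <- as.vector(t(reference$xyz[selection, , drop = FALSE]))
  nf <- dim(traj$frames)[3]
  vapply(seq_len(nf), function(f) {
    mob <- as.vector(t(traj$frames[selection, , f]))
    bio3d::rmsd(ref_flat, mob, fit = TRUE)
  }, numeric(1))
}

oracle_coulomb <- function(xyz, q, pairs, eps) {
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e <- e + 1389.35458 * q[i] * q[j] / (eps * r)
  }
  e
}

oracle_lj <- function(xyz, sigma, epsilon, pairs) {
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    s <- (sigma[i] + sigma[j]) / 2
    ep <- sqrt(epsilon[i] * epsilon[j])
    e <- e + 4 * ep * ((s / r)^12 - (s / r)^6)
  }
  e
}

# Still pairwise GB energy given precomputed Born radii
oracle_gb_still <- function(xyz, q, born, eps_in, eps_out) {
  tau <- 1 / eps_in - 1 / eps_out
  n <- length(q)
  e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r2 <- sum((xyz[i, ] - xyz[j, ])^2)
      fgb <- sqrt(r2 + born[i] * born[j] * exp(-r2 / (4 * born[i] * born[j])))
      e <- e - 0.5 * tau * 1389.35458 * q[i] * q[j] / fgb
    }
  }
  e
}

# latitude-longitude quadrature of accessible area (independent of the
# golden-spiral Shrake-Rupley implementation)
oracle_sasa_latlong <- function(xyz, radii, probe, n_theta = 200) {
  n <- nrow(xyz)
  r <- radii + probe
  total <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    thetas <- (seq_len(n_theta) - 0.5) * pi / n_theta
    for (t in thetas) {
      n_phi <- max(8, round(2 * n_theta * sin(t)))
      phis <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
      pts <- cbind(r[i] * sin(t) * cos(phis), r[i] * sin(t) * sin(phis),
                   r[i] * cos(t))
      pts <- sweep(pts, 2, xyz[i, ], "+")
      w <- r[i]^2 * sin(t) * (pi / n_theta) * (2 * pi / n_phi)
      exposed <- rep(TRUE, n_phi)
      for (j in seq_len(n)[-i]) {
        dj <- sqrt(rowSums(sweep(pts, 2, xyz[j, ])^2))
        exposed <- exposed & dj >= r[j]
      }
      acc <- acc + w * sum(exposed)
    }
    total[i] <- acc
  }
  total
}

oracle_salt_bridges <- function(traj, d_cut = 4) {
  at <- traj$atoms
  acid_atoms <- which(at$resname %in% c("ASP", "GLU") &
                      at$atom_name %in% c("OD1", "OD2", "OE1", "OE2"))
  base_atoms <- which((at$resname == "LYS" & at$atom_name == "NZ") |
                      (at$resname == "ARG" & at$atom_name %in% c("NH1", "NH2")) |
                      (at$resname == "HIS" & at$atom_name == "NE2"))
  acid_res <- unique(paste(at$chain[acid_atoms], at$resno[acid_atoms], sep = ":"))
  base_res <- unique(paste(at$chain[base_atoms], at$resno[base_atoms], sep = ":"))
  single_chain <- length(unique(at$chain)) == 1
  nf <- dim(traj$frames)[3]
  out <- list()
  for (ar in acid_res) {
    for (br in base_res) {
      ac <- sub(":.*", "", ar); bc <- sub(":.*", "", br)
      if (!single_chain && ac == bc) next
      ai <- acid_atoms[paste(at$chain[acid_atoms], at$resno[acid_atoms],
                             sep = ":") == ar]
      bi <- base_atoms[paste(at$chain[base_atoms], at$resno[base_atoms],
                             sep = ":") == br]
      mins <- numeric(nf)
      for (f in seq_len(nf)) {
        m <- Inf
        for (a in ai) for (b in bi) {
          d <- sqrt(sum((traj$frames[a, , f] - traj$frames[b, , f])^2))
          if (d < m) m <- d
        }
        mins[f] <- m
      }
      if (mean(mins) < d_cut) {
        out[[length(out) + 1]] <- data.frame(
          acid = ar, base = br, mean_min = mean(mins),
          occupancy = mean(mins < d_cut))
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(acid = character(), base = character(),
               mean_min = numeric(), occupancy = numeric())
}

oracle_interaction_map <- function(traj, annotation, peptide_chain, cutoff) {
  at <- traj$atoms
  heavy <- which(at$element != "H")
  pep <- heavy[at$chain[heavy] == peptide_chain]
  rec <- heavy[at$chain[heavy] != peptide_chain]
  doms <- annotate_residues(annotation, at$resno[rec])
  nf <- dim(traj$frames)[3]
  out <- list()
  for (p in unique(at$resno[pep])) {
    pi <- pep[at$resno[pep] == p]
    for (dom in unique(doms)) {
      ri <- rec[doms == dom]
      cnt <- 0
      for (f in seq_len(nf)) {
        hit <- FALSE
        for (a in pi) for (b in ri) {
          if (sqrt(sum((traj$frames[a, , f] - traj$frames[b, , f])^2)) <= cutoff)
            hit <- TRUE
        }
        if (hit) cnt <- cnt + 1
      }
      out[[length(out) + 1]] <- data.frame(resno = p, domain = dom,
                                           frequency = cnt / nf)
    }
  }
  do.call(rbind, out)
}
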