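test_that("native contacts match threshold definition and brute force", {
  # two far residues plus one near pair at 4.9 A
  s <- point_residue_structure(rbind(c(0, 0, 0), c(50, 0, 0), c(4.9, 0, 0)),
                               resno = c(1, 3, 5))
  cs <- native_contacts(s, cutoff = 5)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$resno_i, 1)
  expect_equal(cs$resno_j, 5)

  # all coordinates scaled x10 -> empty set
  s10 <- point_residue_structure(10 * rbind(c(0, 0, 0), c(50, 0, 0),
                                            c(4.9, 0, 0)),
                                 resno = c(1, 3, 5))
  expect_equal(nrow(native_contacts(s10, cutoff = 5)), 0)

  # toy helix structure equals the brute-force double loop
  cplx <- make_toy_complex(seq = "SDKRES")
  ref <- pep_structure(cplx$atoms, cplx$xyz)
  cs2 <- native_contacts(ref)
  expect_equal(contact_set_keys(cs2), oracle_native_contacts(ref))
})

test_that("Q(x) is 1 on the reference, 0 when scattered, and oracle-exact", {
  cplx <- make_toy_complex()
  plan <- interaction_plan(
    fluctuation = tibble::tibble(chain = "P", resno = 1:6, sigma = 0.8),
    seed = 9)
  traj <- generate_trajectory(cplx, plan, 30)
  ref <- pep_structure(cplx$atoms, cplx$xyz)
  cs <- native_contacts(ref)
  q <- fraction_native_contacts(traj, cs)
  expect_true(all(q$value >= 0 & q$value <= 1))
  expect_equal(q$value, oracle_q(traj, cs, attr(cs, "cutoff")))

  ref_traj <- static_trajectory(ref, n = 1)
  expect_equal(fraction_native_contacts(ref_traj, cs)$value, 1)

  scattered <- ref
  scattered$xyz <- ref$xyz * 100
  expect_equal(
    fraction_native_contacts(static_trajectory(scattered, 1), cs)$value, 0)

  expect_error(fraction_native_contacts(traj, cs[0, ]),
               class = "coag_validation_error")
})

test_that("RMSD removes rigid-body motion and matches the bio3d oracle", {
  cplx <- make_toy_complex()
  ref <- pep_structure(cplx$atoms, cplx$xyz)

  same <- static_trajectory(ref, 1)
  expect_equal(traj_rmsd(same, ref)$value, 0, tolerance = 1e-9)

  shifted <- ref
  shifted$xyz <- sweep(ref$xyz, 2, c(5, 0, 0), "+")
  expect_equal(traj_rmsd(static_trajectory(shifted, 1), ref)$value, 0,
               tolerance = 1e-9)

  plan <- interaction_plan(
    fluctuation = tibble::tibble(chain = "P", resno = 1:6, sigma = 0.6),
    seed = 21)
  traj <- generate_trajectory(cplx, plan, 10)
  sel <- select_atoms(traj, chain = "P")
  # bio3d reports superposed RMSD rounded to 3 decimals
  expect_equal(round(traj_rmsd(traj, ref, selection = sel)$value, 3),
               oracle_rmsd_bio3d(traj, ref, sel), tolerance = 1e-9)
})

test_that("RMSF is zero for static trajectories and exact on two frames", {
  cplx <- make_toy_complex()
  static <- static_trajectory(pep_structure(cplx$atoms, cplx$xyz), 5)
  expect_true(all(traj_rmsf(static)$rmsf < 1e-9))
  expect_error(traj_rmsf(static_trajectory(pep_structure(cplx$atoms,
                                                         cplx$xyz), 1)),
               class = "coag_validation_error")

  # two pre-aligned frames: the fourth atom oscillates +-1 A about its
  # mean, so the direct formula gives RMSF exactly 1 A for its residue
  base <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(0, 0, 0))
  s <- point_residue_structure(base, resno = c(1, 3, 5, 7))
  f1 <- base; f2 <- base
  f1[4, 3] <- 1; f2[4, 3] <- -1
  traj <- pep_trajectory(s$atoms, list(f1, f2))
  prof <- traj_rmsf(traj, fit = FALSE)
  expect_equal(prof$rmsf[prof$resno == 7], 1, tolerance = 1e-12)
  expect_true(all(prof$rmsf[prof$resno != 7] == 0))
  # superposition can only redistribute, never create, fluctuation
  expect_lte(sum(traj_rmsf(traj)$rmsf^2), sum(prof$rmsf^2) + 1e-9)
})

test_that("radius of gyration matches symmetry and the direct formula", {
  one <- point_residue_structure(rbind(c(1, 2, 3)))
  expect_equal(radius_of_gyration(static_trajectory(one, 1))$value, 0)

  two <- point_residue_structure(rbind(c(0, 0, 0), c(4, 0, 0)),
                                 resno = c(1, 3))
  expect_equal(radius_of_gyration(static_trajectory(two, 1))$value, 2)

  xyz <- rbind(c(0, 0, 0), c(1, 2, 0), c(-1, 1, 3), c(2, -2, 1), c(0, 3, -2))
  five <- point_residue_structure(xyz, resno = c(1, 3, 5, 7, 9))
  com <- colMeans(xyz)
  expected <- sqrt(mean(rowSums(sweep(xyz, 2, com)^2)))
  expect_equal(radius_of_gyration(static_trajectory(five, 1))$value, expected)
})

test_that("hydrogen-bond occupancy recovers planted populations", {
  cplx <- make_toy_complex(seq = "SDKRES",
                           receptor = c(`385` = "D", `390` = "S"))
  plan <- interaction_plan(
    hbonds = tibble::tibble(donor_chain = "P", donor_resno = 2,
                            donor_atom = "N", acceptor_chain = "R",
                            acceptor_resno = 385, acceptor_atom = "OD1",
                            occupancy = 0.9),
    seed = 13)
  nf <- 500
  traj <- generate_trajectory(cplx, plan, nf)
  donors <- tibble::tibble(chain = "P", resno = 2, atom_name = "N")
  acceptors <- tibble::tibble(chain = "R", resno = c(385, 390),
                              atom_name = c("OD1", "CB"))
  hb <- hbond_occupancy(traj, donors, acceptors)
  expect_equal(nrow(hb), 1)  # the never-close acceptor is absent
  expect_equal(hb$acceptor_resno, 385)
  expect_lt(abs(hb$occupancy - 0.9), 3 * sqrt(0.9 * 0.1 / nf))
  expect_true(hb$strong)
  expect_lt(hb$mean_distance, 3.0)

  no_h <- tibble::tibble(chain = "P", resno = 2, atom_name = "CA")
  stripped <- traj
  keep <- stripped$atoms$element != "H"
  stripped <- pep_trajectory(stripped$atoms[keep, ],
                             stripped$frames[keep, , , drop = FALSE])
  expect_error(hbond_occupancy(stripped, no_h, acceptors),
               class = "coag_validation_error")
})

test_that("salt-bridge detection matches the brute-force enumeration", {
  cplx <- make_toy_complex(seq = "SDKRES",
                           receptor = c(`10` = "K", `20` = "E"))
  plan <- interaction_plan(
    saltbridges = tibble::tibble(
      acid_chain = c("P", "R"), acid_resno = c(2, 20),
      base_chain = c("R", "P"), base_resno = c(10, 3),
      distance = c(3.0, 3.5), occupancy = c(0.9, 0.6)),
    fluctuation = tibble::tibble(chain = "P", resno = 1:6, sigma = 0.1),
    seed = 17)
  traj <- generate_trajectory(cplx, plan, 40)
  sb <- salt_bridges(traj)
  orc <- oracle_salt_bridges(traj)
  expect_equal(nrow(sb), nrow(orc))
  got <- sort(paste(sb$acid_chain, sb$acid_resno, sb$base_chain, sb$base_resno))
  want <- sort(paste(sub(":", " ", orc$acid), sub(":", " ", orc$base)))
  expect_equal(got, want)
  expect_equal(sort(sb$occupancy), sort(orc$occupancy))
  expect_equal(sort(sb$mean_min_NO_distance), sort(orc$mean_min), tolerance = 1e-9)

  # all charged pairs far apart -> empty, not an error
  far <- make_toy_complex(seq = "SDKRES", receptor = c(`10` = "K"),
                          radius = 60)
  quiet <- generate_trajectory(far, interaction_plan(seed = 1), 3)
  expect_equal(nrow(salt_bridges(quiet)), 0)

  # no charged residues at all -> empty list
  neutral <- make_toy_complex(seq = "SSQGTS", receptor = c(`10` = "S"))
  tq <- generate_trajectory(neutral, interaction_plan(seed = 1), 2)
  expect_equal(nrow(salt_bridges(tq)), 0)
})

test_that("salt-bridge tiers are a deterministic function of occupancy", {
  expect_equal(salt_bridge_tier(c(0.95, 0.80, 0.79, 0.50, 0.49)),
               c("strong", "strong", "moderate", "moderate", "weak"))
})

test_that("interaction map recovers planted domain contacts and the oracle", {
  cplx <- make_toy_complex(seq = "SDKRESDKR",
                           receptor = c(`378` = "R", `430` = "S"))
  ann <- receptor_annotation(tibble::tibble(
    start = c(370, 420), end = c(380, 440), label = c("ECL3", "TM7")))
  occ <- 0.8
  plan <- interaction_plan(
    saltbridges = tibble::tibble(acid_chain = "P", acid_resno = 7,
                                 base_chain = "R", base_resno = 378,
                                 distance = 3.0, occupancy = occ),
    seed = 23)
  nf <- 100
  traj <- generate_trajectory(cplx, plan, nf)
  im <- interaction_map(traj, ann)
  expect_true(all(im$frequency >= 0 & im$frequency <= 1))
  hot <- im$frequency[im$resno == 7 & im$domain == "ECL3"]
  expect_lt(abs(hot - occ), 3 * sqrt(occ * (1 - occ) / nf))

  # no contacts -> zero matrix
  far <- make_toy_complex(seq = "SDKR", receptor = c(`378` = "R"),
                          radius = 80)
  tfar <- generate_trajectory(far, interaction_plan(seed = 2), 3)
  expect_true(all(interaction_map(tfar, ann)$frequency == 0))

  # small instance equals brute-force recount
  small <- generate_trajectory(
    make_toy_complex(seq = "SDKR", receptor = c(`378` = "R")),
    interaction_plan(
      saltbridges = tibble::tibble(acid_chain = "P", acid_resno = 2,
                                   base_chain = "R", base_resno = 378,
                                   distance = 3.0, occupancy = 0.5),
      seed = 3),
    20)
  got <- interaction_map(small, ann)
  orc <- oracle_interaction_map(small, ann, "P", 5)
  merged <- merge(as.data.frame(got), orc, by = c("resno", "domain"))
  expect_equal(merged$frequency.x, merged$frequency.y)
})

test_that("distance metrics are invariant under uniform rigid-body motion", {
  cplx <- make_toy_complex()
  plan <- interaction_plan(
    fluctuation = tibble::tibble(chain = "P", resno = 1:6, sigma = 0.4),
    seed = 31)
  traj <- generate_trajectory(cplx, plan, 8)
  ref <- pep_structure(cplx$atoms, cplx$xyz)
  cs <- native_contacts(ref)

  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- traj
  for (f in seq_len(trajectory_length(traj))) {
    moved$frames[, , f] <- traj$frames[, , f] %*% t(R) +
      matrix(c(10, -4, 2), nrow(cplx$xyz), 3, byrow = TRUE)
  }
  expect_equal(fraction_native_contacts(moved, cs)$value,
               fraction_native_contacts(traj, cs)$value)
  expect_equal(traj_rmsd(moved, ref)$value, traj_rmsd(traj, ref)$value,
               tolerance = 1e-6)
  expect_equal(radius_of_gyration(moved)$value,
               radius_of_gyration(traj)$value, tolerance = 1e-9)
  expect_equal(traj_rmsf(moved)$rmsf, traj_rmsf(traj)$rmsf,
               tolerance = 1e-6)
})
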