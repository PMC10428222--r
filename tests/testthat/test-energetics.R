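test_that("Coulomb kernel reproduces the closed form and the pair-loop oracle", {
  s <- make_structure(list(c("O1", "O", "1", "GLY", "P"),
                           c("N1", "N", "1", "GLY", "R")),
                      rbind(c(0, 0, 0), c(5, 0, 0)),
                      charge = c(1, -1))
  expect_equal(coulomb_energy(s, cbind(1, 2), eps_in = 2), -138.935458,
               tolerance = 1e-6)

  s0 <- make_structure(list(c("O1", "O", "1", "GLY", "P"),
                            c("N1", "N", "1", "GLY", "R")),
                       rbind(c(0, 0, 0), c(5, 0, 0)), charge = c(0, 0))
  expect_equal(coulomb_energy(s0, cbind(1, 2)), 0)

  set.seed(1)
  xyz <- matrix(rnorm(12, sd = 4), 4, 3)
  q <- c(0.3, -0.5, 1.0, -0.2)
  s4 <- make_structure(lapply(1:4, function(i)
    c(paste0("A", i), "C", as.character(i), "GLY", "P")), xyz, charge = q)
  pairs <- t(combn(4, 2))
  expect_equal(coulomb_energy(s4, pairs, eps_in = 2),
               oracle_coulomb(xyz, q, pairs, 2), tolerance = 1e-12)

  coincident <- s4
  coincident$xyz[2, ] <- coincident$xyz[1, ]
  expect_error(coulomb_energy(coincident, pairs),
               class = "coag_numeric_error")
})

test_that("LJ kernel has its roots and minimum in the right places", {
  mk <- function(r, sig = 3.4, eps = 0.5) {
    make_structure(list(c("C1", "C", "1", "GLY", "P"),
                        c("C2", "C", "2", "GLY", "R")),
                   rbind(c(0, 0, 0), c(r, 0, 0)),
                   lj_sigma = c(sig, sig), lj_epsilon = c(eps, eps))
  }
  expect_equal(lj_energy(mk(3.4), cbind(1, 2)), 0, tolerance = 1e-12)
  expect_equal(lj_energy(mk(2^(1 / 6) * 3.4), cbind(1, 2)), -0.5,
               tolerance = 1e-12)

  set.seed(2)
  xyz <- matrix(rnorm(9, sd = 5), 3, 3)
  sig <- c(3.2, 3.4, 3.0); eps <- c(0.3, 0.6, 0.9)
  s3 <- make_structure(lapply(1:3, function(i)
    c(paste0("C", i), "C", as.character(i), "GLY", "P")), xyz,
    lj_sigma = sig, lj_epsilon = eps)
  pairs <- t(combn(3, 2))
  expect_equal(lj_energy(s3, pairs), oracle_lj(xyz, sig, eps, pairs),
               tolerance = 1e-12)
})

test_that("generalized Born matches the Born ion and the Still-sum oracle", {
  ion <- make_structure(list(c("NZ", "N", "1", "LYS", "P")),
                        rbind(c(0, 0, 0)), charge = 1)
  expect_equal(gb_polar_energy(ion, energetics_config(), radii = 2),
               -0.5 * (1 / 2 - 1 / 80) * 1389.35458 / 2, tolerance = 1e-9)
  expect_equal(gb_polar_energy(ion, energetics_config(), radii = 2),
               -169.3, tolerance = 1e-3)

  neutral <- make_structure(list(c("CA", "C", "1", "GLY", "P")),
                            rbind(c(0, 0, 0)), charge = 0)
  expect_equal(gb_polar_energy(neutral), 0)

  # two-ion system against an independent evaluation of the Still sum
  two <- make_structure(list(c("NZ", "N", "1", "LYS", "P"),
                             c("OD1", "O", "2", "ASP", "R")),
                        rbind(c(0, 0, 0), c(4, 0, 0)), charge = c(1, -1))
  B <- born_radii(two)
  cfg <- energetics_config()
  expect_equal(gb_polar_energy(two, cfg),
               oracle_gb_still(two$xyz, c(1, -1), B, 2, 80),
               tolerance = 1e-12)

  # eps_in -> eps_out limit: polar term vanishes
  cfg_limit <- energetics_config(eps_in = 80 - 1e-9, eps_out = 80)
  expect_lt(abs(gb_polar_energy(two, cfg_limit)), 1e-9)
})

test_that("SASA matches closed forms and a quadrature oracle", {
  one <- make_structure(list(c("CA", "C", "1", "GLY", "P")),
                        rbind(c(0, 0, 0)))
  a <- sasa(one, probe = 1.4, radii = 1.6)
  expect_equal(a, 4 * pi * 3^2, tolerance = 0.02 * 4 * pi * 9)

  # fully overlapping identical spheres expose one sphere's worth of area
  two_same <- make_structure(list(c("C1", "C", "1", "GLY", "P"),
                                  c("C2", "C", "2", "GLY", "P")),
                             rbind(c(0, 0, 0), c(0, 0, 0)))
  a2 <- sasa(two_same, probe = 1.4, radii = c(1.6, 1.6))
  expect_equal(sum(a2), 4 * pi * 3^2, tolerance = 0.02 * 4 * pi * 9)

  # three partially overlapping spheres against the quadrature integrator
  xyz <- rbind(c(0, 0, 0), c(2.2, 0, 0), c(1.1, 1.8, 0.4))
  radii <- c(1.6, 1.5, 1.7)
  three <- make_structure(lapply(1:3, function(i)
    c(paste0("C", i), "C", as.character(i), "GLY", "P")), xyz)
  got <- sasa(three, probe = 1.4, radii = radii)
  want <- oracle_sasa_latlong(xyz, radii, 1.4)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("binding free energy vanishes for non-interacting partners", {
  # uncharged, epsilon-free atoms 25 A apart: every component is zero
  s <- make_structure(list(c("CA", "C", "1", "GLY", "P"),
                           c("CA", "C", "1", "GLY", "R")),
                      rbind(c(0, 0, 0), c(25, 0, 0)),
                      charge = c(0, 0), lj_sigma = c(3.4, 3.4),
                      lj_epsilon = c(0, 0))
  traj <- static_trajectory(s, 2)
  d <- binding_free_energy(traj, ligand_chains = "P")
  expect_lt(abs(glance(d)$dg_bind), 1e-6)
})

test_that("decomposition conserves totals and splits symmetric interfaces evenly", {
  cplx <- make_toy_complex(seq = "SDKRES", receptor = c(`10` = "K", `20` = "E"))
  plan <- interaction_plan(
    saltbridges = tibble::tibble(acid_chain = "P", acid_resno = 2,
                                 base_chain = "R", base_resno = 10,
                                 distance = 3.0, occupancy = 1),
    seed = 4)
  traj <- generate_trajectory(cplx, plan, 2)
  d <- per_residue_decomposition(traj)
  td <- tidy(d)
  tot <- attr(d, "totals")
  for (comp in c("elec", "vdw", "polar", "nonpolar", "total")) {
    expect_equal(sum(td[[comp]]), unname(tot[[comp]]),
                 tolerance = 1e-6)
  }
  expect_equal(td$total, td$elec + td$vdw + td$polar + td$nonpolar,
               tolerance = 1e-12)

  # symmetric two-residue interface with equal charges splits evenly
  sym <- make_structure(list(c("NZ", "N", "1", "LYS", "P"),
                             c("NZ", "N", "1", "LYS", "R")),
                        rbind(c(0, 0, 0), c(6, 0, 0)), charge = c(1, 1),
                        lj_sigma = c(3.2, 3.2), lj_epsilon = c(0.5, 0.5))
  ds <- per_residue_decomposition(static_trajectory(sym, 1),
                                  ligand_chains = "P")
  ts <- tidy(ds)
  expect_equal(ts$elec[1], ts$elec[2], tolerance = 1e-12)
  expect_equal(ts$vdw[1], ts$vdw[2], tolerance = 1e-12)

  # zero-charge system: elec column identically zero
  zc <- sym
  zc$atoms$charge <- 0
  dz <- per_residue_decomposition(static_trajectory(zc, 1),
                                  ligand_chains = "P")
  expect_true(all(tidy(dz)$elec == 0))
})

test_that("binding free energy averages per-frame kernel evaluations", {
  cplx <- make_toy_complex(seq = "SDKR", receptor = c(`10` = "E"))
  plan <- interaction_plan(
    fluctuation = tibble::tibble(chain = "P", resno = 1:4, sigma = 0.3),
    seed = 6)
  traj <- generate_trajectory(cplx, plan, 2)
  cfg <- energetics_config()
  lig <- which(cplx$atoms$chain == "P")
  rec <- which(cplx$atoms$chain == "R")
  cross <- as.matrix(expand.grid(lig, rec))
  per_frame <- vapply(1:2, function(f) {
    s <- pep_structure(cplx$atoms, traj$frames[, , f])
    sl <- pep_structure(cplx$atoms[lig, ], traj$frames[lig, , f])
    sr <- pep_structure(cplx$atoms[rec, ], traj$frames[rec, , f])
    rho <- unname(c(H = 1.2, C = 1.7, N = 1.55, O = 1.52,
                    S = 1.8)[cplx$atoms$element]) - 0.09
    coulomb_energy(s, cross, eps_in = cfg$eps_in) + lj_energy(s, cross) +
      (gb_polar_energy(s, cfg, radii = rho) -
         gb_polar_energy(sl, cfg, radii = rho[lig]) -
         gb_polar_energy(sr, cfg, radii = rho[rec])) +
      cfg$gamma_sasa * (sum(sasa(s, cfg$probe_radius)) -
                          sum(sasa(sl, cfg$probe_radius)) -
                          sum(sasa(sr, cfg$probe_radius)))
  }, numeric(1))
  d <- binding_free_energy(traj, ligand_chains = "P", config = cfg)
  expect_equal(glance(d)$dg_bind, mean(per_frame), tolerance = 1e-9)
})

test_that("shortening an attractive interface pair strictly lowers the electrostatics", {
  mk_traj <- function(r) {
    s <- make_structure(list(c("OD1", "O", "1", "ASP", "P"),
                             c("NZ", "N", "1", "LYS", "R")),
                        rbind(c(0, 0, 0), c(r, 0, 0)), charge = c(-1, 1),
                        lj_sigma = c(3, 3), lj_epsilon = c(0.2, 0.2))
    static_trajectory(s, 1)
  }
  elecs <- vapply(c(4.5, 4.0, 3.5, 3.0),
                  function(r) glance(binding_free_energy(mk_traj(r)))$elec,
                  numeric(1))
  expect_true(all(diff(elecs) < 0))
})

test_that("binding free energy is invariant under rigid motion of the complex", {
  cplx <- make_toy_complex(seq = "SDKR", receptor = c(`10` = "E"))
  traj <- static_trajectory(pep_structure(cplx$atoms, cplx$xyz), 1)
  d0 <- glance(binding_free_energy(traj))$dg_bind
  theta <- 1.1
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- traj
  moved$frames[, , 1] <- traj$frames[, , 1] %*% t(R) +
    matrix(c(3, 8, -5), nrow(cplx$xyz), 3, byrow = TRUE)
  expect_equal(glance(binding_free_energy(moved))$dg_bind, d0,
               tolerance = 1e-6)
})

test_that("difference maps subtract aligned positions and flag disjoint sets", {
  cplx <- make_toy_complex(seq = "SDKR", receptor = c(`10` = "E"))
  traj <- static_trajectory(pep_structure(cplx$atoms, cplx$xyz), 1)
  d <- binding_free_energy(traj)
  dm <- difference_map(d, d)
  expect_true(all(dm$delta == 0))

  d2 <- d
  shift_at <- which(d2$resno == 3 & d2$chain == "P")
  d2$total[shift_at] <- d2$total[shift_at] + 5
  dm2 <- difference_map(d, d2)
  expect_equal(dm2$delta[dm2$chain == "P" & dm2$resno == 3], -5)
  expect_true(all(dm2$delta[!(dm2$chain == "P" & dm2$resno == 3)] == 0))

  d3 <- d
  d3$resno <- d3$resno + 1000
  expect_error(difference_map(d, d3), class = "coag_validation_error")

  set.seed(8)
  ra <- d; rb <- d
  ra$total <- rnorm(nrow(ra)); rb$total <- rnorm(nrow(rb))
  dm3 <- difference_map(ra, rb)
  expect_equal(dm3$delta,
               ra$total[order(ra$chain, ra$resno)] -
                 rb$total[order(rb$chain, rb$resno)])
})
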