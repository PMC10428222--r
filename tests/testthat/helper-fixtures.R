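# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# a bare structure from an atom spec matrix: list(c(name, elem, resno, resname,
# chain), ...) plus coordinates
make_structure <- function(spec, xyz, charge = NULL, lj_sigma = NULL,
                           lj_epsilon = NULL) {
  atoms <- tibble::tibble(
    atom_name = vapply(spec, `[`, "", 1),
    element = vapply(spec, `[`, "", 2),
    resno = as.integer(vapply(spec, `[`, "", 3)),
    resname = vapply(spec, `[`, "", 4),
    chain = vapply(spec, `[`, "", 5))
  if (!is.null(charge)) atoms$charge <- charge
  if (!is.null(lj_sigma)) atoms$lj_sigma <- lj_sigma
  if (!is.null(lj_epsilon)) atoms$lj_epsilon <- lj_epsilon
  pep_structure(atoms, xyz)
}

# single-atom residues (CA only) on given coordinates, one chain
point_residue_structure <- function(xyz, chain = "P", resno = NULL) {
  n <- nrow(xyz)
  resno <- resno %||% seq_len(n)
  make_structure(
    lapply(seq_len(n), function(i)
      c("CA", "C", as.character(resno[i]), "GLY", chain)),
    xyz)
}

static_trajectory <- function(structure, n = 2) {
  pep_trajectory(structure$atoms,
                 array(rep(structure$xyz, n),
                       dim = c(nrow(structure$xyz), 3, n)))
}

# small bound complex used across metric/energetics tests
make_toy_complex <- function(seq = "SDKRES", receptor = NULL, radius = 18) {
  pep <- build_ideal_helix(peptide_seq(seq))
  rec <- build_toy_receptor(residues = receptor, n_pocket_residues = 4,
                            radius = radius)
  assign_params(combine_structures(pep, rec))
}

# the printed reference fixture: a Cotadutide-sequence helix in a toy pocket
# carrying Arg146, Asp225 and Arg231, with the three salt bridges planted at
# 3.0 Angstrom / 95% occupancy
cotadutide_gcgr_fixture <- function(n_frames = 200, seed = 11) {
  cot <- build_design("cotadutide")
  pep <- build_ideal_helix(cot)
  rec <- build_toy_receptor(
    residues = c(`146` = "R", `225` = "D", `231` = "R"), radius = 20)
  cplx <- assign_params(combine_structures(pep, rec))
  plan <- interaction_plan(
    saltbridges = tibble::tibble(
      acid_chain = c("P", "R", "P"), acid_resno = c(27, 225, 15),
      base_chain = c("R", "P", "R"), base_resno = c(146, 10, 231),
      distance = 3.0, occupancy = 0.95),
    seed = seed)
  generate_trajectory(cplx, plan, n_frames)
}

expect_tbl_equal_num <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
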