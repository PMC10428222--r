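#' Parse point-mutation labels
#'
#' Converts `"S16W"`-style labels into a tibble of mutation specs
#' (`position`, `wt`, `mut`, `label`). The wild-type letter is kept so that
#' application can guard against numbering drift.
#'
#' @param labels Character vector of mutation labels.
#' @return Tibble with one row per mutation.
#' @export
mutation_spec <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Z])([0-9]+)([A-Z])$", labels))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    abort(sprintf("cannot parse mutation label '%s'", labels[bad][1]),
          class = "coag_validation_error")
  }
  out <- tibble(
    position = vapply(m, function(x) as.integer(x[3]), integer(1)),
    wt = vapply(m, `[`, character(1), 2),
    mut = vapply(m, `[`, character(1), 4),
    label = labels)
  if (any(out$wt == out$mut)) {
    abort("wild-type and mutant residues must differ",
          class = "coag_validation_error")
  }
  if (any(!c(out$wt, out$mut) %in% AA1)) {
    abort("mutation letters must be canonical residues",
          class = "coag_validation_error")
  }
  out
}

#' Apply point mutations to a peptide
#'
#' Substitutes residues at the given 1-based positions. Each spec's
#' wild-type letter must match the current sequence at that position
#' (guarding against numbering drift); the labels are appended to the
#' sequence's provenance. Length never changes.
#'
#' @param seq A [peptide_seq()].
#' @param muts Character vector of labels (`"S16W"`) or a [mutation_spec()]
#'   tibble. Empty means identity.
#' @return The mutated [peptide_seq()].
#' @export
apply_mutations <- function(seq, muts) {
  if (is.character(muts)) {
    if (!length(muts)) return(seq)
    muts <- mutation_spec(muts)
  }
  if (!nrow(muts)) return(seq)
  res <- seq$residues
  for (k in seq_len(nrow(muts))) {
    p <- muts$position[k]
    if (p > length(res)) {
      abort(sprintf("mutation %s: position %d beyond sequence length %d",
                    muts$label[k], p, length(res)),
            class = "coag_validation_error")
    }
    if (res[p] != muts$wt[k]) {
      abort(sprintf(
        "mutation %s: expected %s at position %d of '%s' but found %s",
        muts$label[k], muts$wt[k], p, seq$id, res[p]),
        class = "coag_validation_error")
    }
    res[p] <- muts$mut[k]
  }
  peptide_seq(res, id = seq$id,
              provenance = c(seq$provenance, muts$label))
}

#' Graft a donor C-terminal segment onto a peptide
#'
#' Appends residues `donor_from..length(donor)` of the donor sequence to the
#' C-terminus (the chimera-construction step of the coagonist design).
#'
#' @param seq A [peptide_seq()].
#' @param donor Donor [peptide_seq()].
#' @param donor_from 1-based start position in the donor. A start one past
#'   the donor length appends nothing (identity).
#' @return The extended [peptide_seq()].
#' @export
graft_cterm <- function(seq, donor, donor_from) {
  if (donor_from > length(donor$residues) + 1 || donor_from < 1) {
    abort(sprintf("graft start %d out of range for donor '%s' (length %d)",
                  donor_from, donor$id, length(donor$residues)),
          class = "coag_validation_error")
  }
  if (donor_from == length(donor$residues) + 1) return(seq)
  appended <- donor$residues[donor_from:length(donor$residues)]
  peptide_seq(c(seq$residues, appended), id = seq$id,
              provenance = c(seq$provenance,
                             sprintf("graft:%s[%d-%d]", donor$id, donor_from,
                                     length(donor$residues))))
}

#' Classify a point mutation from its dual-receptor ddG values
#'
#' ddG convention: mutant minus reference binding free energy, so negative
#' values improve binding. A mutation improves a receptor when its ddG is at
#' or below `-threshold`; it penalizes when neither receptor improves and
#' either ddG is at or above `+threshold`; otherwise it is neutral
#' ("confers no significant advantage").
#'
#' @param ddg_gcgr,ddg_glp1r Binding free energy changes, kJ/mol.
#' @param threshold Significance band half-width, kJ/mol (default 5).
#' @param label Optional mutation label carried through.
#' @return One-row tibble: `label`, `ddg_gcgr`, `ddg_glp1r`, `class`,
#'   `threshold`.
#' @export
classify_mutation <- function(ddg_gcgr, ddg_glp1r, threshold = 5,
                              label = NA_character_) {
  stopifnot(is.finite(ddg_gcgr), is.finite(ddg_glp1r), threshold > 0)
  imp_g <- ddg_gcgr <= -threshold
  imp_l <- ddg_glp1r <= -threshold
  cls <- if (imp_g && imp_l) "improves_both"
  else if (imp_g) "improves_GCGR"
  else if (imp_l) "improves_GLP1R"
  else if (ddg_gcgr >= threshold || ddg_glp1r >= threshold) "penalizes"
  else "neutral"
  tibble(label = label, ddg_gcgr = ddg_gcgr, ddg_glp1r = ddg_glp1r,
         class = cls, threshold = threshold)
}

#' Residues contributing significantly to binding
#'
#' Positions whose per-residue total contribution lies below the threshold
#' (default -50 kJ/mol), ascending by position.
#'
#' @param decomp An `energy_decomposition` (or its [tidy()] tibble).
#' @param threshold Contribution cutoff, kJ/mol (default -50).
#' @param chain Optional chain filter (e.g. the peptide chain).
#' @return Integer vector of residue positions.
#' @export
significant_residues <- function(decomp, threshold = -50, chain = NULL) {
  dat <- if (inherits(decomp, "energy_decomposition")) tidy(decomp)
         else as_tibble(decomp)
  if (!nrow(dat)) return(integer())
  if (!is.null(chain)) dat <- filter(dat, .data$chain %in% !!chain)
  sort(dat$resno[dat$total < threshold])
}

#' Coupled dual-receptor affinity score
#'
#' Composite score for dual agonism: the sum of the two binding free
#' energies (lower is better), with the absolute difference as an imbalance
#' diagnostic — two candidates with equal composites but unequal balance are
#' distinguished by the latter.
#'
#' @param dg_gcgr,dg_glp1r Binding free energies, kJ/mol.
#' @return Tibble `composite`, `imbalance` (kJ/mol).
#' @export
coupled_affinity <- function(dg_gcgr, dg_glp1r) {
  stopifnot(all(is.finite(dg_gcgr)), all(is.finite(dg_glp1r)))
  tibble(composite = dg_gcgr + dg_glp1r,
         imbalance = abs(dg_gcgr - dg_glp1r))
}

#' Rank coagonist candidates by coupled affinity
#'
#' Sorts ascending by the composite score (sum of the two binding free
#' energies), breaking ties by imbalance then id; deterministic, and always
#' a permutation of the input rows.
#'
#' @param candidates Data frame with columns `id`, `dg_gcgr`, `dg_glp1r`.
#' @return The input tibble with `composite`, `imbalance` and `rank` added,
#'   sorted.
#' @export
rank_candidates <- function(candidates) {
  cand <- as_tibble(candidates)
  if (!nrow(cand)) {
    abort("no candidates to rank", class = "coag_validation_error")
  }
  sc <- coupled_affinity(cand$dg_gcgr, cand$dg_glp1r)
  cand$composite <- sc$composite
  cand$imbalance <- sc$imbalance
  cand <- arrange(cand, .data$composite, .data$imbalance, .data$id)
  cand$rank <- seq_len(nrow(cand))
  cand
}

#' Read a design rule file
#'
#' Design rules are YAML documents with fields `name`, `template` (a name in
#' the bundled sequence set, or a raw sequence), `mutations` (list of
#' `"S16W"` labels), `back_mutations` (same format) and optional
#' `graft: {donor, from}`. Two rule files ship with the package:
#' `mdd_gr.yaml` (the MD-directed dual-receptor design) and
#' `cotadutide.yaml` (the clinical-stage reference).
#'
#' @param path YAML file path, or the bare name of a shipped rule file
#'   (`"mdd_gr"`, `"cotadutide"`).
#' @return A `design_rules` list.
#' @export
read_design_rules <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", "rules", paste0(path, ".yaml"),
                           package = "coagdesign")
    if (shipped == "") {
      abort(sprintf("design rule file not found: %s", path),
            class = "coag_io_error")
    }
    path <- shipped
  }
  rules <- yaml::read_yaml(path)
  rules$mutations <- as.character(rules$mutations %||% character())
  rules$back_mutations <- as.character(rules$back_mutations %||% character())
  structure(rules, class = "design_rules")
}

resolve_sequence <- function(x, id = NULL) {
  if (inherits(x, "peptide_seq")) return(x)
  bundled <- template_sequences()
  if (x %in% names(bundled)) return(bundled[[x]])
  peptide_seq(x, id = id %||% "sequence")
}

#' Build a designed peptide from a rule set
#'
#' Applies, in this order: the mutation set, the back-mutations, then the
#' C-terminal graft. Provenance records every step. The shipped `mdd_gr`
#' rules encode the dual-receptor design: GLP-1R-oriented mutations
#' (S16W, Q24D, N28D, R17Q) on the 29-residue glucagon template, positions
#' 3 and 15 set back to Glu, and the graft of GLP-1 positions 30-31
#' (Arg, Gly), yielding a 31-residue coagonist.
#'
#' @param rules A `design_rules` list (see [read_design_rules()]) or the
#'   name of a shipped rule file.
#' @param template Optional [peptide_seq()] overriding the rule file's
#'   template.
#' @return The designed [peptide_seq()].
#' @export
build_design <- function(rules, template = NULL) {
  if (is.character(rules)) rules <- read_design_rules(rules)
  seq <- template %||% resolve_sequence(rules$template)
  seq$id <- rules$name %||% seq$id
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("design step '%s' failed: %s", what, conditionMessage(e)),
            class = "coag_design_error")
    })
  }
  seq <- step("mutations", apply_mutations(seq, rules$mutations))
  seq <- step("back_mutations", apply_mutations(seq, rules$back_mutations))
  if (!is.null(rules$graft)) {
    donor <- step("graft", resolve_sequence(rules$graft$donor))
    seq <- step("graft", graft_cterm(seq, donor, rules$graft$from))
  }
  seq
}
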