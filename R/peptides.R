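#' Peptide sequences
#'
#' A `peptide_seq` is a 1-based amino-acid sequence (20-canonical one-letter
#' alphabet) carrying an id and a provenance trail of the design steps
#' (mutations, grafts) that produced it.
#'
#' @param residues Character: either a single string (`"HSQG..."`) or a vector
#'   of one-letter codes.
#' @param id Sequence identifier.
#' @param provenance Character vector of applied design-step labels
#'   (e.g. `"S16W"`, `"graft:GLP1[30-31]"`).
#' @return A `peptide_seq` object.
#' @examples
#' peptide_seq("HSQGTFTSD", id = "gcg_frag")
#' @export
peptide_seq <- function(residues, id = "peptide", provenance = character()) {
  if (length(residues) == 1 && nchar(residues) > 1) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 1) {
    abort("a peptide sequence must contain at least one residue",
          class = "coag_validation_error")
  }
  bad <- which(!residues %in% AA1)
  if (length(bad)) {
    abort(sprintf("non-canonical residue '%s' at position %d of '%s'",
                  residues[bad[1]], bad[1], id),
          class = "coag_validation_error")
  }
  structure(list(id = id, residues = residues,
                 provenance = as.character(provenance)),
            class = "peptide_seq")
}

#' @export
print.peptide_seq <- function(x, ...) {
  cat(sprintf("<peptide_seq> %s (%d aa)\n", x$id, length(x$residues)))
  cat(" ", paste(x$residues, collapse = ""), "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.peptide_seq <- function(x) length(x$residues)

#' @export
as.character.peptide_seq <- function(x, ...) paste(x$residues, collapse = "")

#' Read and write peptide FASTA files
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()] that validate every record against the
#' canonical 20-residue alphabet and preserve record order.
#'
#' @param path File path.
#' @param seqs For `write_fasta()`, a list of [peptide_seq()] objects (or one).
#' @return `read_fasta()`: a named list of `peptide_seq`; `write_fasta()`:
#'   `path`, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "coag_io_error")
  }
  aas <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(aas), function(i) {
    peptide_seq(as.character(aas[[i]]), id = names(aas)[i])
  })
  names(out) <- names(aas)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "peptide_seq")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, as.character, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Bundled template sequences
#'
#' Returns the editable template/donor sequences shipped with the package:
#' the 29-residue human glucagon peptide and GLP-1(7-37) (31 residues, whose
#' positions 30-31 are Arg,Gly). These are data, not hard-coded truth: the
#' design rule files reference them by name but may override them.
#'
#' @return Named list of [peptide_seq()] objects.
#' @export
template_sequences <- function() {
  path <- system.file("extdata", "sequences.fasta", package = "coagdesign")
  read_fasta(path)
}
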