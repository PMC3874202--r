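## Monoisotopic mass bookkeeping for derivatized histone peptides.
## All masses in Da; reflector-mode MALDI context, so monoisotopic only.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic residue (i.e. dehydrated) masses for the 20
#' standard amino acids, in Da.
#'
#' @return Named numeric vector, one element per one-letter residue code.
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
}

MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276

## Modification mass deltas (Da): propionyl C3H4O, acetyl C2H2O, methyl CH2.
MOD_DELTAS <- c(
  prop        = 56.026215,
  ac          = 42.010565,
  me1         = 14.015650,
  "me1+prop"  = 14.015650 + 56.026215,
  me2         = 2 * 14.015650,
  me3         = 3 * 14.015650,
  none        = 0
)

#' Mass shift of a lysine/N-terminal modification state
#'
#' @param state character vector of states among `"prop"`, `"ac"`, `"me1"`,
#'   `"me1+prop"`, `"me2"`, `"me3"`, `"none"`.
#' @return Numeric vector of monoisotopic mass deltas in Da.
#' @export
mod_delta <- function(state) {
  bad <- setdiff(state, names(MOD_DELTAS))
  if (length(bad))
    stop("unknown modification state(s): ", paste(bad, collapse = ", "))
  unname(MOD_DELTAS[state])
}

#' Peptide monoisotopic mass
#'
#' Sum of residue masses plus one water; no modifications.
#'
#' @param seq single peptide string, uppercase one-letter codes.
#' @return Monoisotopic neutral mass in Da.
#' @export
#' @examples
#' peptide_mono_mass("G")  # 75.03203
peptide_mono_mass <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  res <- strsplit(seq, "")[[1]]
  masses <- residue_masses()
  bad <- setdiff(res, names(masses))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  sum(masses[res]) + MASS_WATER
}

## Mature (initiator-Met removed) S. cerevisiae core histone sequences.
## Residue 1 is the first residue after Met, matching the numbering used for
## modification sites (H4 K5/K8/K12/K16, H3 K9/K14/K23/K27/K36/K56/K79).
HISTONE_SEQS <- list(
  H4 = paste0("SGRGKGGKGLGKGGAKRHRKILRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLK",
              "VFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG"),
  H3 = paste0("ARTKQTARKSTGGKAPRKQLASKAARKSAPSTGGVKKPHRYKPGTVALREIRRFQKSTE",
              "LLIRKLPFQRLVREIAQDFKTDLRFQSSAIGALQESVEAYLVSLFEDTNLAAIHAKRVT",
              "IQKKDIKLARRLRGERS")
)

#' Built-in histone sequence
#'
#' Returns a `histone_sequence` object for budding-yeast H3 or H4 with the
#' initiator methionine removed, so residue numbers match the conventional
#' modification-site numbering.
#'
#' @param name `"H3"` or `"H4"`.
#' @return Object of class `histone_sequence`: list with `name`, `residues`
#'   and `numbering_offset` (residue number of the first character).
#' @export
#' @examples
#' substr(histone_sequence("H4")$residues, 4, 17)
histone_sequence <- function(name = c("H4", "H3")) {
  name <- match.arg(name)
  new_histone_sequence(name, HISTONE_SEQS[[name]])
}

new_histone_sequence <- function(name, residues, numbering_offset = 1L) {
  residues <- toupper(residues)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", residues))
    stop("residues must be uppercase standard one-letter amino-acid codes")
  structure(list(name = name, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "histone_sequence")
}

#' Read histone sequences from a FASTA file
#'
#' Minimal single-purpose FASTA reader for plain protein FASTA (no wrapping
#' constraints). Initiator methionine, if present, is removed so numbering
#' matches modification-site convention.
#'
#' @param path FASTA file.
#' @param strip_met drop a leading "M" from each record (default TRUE).
#' @return Named list of `histone_sequence` objects.
#' @export
read_histone_fasta <- function(path, strip_met = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "\\s+"), `[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  out <- vector("list", length(names_))
  for (i in seq_along(names_)) {
    s <- toupper(seqs[[i]])
    if (strip_met && startsWith(s, "M")) s <- substr(s, 2L, nchar(s))
    out[[i]] <- new_histone_sequence(names_[i], s)
  }
  names(out) <- names_
  out
}

#' @export
print.histone_sequence <- function(x, ...) {
  cat("histone_sequence", x$name, "-", nchar(x$residues), "aa",
      sprintf("(numbering starts at %d)\n", x$numbering_offset))
  invisible(x)
}
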