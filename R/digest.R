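# standard monoisotopic residue masses (Da); peptide mass = sum + water
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
.WATER_MONO <- 18.010565

.check_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  res <- strsplit(seq, "")[[1]]
  bad <- setdiff(res, names(.AA_MONO))
  if (length(bad)) stop("invalid residues: ", paste(bad, collapse = ", "))
  res
}

#' Trypsin cleavage rules
#'
#' Trypsin cuts after lysine (K) and arginine (R). Classic trypsin skips
#' sites followed by proline; the search rules used here allow cleavage
#' even when K/R is followed by P (`cleave_before_proline = TRUE`, the
#' default), with the classic behaviour available as a toggle.
#'
#' @param max_missed maximum number of missed cleavages per peptide.
#' @param cleave_before_proline allow cleavage when K/R precedes P.
#' @return a `cleavage_rules` list.
#' @export
cleavage_rules <- function(max_missed = 1L, cleave_before_proline = TRUE) {
  stopifnot(max_missed >= 0)
  structure(list(residues = c("K", "R"),
                 max_missed = as.integer(max_missed),
                 cleave_before_proline = isTRUE(cleave_before_proline)),
            class = "cleavage_rules")
}

#' Tryptic cleavage sites of a sequence
#'
#' Returns the positions after which the sequence is cut: every internal K
#' or R (the C-terminal residue never yields a site), dropping K/R-before-P
#' sites when `cleave_before_proline` is off.
#'
#' @param seq amino-acid sequence (single string).
#' @param rules a [cleavage_rules()] object.
#' @return integer vector of cleavage positions (cut after these indices).
#' @export
cleavage_sites <- function(seq, rules = cleavage_rules()) {
  res <- .check_seq(seq)
  n <- length(res)
  if (n < 2) return(integer(0))
  sites <- which(res[-n] %in% rules$residues)
  if (!rules$cleave_before_proline) {
    sites <- sites[res[sites + 1L] != "P"]
  }
  sites
}

#' In-silico tryptic digestion
#'
#' Enumerates every peptide with 0 to `max_missed` internal missed
#' cleavages. With `s` internal sites and `max_missed = 1` this yields
#' `(s + 1) + s` peptides. Peptide coordinates are reported in reference
#' numbering via `numbering_offset` (the reference index of residue 1), so
#' that expression constructs report full-length protein positions.
#'
#' @param seq amino-acid sequence (single string).
#' @param rules a [cleavage_rules()] object.
#' @param numbering_offset reference index of the first residue (default 1).
#' @return data.frame with columns `start`, `end` (reference numbering,
#'   1-based inclusive), `sequence`, `missed_cleavages`,
#'   `monoisotopic_mass`, `n_cys`, and list-column `cys_positions`
#'   (reference indices of cysteines).
#' @export
digest <- function(seq, rules = cleavage_rules(), numbering_offset = 1L) {
  res <- .check_seq(seq)
  n <- length(res)
  sites <- cleavage_sites(seq, rules)
  bounds <- c(0L, sites, n)              # piece i = (bounds[i]+1)..bounds[i+1]
  n_pieces <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(n_pieces)) {
    for (m in 0:min(rules$max_missed, n_pieces - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + m]
      pep <- substr(seq, s, e)
      cys <- s - 1L + which(res[s:e] == "C")
      out[[length(out) + 1L]] <- data.frame(
        start = s + numbering_offset - 1L,
        end = e + numbering_offset - 1L,
        sequence = pep,
        missed_cleavages = m,
        monoisotopic_mass = monoisotopic_mass(pep),
        n_cys = length(cys)
      )
      out[[length(out)]]$cys_positions <-
        list(cys + numbering_offset - 1L)
    }
  }
  do.call(rbind, out)
}

#' Monoisotopic peptide mass
#'
#' Sum of the standard monoisotopic residue masses plus one water
#' (18.010565 Da). No fixed modifications are applied (in particular no
#' cysteine carbamidomethylation; the workflow reduces with TCEP and has
#' no alkylation step).
#'
#' @param peptide amino-acid sequence(s).
#' @return monoisotopic mass in Da (vectorized).
#' @export
monoisotopic_mass <- function(peptide) {
  vapply(peptide, function(p) {
    res <- .check_seq(p)
    sum(.AA_MONO[res]) + .WATER_MONO
  }, numeric(1), USE.NAMES = FALSE)
}

#' Candidate masses of cysteine covalent adducts
#'
#' Variable-modification semantics: a peptide with `k` cysteines yields,
#' for each ligand, the candidate masses `base + 0..k * delta`, covering
#' every possible number of covalently modified cysteines.
#'
#' @param base_mass unmodified peptide monoisotopic mass (Da).
#' @param n_cys number of cysteines in the peptide.
#' @param ligand_deltas named numeric vector of ligand adduct mass shifts
#'   (Da).
#' @return named list: ligand -> numeric vector of candidate masses.
#' @export
enumerate_cys_adducts <- function(base_mass, n_cys, ligand_deltas) {
  stopifnot(base_mass > 0, n_cys >= 0, all(is.finite(ligand_deltas)))
  lapply(as.list(ligand_deltas), function(delta) {
    base_mass + (0:n_cys) * delta
  })
}

#' Precursor-mass match at ppm tolerance
#'
#' A candidate matches an observed mass iff
#' `|observed - candidate| / candidate * 1e6 <= tol_ppm`.
#'
#' @param observed observed precursor mass (Da).
#' @param candidates candidate masses (Da).
#' @param tol_ppm relative tolerance in parts per million (default 10).
#' @return logical vector over `candidates`.
#' @export
ppm_match <- function(observed, candidates, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  abs(observed - candidates) / candidates * 1e6 <= tol_ppm
}

#' Reference positions of cysteines in a digest peptide span
#'
#' Verifies that the given span (in reference numbering) is producible by
#' the digestion rules and returns the reference positions of its cysteine
#' residues — the covalent-modification site candidates for that peptide.
#'
#' @param seq amino-acid sequence (single string).
#' @param rules a [cleavage_rules()] object.
#' @param span integer (start, end) in reference numbering.
#' @param numbering_offset reference index of the first residue.
#' @return integer vector of cysteine reference positions (possibly empty).
#' @export
locate_modified_cysteine <- function(seq, rules = cleavage_rules(),
                                     span, numbering_offset = 1L) {
  stopifnot(length(span) == 2L, span[2] >= span[1])
  peps <- digest(seq, rules, numbering_offset = numbering_offset)
  hit <- peps$start == span[1] & peps$end == span[2]
  if (!any(hit)) {
    stop("span ", span[1], "-", span[2],
         " is not a digest peptide under these rules")
  }
  peps$cys_positions[[which(hit)[1]]]
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file path.
#' @param which record index (default first).
#' @return a single character string.
#' @export
read_protein_fasta <- function(path, which = 1L) {
  aa <- Biostrings::readAAStringSet(path)
  as.character(aa[[which]])
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
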