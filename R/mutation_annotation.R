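# Cross-species mutation interpretation: residue mapping between ortholog
# proteins by global alignment, beta-catenin phosphodegron flagging, and
# premature stop detection in intron-retaining transcripts.
#
# Coordinates are 1-based on the ungapped protein / CDS throughout, matching
# the conventional numbering of mutations such as CTNNB1 S45 or TP53 R175.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

check_protein <- function(seq, arg) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(sprintf("`%s` must be a non-empty protein sequence string", arg),
         call. = FALSE)
  chars <- strsplit(toupper(seq), "")[[1L]]
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad))
    stop(sprintf("invalid amino acid '%s' at position %d of `%s`",
                 chars[bad[[1L]]], bad[[1L]], arg), call. = FALSE)
  paste(chars, collapse = "")
}

#' Global protein alignment with residue correspondence map
#'
#' Needleman-Wunsch global alignment with affine gaps (via
#' `Biostrings::pairwiseAlignment`), defaulting to BLOSUM62 with gap open 10
#' and gap extend 0.5 -- standard protein-alignment parameters. The result
#' carries a per-position correspondence map between the two ungapped
#' sequences, the substrate for cross-species residue equivalence (e.g.
#' relating a canine TP53 mutation position to its human counterpart).
#'
#' @param seq_a,seq_b Protein sequences (strings over the 20 amino acids).
#' @param substitution_matrix Name of the substitution matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return List of class `protein_alignment`: `aligned_a`, `aligned_b`
#'   (gapped strings), `map_ab` (integer vector over A positions; `NA` where
#'   A faces a gap), `map_ba` (the reverse map), `score`, `parameters`.
#' @export
align_proteins <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  seq_a <- check_protein(seq_a, "seq_a")
  seq_b <- check_protein(seq_b, "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  stopifnot(length(pa) == length(pb))
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  map_ab <- rep(NA_integer_, nchar(seq_a))
  map_ba <- rep(NA_integer_, nchar(seq_b))
  map_ab[ia[both]] <- ib[both]
  map_ba[ib[both]] <- ia[both]
  structure(list(aligned_a = paste(pa, collapse = ""),
                 aligned_b = paste(pb, collapse = ""),
                 map_ab = map_ab, map_ba = map_ba,
                 score = Biostrings::score(aln),
                 parameters = list(substitution_matrix = substitution_matrix,
                                   gap_open = gap_open,
                                   gap_extend = gap_extend)),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: score %.1f, %d/%d A positions mapped\n",
              x$score, sum(!is.na(x$map_ab)), length(x$map_ab)))
  invisible(x)
}

#' Map a residue position through an alignment
#'
#' @param alignment A `protein_alignment` from [align_proteins()].
#' @param position_in_a 1-based position in the ungapped A sequence.
#' @return The 1-based partner position in B, or the string `"gapped"` if
#'   A's residue faces a gap.
#' @export
map_residue <- function(alignment, position_in_a) {
  stopifnot(inherits(alignment, "protein_alignment"))
  check_count(position_in_a, "position_in_a")
  if (position_in_a > length(alignment$map_ab))
    stop("position exceeds the length of sequence A", call. = FALSE)
  p <- alignment$map_ab[[position_in_a]]
  if (is.na(p)) "gapped" else p
}

#' The beta-catenin N-terminal phosphodegron
#'
#' The destruction motif `D(32)pS(33)G(34)-phi-X-pS(37)` plus the upstream
#' CK1/GSK3 priming cascade (T41, S45) of the CTNNB1 N-terminal peptide:
#' phosphorylation of the Ser/Thr residues initiates beta-catenin
#' ubiquitination by beta-TrCP1 and degradation. Mutations at these
#' positions (e.g. S45F/P, D32Y, G34E) stabilize beta-catenin and act as
#' WNT-pathway-activating drivers. T41 carries its canonical role in the
#' phosphorylation cascade even though it is an interpretive addition to the
#' positions with reported tumor mutations.
#'
#' @return A list of class `degron_spec`: `gene`, `motif`, `positions`
#'   (named integer vector), `roles` (same names).
#' @export
ctnnb1_degron <- function() {
  pos <- c(D32 = 32L, S33 = 33L, G34 = 34L, S37 = 37L, T41 = 41L, S45 = 45L)
  roles <- c(D32 = "motif-structural", S33 = "phospho-acceptor",
             G34 = "motif-structural", S37 = "phospho-acceptor",
             T41 = "phospho-acceptor", S45 = "priming-phospho")
  structure(list(gene = "CTNNB1",
                 motif = "DpSG-phi-X-pS destruction motif + CK1/GSK3 cascade",
                 positions = pos, roles = roles),
            class = "degron_spec")
}

#' Flag a mutation against a phosphodegron spec
#'
#' Classifies a protein mutation by position: a spec critical position is
#' flagged `"degron-disrupting"` with that position's role; a position
#' inside the motif span but non-critical is `"motif-adjacent"`; anything
#' else is `"outside"`. Only the position enters the call -- the identity of
#' the alternate residue is not modeled (a documented limitation: a
#' conservative substitution at a critical site is still flagged).
#'
#' @param gene Gene symbol of the mutation.
#' @param position 1-based protein position.
#' @param ref,alt Reference/alternate residues (1-letter); checked for
#'   validity, `ref != alt`.
#' @param spec A `degron_spec`, default [ctnnb1_degron()].
#' @return List: `status` ("degron-disrupting" / "motif-adjacent" /
#'   "outside"), `role` (`NA` unless disrupting), `position`.
#' @export
#' @examples
#' flag_degron_mutation("CTNNB1", 45, "S", "F")$status  # degron-disrupting
#' flag_degron_mutation("CTNNB1", 60, "T", "S")$status  # outside
flag_degron_mutation <- function(gene, position, ref, alt,
                                 spec = ctnnb1_degron()) {
  stopifnot(inherits(spec, "degron_spec"))
  if (!identical(toupper(gene), toupper(spec$gene)))
    stop("mutation gene '", gene, "' does not match spec gene '", spec$gene,
         "'", call. = FALSE)
  check_count(position, "position")
  for (r in c(ref, alt))
    if (!toupper(r) %in% AA_LETTERS)
      stop("invalid residue: ", r, call. = FALSE)
  if (toupper(ref) == toupper(alt))
    stop("`ref` and `alt` must differ", call. = FALSE)
  if (position %in% spec$positions) {
    nm <- names(spec$positions)[match(position, spec$positions)]
    list(status = "degron-disrupting", role = unname(spec$roles[[nm]]),
         position = position)
  } else if (position >= min(spec$positions) && position <= max(spec$positions)) {
    list(status = "motif-adjacent", role = NA_character_, position = position)
  } else {
    list(status = "outside", role = NA_character_, position = position)
  }
}

#' Detect premature stop codons in a CDS with a retained intron
#'
#' Scans the sequence codon by codon in the given reading frame and reports
#' every in-frame stop codon (TAA, TAG, TGA) occurring before the canonical
#' stop -- by default the final in-frame stop when the sequence ends in one,
#' otherwise the scan end. Intron retention typically injects such stops and
#' truncates the protein.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param frame_offset 0, 1 or 2: number of bases skipped before the first
#'   codon.
#' @param canonical_stop Optional 1-based nucleotide position of the
#'   canonical stop codon's first base; stops at or after it are not
#'   premature. Default: the last complete in-frame codon if it is a stop.
#' @return List: `positions` (1-based first-base positions of premature
#'   stops), `truncation_codons` (number of codons translated before the
#'   first premature stop; `NA` if none).
#' @export
detect_premature_stops <- function(sequence, frame_offset = 0,
                                   canonical_stop = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("`sequence` must be a single DNA string", call. = FALSE)
  if (!frame_offset %in% 0:2) stop("`frame_offset` must be 0, 1 or 2", call. = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[[1L]]],
                 bad[[1L]]), call. = FALSE)
  starts <- as.integer(seq(1L + frame_offset, length(chars) - 2L, by = 3L))
  if (!length(starts)) return(list(positions = integer(), truncation_codons = NA_integer_))
  codons <- vapply(starts, function(s) paste(chars[s:(s + 2L)], collapse = ""), "")
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  stop_pos <- starts[is_stop]
  if (is.null(canonical_stop)) {
    last <- starts[length(starts)]
    canonical_stop <- if (length(stop_pos) && stop_pos[length(stop_pos)] == last)
      last else last + 3L
  }
  premature <- stop_pos[stop_pos < canonical_stop]
  trunc <- if (length(premature))
    as.integer((premature[[1L]] - 1L - frame_offset) / 3L) else NA_integer_
  list(positions = premature, truncation_codons = trunc)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` returning plain character
#' strings named by record id.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
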