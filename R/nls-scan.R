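#' Scan a protein sequence for the classical monopartite NLS consensus
#'
#' Reports every 4-residue window matching K-(K/R)-X-(K/R): position 1 is
#' lysine, positions 2 and 4 are lysine or arginine, position 3 is any of
#' the 20 residues (including K/R). Overlapping matches are all reported,
#' in ascending start coordinate. Coordinates are 1-based, inclusive, in
#' full-protein numbering (via the sequence anchor).
#'
#' @param seq a [ProteinSequence-class] object.
#' @return a data.frame with columns `seq_id`, `start`, `end`, `matched`,
#'   `pattern_id` (zero rows when there is no match). `end = start + 3`
#'   always.
#' @examples
#' scanMonopartiteNLS(ProteinSequence("DEQVKKRKLDY", anchor = 777))
#' @export
scanMonopartiteNLS <- function(seq) {
  stopifnot(is(seq, "ProteinSequence"))
  validObject(seq)
  res <- seq@residues
  n <- nchar(res)
  emptyHits <- data.frame(
    seq_id = character(), start = integer(), end = integer(),
    matched = character(), pattern_id = character(),
    stringsAsFactors = FALSE
  )
  if (n < 4L) return(emptyHits)
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  basic <- chars %in% c("K", "R")
  starts <- which(
    chars[seq_len(n - 3L)] == "K" &
      basic[seq_len(n - 3L) + 1L] &
      basic[seq_len(n - 3L) + 3L]
  )
  if (!length(starts)) return(emptyHits)
  data.frame(
    seq_id = rep(seq@id, length(starts)),
    start = seq@anchor + starts - 1L,
    end = seq@anchor + starts + 2L,
    matched = substring(res, starts, starts + 3L),
    pattern_id = "K-(K/R)-X-(K/R)",
    stringsAsFactors = FALSE
  )
}

# Convert a full-protein coordinate to a local string offset, checking range.
localIndex <- function(seq, coord) {
  i <- coord - seq@anchor + 1L
  if (i < 1L || i > nchar(seq@residues)) {
    stop(sprintf(
      "coordinate %d outside sequence [%d, %d]",
      coord, seq@anchor, seq@anchor + nchar(seq@residues) - 1L
    ), call. = FALSE)
  }
  i
}

#' Delete a residue segment (full-protein coordinates, inclusive)
#'
#' Excises residues `[start, end]`; the anchor is unchanged, so residues
#' upstream of the deletion keep their full-protein coordinates. Used to
#' build deletion alleles such as the KKRK-core deletion.
#'
#' @param seq a [ProteinSequence-class] object.
#' @param start,end 1-based full-protein coordinates, `start <= end`.
#' @return a new [ProteinSequence-class], shorter by `end - start + 1`.
#' @examples
#' deleteSegment(ProteinSequence("DEQVKKRKLDY", anchor = 777), 781, 784)
#' @export
deleteSegment <- function(seq, start, end) {
  stopifnot(is(seq, "ProteinSequence"))
  if (end < start) stop("need start <= end", call. = FALSE)
  i <- localIndex(seq, start)
  j <- localIndex(seq, end)
  res <- paste0(
    substr(seq@residues, 1L, i - 1L),
    substr(seq@residues, j + 1L, nchar(seq@residues))
  )
  new("ProteinSequence", id = seq@id, residues = res, anchor = seq@anchor)
}

#' Append a residue segment to the carboxyl terminus
#'
#' Fuses `tail` to the end of the sequence, as when adding the SV40
#' T-antigen NLS to a deletion allele.
#'
#' @param seq a [ProteinSequence-class] object.
#' @param tail amino-acid string (may be empty).
#' @return a new [ProteinSequence-class] of additive length.
#' @export
appendSegment <- function(seq, tail) {
  stopifnot(is(seq, "ProteinSequence"), is.character(tail), length(tail) == 1L)
  if (grepl("[a-z]", tail)) {
    warning("lower-case residues upper-cased", call. = FALSE)
    tail <- toupper(tail)
  }
  if (nchar(tail) > 0L) {
    chars <- strsplit(tail, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% AA_ALPHABET_20)
    if (length(bad)) {
      stop(sprintf("invalid residue '%s' at tail position %d", chars[bad[1L]], bad[1L]),
           call. = FALSE)
    }
  }
  new("ProteinSequence", id = seq@id,
      residues = paste0(seq@residues, tail), anchor = seq@anchor)
}

#' Read protein sequences from FASTA
#'
#' Record descriptions may carry an `anchor=<int>` key
#' (e.g. `>cand1 anchor=777`) giving the full-protein coordinate of the
#' first residue; records without one default to anchor 1.
#'
#' @param path FASTA file.
#' @return a list of [ProteinSequence-class] objects.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  lapply(seq_along(aa), function(i) {
    header <- names(aa)[i]
    id <- strsplit(header, "\\s+")[[1L]][1L]
    anchor <- 1L
    m <- regmatches(header, regexpr("anchor=\\d+", header))
    if (length(m) && nzchar(m)) anchor <- as.integer(sub("anchor=", "", m))
    ProteinSequence(as.character(aa[[i]]), id = id, anchor = anchor)
  })
}

#' Write protein sequences to FASTA
#'
#' The anchor is recorded in the description as `anchor=<int>`.
#'
#' @param seqs a list of [ProteinSequence-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is(seqs, "ProteinSequence")) seqs <- list(seqs)
  aa <- Biostrings::AAStringSet(vapply(seqs, function(s) s@residues, ""))
  names(aa) <- vapply(seqs, function(s) {
    sprintf("%s anchor=%d", if (is.na(s@id)) "seq" else s@id, s@anchor)
  }, "")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
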