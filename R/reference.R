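#' Rotated mitochondrial reference
#'
#' nCATS sequencing linearizes the circular mitochondrial genome at the Cas9
#' cut site, so reads start near the cut and never wrap the origin of the
#' standard (rCRS-style) coordinate frame. To align and call deletions without
#' artifactual junctions at position 1, the reference is re-origined ("rotated")
#' at the cut site: the bases before the cut are moved to the end of the
#' sequence. For the human chrM reference the cut falls after base 1547, so the
#' rotated sequence begins at standard position 1548.
#'
#' @param sequence reference sequence: a single character string, a
#'   [Biostrings::DNAString], or a length-1 [Biostrings::DNAStringSet].
#' @param rotation_offset number of leading standard-frame bases moved to the
#'   end of the sequence (default 1547, the human mtDNA Cas9 cut site used
#'   throughout the package).
#' @param name contig name recorded for SAM/FASTA output.
#'
#' @return An object of class `rotated_reference`: a list with elements
#'   `name`, `sequence` (rotated frame, character), `length`, and `offset`.
#' @examples
#' ref <- rotate_reference("ACGTACGTACGT", rotation_offset = 3)
#' ref$sequence  # "TACGTACGTACG"
#' @export
rotate_reference <- function(sequence, rotation_offset = 1547L,
                             name = "chrM_rotated") {
  sequence <- .as_sequence_string(sequence)
  L <- nchar(sequence)
  if (L < 2L)
    stop("reference sequence must contain at least 2 bases")
  if (!grepl("^[ACGTUMRWSYKVHDBN]+$", toupper(sequence)))
    stop("reference sequence contains non-IUPAC characters")
  rotation_offset <- .as_count(rotation_offset, "rotation_offset")
  if (rotation_offset < 1L || rotation_offset >= L)
    stop("rotation_offset must satisfy 1 <= offset < length(sequence)")
  rotated <- paste0(substr(sequence, rotation_offset + 1L, L),
                    substr(sequence, 1L, rotation_offset))
  structure(
    list(name = name, sequence = toupper(rotated), length = L,
         offset = as.integer(rotation_offset)),
    class = "rotated_reference"
  )
}

#' Wrap an already-rotated sequence
#'
#' For input that was rotated upstream (e.g. a rotated FASTA written by a
#' previous run): records the sequence as-is together with the offset used
#' to produce it, so coordinate maps work without rotating again.
#'
#' @inheritParams rotate_reference
#' @param sequence the rotated-frame sequence.
#' @return A `rotated_reference`.
#' @export
rotated_reference <- function(sequence, rotation_offset = 1547L,
                              name = "chrM_rotated") {
  sequence <- toupper(.as_sequence_string(sequence))
  L <- nchar(sequence)
  rotation_offset <- .as_count(rotation_offset, "rotation_offset")
  if (rotation_offset < 1L || rotation_offset >= L)
    stop("rotation_offset must satisfy 1 <= offset < length(sequence)")
  structure(list(name = name, sequence = sequence, length = L,
                 offset = rotation_offset),
            class = "rotated_reference")
}

#' @export
print.rotated_reference <- function(x, ...) {
  cat(sprintf("rotated_reference '%s': %d bp, rotation offset %d\n",
              x$name, x$length, x$offset))
  invisible(x)
}

.as_sequence_string <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) {
    if (length(sequence) != 1L)
      stop("expected a single reference sequence")
    sequence <- sequence[[1L]]
  }
  if (inherits(sequence, "DNAString"))
    sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string or DNAString")
  sequence
}

.as_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    stop(sprintf("%s must be a single integer", what))
  as.integer(x)
}

#' Read a reference genome from FASTA
#'
#' Reads the first (and only expected) record of a FASTA file.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] of length 1.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("no sequences found in ", path)
  if (length(seqs) > 1L)
    warning("multiple sequences in ", path, "; using the first")
  seqs[1L]
}

#' Write the rotated reference as FASTA
#'
#' The rotated FASTA is what external long-read aligners (e.g. minimap2)
#' should be given so that their output matches the coordinate frame of the
#' deletion callers.
#'
#' @param ref a `rotated_reference`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "rotated_reference"))
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$name
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Convert rotated-frame positions to the standard frame
#'
#' Positions are 1-based in both frames. Rotated position 1 corresponds to
#' standard position `offset + 1` (1548 for the human default).
#'
#' @param pos integer vector of rotated-frame positions in `[1, L]`.
#' @param ref a `rotated_reference` (or a list with `length` and `offset`).
#' @return integer vector of standard-frame positions.
#' @seealso [std_to_rot()]
#' @export
rot_to_std <- function(pos, ref) {
  L <- ref$length; off <- ref$offset
  .check_positions(pos, L)
  ifelse(pos <= L - off, pos + off, pos - (L - off))
}

#' Convert standard-frame positions to the rotated frame
#'
#' Inverse of [rot_to_std()].
#'
#' @inheritParams rot_to_std
#' @param pos integer vector of standard-frame positions in `[1, L]`.
#' @return integer vector of rotated-frame positions.
#' @export
std_to_rot <- function(pos, ref) {
  L <- ref$length; off <- ref$offset
  .check_positions(pos, L)
  ifelse(pos > off, pos - off, pos + (L - off))
}

.check_positions <- function(pos, L) {
  if (!is.numeric(pos) || any(is.na(pos)))
    stop("positions must be non-missing numbers")
  if (any(pos < 1L | pos > L))
    stop(sprintf("positions must lie in [1, %d]", L))
  invisible(TRUE)
}

#' Minor/major arc model of the mitochondrial genome
#'
#' The two origins of replication split the mitochondrial circle into the
#' "minor arc" (standard positions 408-5746 for human mtDNA) and the "major
#' arc" (5747 wrapping through the origin to 407). Because deletion calls are
#' made in the rotated frame, the model precomputes the rotated-frame
#' interval(s) covered by each arc; with the default cut site (offset 1547)
#' inside the minor arc, the rotated minor arc is split into two intervals
#' and the major arc is a single interval.
#'
#' @param ref a `rotated_reference`.
#' @param minor_start,minor_end standard-frame bounds of the minor arc
#'   (defaults 408 and 5746, human mtDNA).
#' @return An object of class `arc_model`: list with `minor` and `major`,
#'   each a two-column matrix of rotated-frame closed intervals, plus the
#'   standard-frame bounds.
#' @export
arc_model <- function(ref, minor_start = 408L, minor_end = 5746L) {
  L <- ref$length; off <- ref$offset
  minor_start <- .as_count(minor_start, "minor_start")
  minor_end <- .as_count(minor_end, "minor_end")
  if (!(minor_start >= 1L && minor_start < minor_end && minor_end <= L))
    stop("invalid minor arc bounds")
  minor <- .std_interval_to_rot(minor_start, minor_end, L, off)
  # major arc = complement of the minor arc on the circle, as rotated intervals
  cov <- rep(TRUE, L)
  for (i in seq_len(nrow(minor))) cov[minor[i, 1]:minor[i, 2]] <- FALSE
  major <- .runs_to_intervals(cov)
  structure(list(minor = minor, major = major,
                 minor_start = minor_start, minor_end = minor_end),
            class = "arc_model")
}

# map a standard-frame closed interval into rotated-frame interval(s);
# the rotation cut between std positions `off` and `off + 1` may split it
.std_interval_to_rot <- function(s, e, L, off) {
  pieces <- list()
  if (s <= off)
    pieces <- c(pieces, list(c(s, min(e, off)) + (L - off)))
  if (e > off)
    pieces <- c(pieces, list(c(max(s, off + 1L), e) - off))
  m <- do.call(rbind, pieces)
  m[order(m[, 1]), , drop = FALSE]
}

.runs_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Classify a deletion as minor-arc, major-arc, or both
#'
#' A deletion is `"minor"` if all deleted bases fall inside a single
#' rotated-frame minor-arc interval, `"major"` if inside a single major-arc
#' interval, and `"both"` otherwise. Deletion intervals are half-open
#' `[start, end)` in the rotated frame (the deleted bases are
#' `start .. end - 1`); rotated-frame deletions never wrap because molecules
#' are linearized at the cut site.
#'
#' @param del_start_rot,del_end_rot integer vectors, rotated-frame half-open
#'   deletion bounds with `start < end`.
#' @param arc an `arc_model`.
#' @return character vector in `c("minor", "major", "both")`.
#' @export
classify_arc <- function(del_start_rot, del_end_rot, arc) {
  stopifnot(inherits(arc, "arc_model"))
  if (length(del_start_rot) != length(del_end_rot))
    stop("start and end vectors must have equal length")
  if (any(del_start_rot >= del_end_rot))
    stop("deletion start must be < end")
  lo <- del_start_rot
  hi <- del_end_rot - 1L  # last deleted base
  inside <- function(iv) {
    hit <- rep(FALSE, length(lo))
    for (i in seq_len(nrow(iv)))
      hit <- hit | (lo >= iv[i, 1] & hi <= iv[i, 2])
    hit
  }
  out <- rep("both", length(lo))
  out[inside(arc$minor)] <- "minor"
  out[inside(arc$major)] <- "major"
  out
}
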