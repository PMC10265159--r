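#' Write simulated reads as a SAM fixture
#'
#' Emits one idealized alignment per truth row against the rotated reference,
#' so the deletion callers can be exercised without an external aligner.
#' Deletion-spanning reads are written either as
#'
#' * `cigar_D`: a single primary record whose CIGAR carries the deletion as a
#'   `D` run (`<a>M<size>D<b>M`), or
#' * `chimeric`: a primary plus one flag-2048 supplementary record split at
#'   the junction, query-contiguous (gap 0) but reference-distant, with the
#'   longer piece as the primary (soft clip on the primary, hard clip on the
#'   supplementary, as long-read aligners emit), or
#' * `mixed`: per read, chimeric with probability
#'   `plogis((size - split_midpoint) / split_scale)` and `cigar_D` otherwise.
#'   This emulates the empirical behaviour of long-read aligners, which
#'   represent small deletions inside the primary CIGAR but report large ones
#'   as chimeric alignments. The split decision for read ordinal j uses one
#'   uniform draw shared across templates (paired with the read geometry of
#'   [simulate_reads()]), so the fraction of D-encoded junctions is exactly
#'   non-increasing in deletion size.
#'
#' Reads that do not span a junction become single full-span `M` records.
#' Records use forward-frame coordinates with flag 16 set for reverse-strand
#' reads; SEQ and QUAL are omitted (`*`), since the callers operate on
#' coordinates and CIGARs.
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param ref the [rotate_reference()] the templates were built from.
#' @param style `"cigar_D"`, `"chimeric"` or `"mixed"`.
#' @param split_midpoint,split_scale logistic parameters of the mixed-style
#'   split probability, in bp (defaults 3000 and 1200).
#' @param seed seed for the mixed-style split draws.
#' @param path if non-NULL, the SAM text is written there.
#' @return character vector of SAM lines, invisibly if `path` is given.
#' @export
write_sam_fixture <- function(truth, ref,
                              style = c("cigar_D", "chimeric", "mixed"),
                              split_midpoint = 3000, split_scale = 1200,
                              seed = 1L, path = NULL) {
  style <- match.arg(style)
  stopifnot(inherits(ref, "rotated_reference"))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length))
  u <- NULL
  if (style == "mixed") {
    u <- .with_seed(seed, stats::runif(max(truth$read_index)))
  }
  recs <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    flag_strand <- if (tr$strand == "-") 16L else 0L
    if (!isTRUE(tr$contains_deletion)) {
      # clean single-segment alignment; map template coords to reference
      pos <- if (tr$del_size > 0L && tr$read_start >= tr$del_start)
        tr$read_start + tr$del_size else tr$read_start
      recs[[i]] <- .sam_line(tr$read_id, flag_strand, ref$name, pos,
                             sprintf("%dM", tr$span_tpl))
      next
    }
    a <- tr$del_start - tr$read_start            # bases before the junction
    b <- tr$read_start + tr$span_tpl - tr$del_start  # bases after it
    as_split <- switch(style,
      cigar_D = FALSE,
      chimeric = TRUE,
      mixed = u[tr$read_index] <
        stats::plogis((tr$del_size - split_midpoint) / split_scale))
    if (!as_split) {
      recs[[i]] <- .sam_line(
        tr$read_id, flag_strand, ref$name, tr$read_start,
        sprintf("%dM%dD%dM", a, tr$del_size, b))
    } else {
      pos_left <- tr$read_start
      pos_right <- tr$del_start + tr$del_size
      if (a >= b) {  # left piece is the primary
        recs[[i]] <- c(
          .sam_line(tr$read_id, flag_strand, ref$name, pos_left,
                    sprintf("%dM%dS", a, b)),
          .sam_line(tr$read_id, flag_strand + 2048L, ref$name, pos_right,
                    sprintf("%dH%dM", a, b)))
      } else {
        recs[[i]] <- c(
          .sam_line(tr$read_id, flag_strand, ref$name, pos_right,
                    sprintf("%dS%dM", a, b)),
          .sam_line(tr$read_id, flag_strand + 2048L, ref$name, pos_left,
                    sprintf("%dM%dH", a, b)))
      }
    }
  }
  lines <- c(header, unlist(recs))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.sam_line <- function(qname, flag, rname, pos, cigar, mapq = 60L) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L, "*", "*",
        sep = "\t")
}
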