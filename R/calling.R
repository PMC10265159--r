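#' Deletion caller thresholds
#'
#' All thresholds of the three deletion callers in one object. Defaults are
#' the operating point used throughout the package: deletions must be
#' strictly larger than 100 bp; candidate deletions on one read within
#' 300 bp are merged; chimeric segments must each exceed 200 bp, be
#' query-contiguous within 300 bp, overlap by less than 50 bp on query and
#' reference, and be separated on the reference by more than `min_ref_gap`
#' (set to `min_deletion` so chimeric calls obey the same size floor as
#' CIGAR calls); realignment is triggered when read length and aligned
#' length disagree by more than 500 bp.
#'
#' @param min_deletion minimum deletion size, strict, bp.
#' @param merge_window merge distance for candidate deletions on a read, bp.
#' @param min_segment minimum query span of each chimeric segment, strict, bp.
#' @param max_query_gap maximum query gap between paired segments, bp.
#' @param max_overlap maximum query/reference overlap of paired segments,
#'   strict, bp.
#' @param realign_trigger read-vs-aligned length divergence that triggers
#'   local realignment, strict, bp.
#' @param min_ref_gap minimum reference gap ("distant on the reference"),
#'   strict, bp; defaults to `min_deletion`.
#' @param min_align_score minimum local-alignment score for the realignment
#'   caller.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(min_deletion = 100L, merge_window = 300L,
                          min_segment = 200L, max_query_gap = 300L,
                          max_overlap = 50L, realign_trigger = 500L,
                          min_ref_gap = min_deletion,
                          min_align_score = 100) {
  p <- list(min_deletion = min_deletion, merge_window = merge_window,
            min_segment = min_segment, max_query_gap = max_query_gap,
            max_overlap = max_overlap, realign_trigger = realign_trigger,
            min_ref_gap = min_ref_gap, min_align_score = min_align_score)
  if (any(unlist(p) < 0)) stop("caller thresholds must be nonnegative")
  structure(p, class = "caller_params")
}

.empty_calls <- function() {
  data.frame(sample_id = character(0), read_id = character(0),
             start_rot = integer(0), end_rot = integer(0),
             size = integer(0), source = character(0),
             stringsAsFactors = FALSE)
}

.calls_df <- function(read_id, start_rot, end_rot, source,
                      sample_id = NA_character_) {
  n <- length(start_rot)
  data.frame(sample_id = rep_len(sample_id, n),
             read_id = rep_len(read_id, n),
             start_rot = as.integer(start_rot),
             end_rot = as.integer(end_rot),
             size = as.integer(end_rot - start_rot),
             source = rep_len(source, n), stringsAsFactors = FALSE)
}

#' Call deletions from a primary alignment's CIGAR
#'
#' Every `D` run strictly longer than `min_deletion` becomes a candidate
#' deletion at its reference interval; candidates on the same read whose
#' reference gap is at most `merge_window` are combined into a single
#' deletion event spanning from the first candidate's start to the last
#' candidate's end.
#'
#' Calls are reported 1-based half-open in the rotated frame:
#' `start_rot` is the first deleted base, `end_rot` the first retained base,
#' `size = end_rot - start_rot`.
#'
#' @param segment a 1-row segment data.frame (see [load_alignments()]) or a
#'   list with `read_id`, `cigar`, `ref_start`.
#' @param params a [caller_params()].
#' @return data.frame of deletion calls with `source = "primary_cigar"`.
#' @export
call_primary_cigar <- function(segment, params = caller_params()) {
  call_primary_cigar_all(
    data.frame(read_id = segment$read_id, cigar = segment$cigar,
               ref_start = segment$ref_start, stringsAsFactors = FALSE),
    params)
}

#' @describeIn call_primary_cigar vectorized over a segment table (rows must
#'   be primary alignments).
#' @param segments data.frame with columns `read_id`, `cigar`, `ref_start`.
#' @export
call_primary_cigar_all <- function(segments, params = caller_params()) {
  if (nrow(segments) == 0L) return(.empty_calls())
  d_runs <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    segments$cigar, pos = segments$ref_start, ops = "D")
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    r <- d_runs[[i]]
    r <- r[IRanges::width(r) > params$min_deletion]
    if (length(r) == 0L) next
    r <- IRanges::reduce(r, min.gapwidth = params$merge_window + 1L)
    out[[i]] <- .calls_df(segments$read_id[i], IRanges::start(r),
                          IRanges::end(r) + 1L, "primary_cigar")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(.empty_calls())
  do.call(rbind, out)
}

#' Call deletions from chimeric primary/supplementary alignment pairs
#'
#' Segments of one read are ordered along the query; each adjacent pair
#' (in either primary/supplementary order) is tested against the pairing
#' rules: both query spans strictly greater than `min_segment`; query gap in
#' `(-max_overlap, max_query_gap]`; reference overlap strictly less than
#' `max_overlap`; same strand; and, taking the pair in reference order, a
#' reference gap strictly greater than `min_ref_gap`. A passing pair yields
#' one deletion spanning the reference interval between the left segment's
#' end and the right segment's start.
#'
#' @param bundle a `read_bundle` from [bundle_reads()] with at least one
#'   supplementary alignment.
#' @param params a [caller_params()].
#' @return data.frame of deletion calls with `source = "chimeric"`.
#' @export
call_chimeric <- function(bundle, params = caller_params()) {
  segs <- rbind(bundle$primary, bundle$supplementaries)
  if (nrow(segs) < 2L) return(.empty_calls())
  segs <- segs[order(segs$query_start, segs$query_end), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(segs) - 1L)) {
    a <- segs[i, ]; b <- segs[i + 1L, ]
    call <- .pair_deletion(a, b, params)
    if (!is.null(call))
      out[[length(out) + 1L]] <- .calls_df(bundle$read_id, call[1L],
                                           call[2L], "chimeric")
  }
  if (length(out) == 0L) return(.empty_calls())
  do.call(rbind, out)
}

# apply the pairing predicates to two query-ordered segments; returns
# c(start_rot, end_rot) (half-open) or NULL
.pair_deletion <- function(a, b, params) {
  span_a <- a$query_end - a$query_start + 1L
  span_b <- b$query_end - b$query_start + 1L
  if (!(span_a > params$min_segment && span_b > params$min_segment))
    return(NULL)
  if (a$strand != b$strand) return(NULL)
  qgap <- b$query_start - a$query_end - 1L
  if (!(qgap > -params$max_overlap && qgap <= params$max_query_gap))
    return(NULL)
  ref_ov <- min(a$ref_end, b$ref_end) - max(a$ref_start, b$ref_start) + 1L
  if (ref_ov >= params$max_overlap) return(NULL)
  # reference order, independent of query order
  if (a$ref_start <= b$ref_start) { left <- a; right <- b }
  else { left <- b; right <- a }
  size <- right$ref_start - left$ref_end - 1L
  if (size <= params$min_ref_gap) return(NULL)
  c(left$ref_end + 1L, right$ref_start)
}

#' Does a read need local realignment?
#'
#' `TRUE` when the read length differs from the primary alignment's
#' reference span by strictly more than `realign_trigger` bp — the signature
#' of an alignment that silently dropped or compressed part of the read.
#'
#' @param segment primary segment (1-row data.frame or list with
#'   `read_length`, `ref_start`, `ref_end`).
#' @param params a [caller_params()].
#' @return logical.
#' @export
needs_realignment <- function(segment, params = caller_params()) {
  aligned <- segment$ref_end - segment$ref_start + 1L
  abs(segment$read_length - aligned) > params$realign_trigger
}

#' Call deletions by two-pass local realignment
#'
#' The read is locally aligned to the rotated reference (affine-gap
#' Smith-Waterman: match 2, mismatch -3, gap open 5, gap extend 2) in both
#' orientations and the better orientation kept. The aligned query interval
#' is then masked and the remaining flank(s) longer than `min_segment` are
#' realigned; the best-scoring flank alignment provides the second segment.
#' The two segments must satisfy the same pairing rules as [call_chimeric()]
#' to yield a deletion.
#'
#' @param read_sequence character string (or DNAString) of the read.
#' @param ref a [rotate_reference()] object.
#' @param params a [caller_params()].
#' @param read_id read name recorded in the output.
#' @return data.frame of deletion calls with `source = "realign"` (possibly
#'   empty).
#' @export
call_realign <- function(read_sequence, ref, params = caller_params(),
                         read_id = "read") {
  read_sequence <- toupper(.as_sequence_string(read_sequence))
  subject <- Biostrings::DNAString(ref$sequence)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = TRUE)
  aln <- function(q) Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), subject, type = "local",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  fwd <- aln(read_sequence)
  rc <- .revcomp(read_sequence)
  rev <- aln(rc)
  if (Biostrings::score(fwd) >= Biostrings::score(rev)) {
    oriented <- read_sequence; first <- fwd; strand <- "+"
  } else {
    oriented <- rc; first <- rev; strand <- "-"
  }
  if (Biostrings::score(first) < params$min_align_score)
    return(.empty_calls())
  n <- nchar(oriented)
  q1 <- .pa_query_range(first)
  s1 <- .pa_subject_range(first)
  # mask the aligned interval, realign the flanks that are long enough
  flanks <- list()
  if (q1[1L] - 1L > params$min_segment)
    flanks$left <- c(1L, q1[1L] - 1L)
  if (n - q1[2L] > params$min_segment)
    flanks$right <- c(q1[2L] + 1L, n)
  best <- NULL
  for (fl in flanks) {
    a2 <- aln(substr(oriented, fl[1L], fl[2L]))
    if (Biostrings::score(a2) < params$min_align_score) next
    if (is.null(best) || Biostrings::score(a2) > best$score)
      best <- list(score = Biostrings::score(a2), offset = fl[1L] - 1L,
                   aln = a2)
  }
  if (is.null(best)) return(.empty_calls())
  q2 <- .pa_query_range(best$aln) + best$offset
  s2 <- .pa_subject_range(best$aln)
  seg <- function(q, s) list(query_start = q[1L], query_end = q[2L],
                             ref_start = s[1L], ref_end = s[2L],
                             strand = strand)
  segs <- list(seg(q1, s1), seg(q2, s2))
  segs <- segs[order(vapply(segs, `[[`, numeric(1), "query_start"))]
  call <- .pair_deletion(segs[[1L]], segs[[2L]], params)
  if (is.null(call)) return(.empty_calls())
  .calls_df(read_id, call[1L], call[2L], "realign")
}

.pa_query_range <- function(pa) {
  r <- pa@pattern@range
  c(IRanges::start(r), IRanges::end(r))
}

.pa_subject_range <- function(pa) {
  r <- pa@subject@range
  c(IRanges::start(r), IRanges::end(r))
}

#' Combine deletion calls from multiple callers
#'
#' Per read, calls whose reference intervals lie within `merge_window` of
#' each other (overlapping included) are collapsed into a single call whose
#' extent is the union of its members; the source of a collapsed call is the
#' highest-sensitivity origin present (`chimeric`, then `realign`, then
#' `primary_cigar`). Output is sorted by sample, read and start.
#'
#' @param primary_calls,chimeric_calls call data.frames (either may be
#'   empty); additional call sets can be passed via `...`.
#' @param ... further call data.frames (e.g. realignment calls).
#' @param merge_window merge distance in bp.
#' @return combined call data.frame.
#' @export
combine_calls <- function(primary_calls, chimeric_calls, ...,
                          merge_window = 300L) {
  calls <- rbind(primary_calls, chimeric_calls, ...)
  if (is.null(calls) || nrow(calls) == 0L) return(.empty_calls())
  key <- paste(calls$sample_id, calls$read_id, sep = "\r")
  pieces <- lapply(split(calls, key), function(df) {
    ir <- IRanges::IRanges(df$start_rot, df$end_rot - 1L)
    red <- IRanges::reduce(ir, min.gapwidth = merge_window + 1L,
                           with.revmap = TRUE)
    members <- S4Vectors::mcols(red)$revmap
    src <- vapply(members, function(ii) {
      s <- df$source[ii]
      for (cand in c("chimeric", "realign", "primary_cigar"))
        if (cand %in% s) return(cand)
      s[1L]
    }, character(1))
    out <- .calls_df(df$read_id[1L], IRanges::start(red),
                     IRanges::end(red) + 1L, src, df$sample_id[1L])
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$sample_id, out$read_id, out$start_rot), , drop = FALSE]
}

#' Annotate calls with standard-frame breakpoints and arc class
#'
#' Adds `start_std`/`end_std` (1-based closed breakpoints in the standard
#' frame: first and last deleted base; for deletions spanning the standard
#' origin `start_std > end_std`, the usual convention for wrapping mtDNA
#' deletions) and `arc` (minor/major/both).
#'
#' @param calls call data.frame.
#' @param ref a [rotate_reference()].
#' @param arc an [arc_model()]; computed from `ref` when NULL.
#' @return annotated call data.frame.
#' @export
annotate_calls <- function(calls, ref, arc = NULL) {
  if (is.null(arc)) arc <- arc_model(ref)
  if (nrow(calls) == 0L) {
    calls$start_std <- integer(0); calls$end_std <- integer(0)
    calls$arc <- character(0)
    return(calls)
  }
  calls$start_std <- as.integer(rot_to_std(calls$start_rot, ref))
  calls$end_std <- as.integer(rot_to_std(calls$end_rot - 1L, ref))
  calls$arc <- classify_arc(calls$start_rot, calls$end_rot, arc)
  calls
}

#' Write / read a deletion call table
#'
#' TSV with one row per deletion event.
#'
#' @param calls (annotated) call data.frame.
#' @param path TSV path.
#' @return `path` (writer) or the call data.frame (reader).
#' @export
write_deletion_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_deletion_table
#' @export
read_deletion_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export calls as BED (0-based, rotated frame)
#'
#' @param calls call data.frame.
#' @param path BED path.
#' @param ref a [rotate_reference()] (for the contig name).
#' @return `path`, invisibly.
#' @export
write_deletion_bed <- function(calls, path, ref) {
  bed <- data.frame(chrom = ref$name, start = calls$start_rot - 1L,
                    end = calls$end_rot - 1L,
                    name = paste0(calls$read_id, ":", calls$source))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
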