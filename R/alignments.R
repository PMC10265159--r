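#' Load alignments to the rotated reference
#'
#' Reads a SAM or BAM file, keeps mapped records on the target contig,
#' discards secondary alignments (flag 256), and computes per-record
#' reference and query spans from the CIGAR. Query coordinates are
#' normalized to the original read orientation using the strand and the
#' soft/hard clip lengths, so the spans of a read's primary and supplementary
#' records can be compared directly on the query.
#'
#' @param path SAM or BAM file (SAM is converted in a temporary directory via
#'   [Rsamtools::asBam()]).
#' @param target_contig contig name to keep (default `"chrM_rotated"`).
#' @return A data.frame of class `mtdel_segments`, one row per alignment
#'   record: `read_id`, `flag`, `is_supplementary`, `is_primary`, `ref_name`,
#'   `ref_start`, `ref_end` (1-based closed), `query_start`, `query_end`
#'   (1-based closed, original read orientation), `strand`, `cigar`, `mapq`,
#'   `read_length`, `mean_quality` (NA when QUAL is absent). The number of
#'   records skipped for missing CIGARs is attached as attribute
#'   `n_skipped_no_cigar`.
#' @export
load_alignments <- function(path, target_contig = "chrM_rotated") {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!target_contig %in% names(hdr))
    stop("contig '", target_contig, "' not present in ", path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand",
             "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  keep <- !is.na(x$rname) & as.character(x$rname) == target_contig
  no_cigar <- keep & (is.na(x$cigar) | x$cigar == "" | x$cigar == "*")
  if (any(no_cigar))
    warning(sum(no_cigar), " mapped records without CIGAR skipped")
  keep <- keep & !no_cigar
  cig <- x$cigar[keep]
  pos <- x$pos[keep]
  strand <- as.character(x$strand)[keep]

  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  clips <- t(vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    lead <- 0L
    j <- 1L
    while (j <= length(o) && o[j] %in% c("S", "H")) {
      lead <- lead + l[j]; j <- j + 1L
    }
    trail <- 0L
    j <- length(o)
    while (j >= 1L && o[j] %in% c("S", "H")) {
      trail <- trail + l[j]; j <- j - 1L
    }
    c(lead, trail)
  }, integer(2)))
  if (length(cig) == 0L) clips <- matrix(integer(0), ncol = 2L)
  read_len <- clips[, 1L] + qwidth + clips[, 2L]
  # query span in original read orientation: leading clip precedes the
  # aligned block for '+' records, follows it (after flipping) for '-'
  q_start <- ifelse(strand == "-", clips[, 2L] + 1L, clips[, 1L] + 1L)
  q_end <- q_start + qwidth - 1L

  qual <- x$qual[keep]
  meanq <- rep(NA_real_, length(cig))
  if (length(qual) > 0) {
    has_q <- !is.na(as.character(qual)) & as.character(qual) != "*"
    if (any(has_q))
      meanq[has_q] <- vapply(which(has_q), function(i)
        mean(as.integer(charToRaw(as.character(qual[i])))) - 33, numeric(1))
  }
  flag <- x$flag[keep]
  seg <- data.frame(
    read_id = x$qname[keep],
    flag = flag,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_primary = bitwAnd(flag, 2048L) == 0L & bitwAnd(flag, 256L) == 0L,
    ref_name = rep(target_contig, length(cig)),
    ref_start = pos,
    ref_end = pos + ref_width - 1L,
    query_start = q_start,
    query_end = q_end,
    strand = strand,
    cigar = cig,
    mapq = x$mapq[keep],
    read_length = read_len,
    mean_quality = meanq,
    stringsAsFactors = FALSE)
  attr(seg, "n_skipped_no_cigar") <- sum(no_cigar)
  attr(seg, "target_contig") <- target_contig
  class(seg) <- c("mtdel_segments", "data.frame")
  seg
}

#' Group alignment segments into per-read bundles
#'
#' @param segments an `mtdel_segments` data.frame from [load_alignments()].
#' @return A named list of `read_bundle` objects, each a list with
#'   `read_id`, `read_length`, `mean_quality`, `primary` (1-row data.frame)
#'   and `supplementaries` (data.frame, possibly empty). Reads without a
#'   primary record on the contig are dropped.
#' @export
bundle_reads <- function(segments) {
  if (nrow(segments) == 0L) return(list())
  parts <- split(as.data.frame(segments), segments$read_id)
  bundles <- lapply(parts, function(df) {
    prim <- df[df$is_primary, , drop = FALSE]
    if (nrow(prim) == 0L) return(NULL)
    if (nrow(prim) > 1L) prim <- prim[1L, , drop = FALSE]
    supp <- df[df$is_supplementary, , drop = FALSE]
    # hard-clipped supplementaries still know the full read length
    rl <- max(df$read_length)
    structure(list(read_id = prim$read_id, read_length = rl,
                   mean_quality = prim$mean_quality,
                   primary = prim, supplementaries = supp),
              class = "read_bundle")
  })
  bundles[!vapply(bundles, is.null, logical(1))]
}

#' Read-level filters for deletion calling
#'
#' A read passes when its length is strictly between `min_len` and `max_len`
#' (400 and 17,000 bp by default: shorter reads cannot be attributed to
#' mtDNA unambiguously because of NUMTs, longer ones may be nuclear) and,
#' when a mean base quality is available, it is at least `min_quality`.
#'
#' @param bundle a `read_bundle`.
#' @param min_len,max_len exclusive read-length bounds in bp.
#' @param min_quality minimum mean Phred quality (applied only when the
#'   alignment file carries base qualities).
#' @return logical.
#' @export
passes_read_filters <- function(bundle, min_len = 400L, max_len = 17000L,
                                min_quality = 5) {
  rl <- bundle$read_length
  if (!(rl > min_len && rl < max_len)) return(FALSE)
  q <- bundle$mean_quality
  is.na(q) || q >= min_quality
}

#' Count mtDNA reads
#'
#' Number of distinct reads with a primary alignment to the target contig:
#' the denominator of every per-read deletion frequency.
#'
#' @param x an `mtdel_segments` data.frame or a list of bundles.
#' @return integer count.
#' @export
count_mt_reads <- function(x) {
  if (inherits(x, "mtdel_segments"))
    return(length(unique(x$read_id[x$is_primary])))
  length(x)
}
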