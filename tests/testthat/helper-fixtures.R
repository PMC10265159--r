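# Shared fixtures and independent oracles used across test files.

# A fixed synthetic mitochondrial-length genome (human chrM base
# composition, deterministic).
test_genome <- local({
  set.seed(16569)
  paste(sample(c("A", "C", "G", "T"), 16569, replace = TRUE,
               prob = c(0.31, 0.31, 0.13, 0.25)), collapse = "")
})

test_ref <- rotate_reference(test_genome, 1547)
test_arc <- arc_model(test_ref)

# Build a 1-row segment data.frame the callers accept.
make_segment <- function(read_id = "r1", ref_start = 1L, ref_end = 1000L,
                         query_start = 1L, query_end = 1000L,
                         strand = "+", cigar = "1000M",
                         is_supplementary = FALSE, read_length = 1000L,
                         mapq = 60L) {
  data.frame(read_id = read_id, flag = if (is_supplementary) 2048L else 0L,
             is_supplementary = is_supplementary,
             is_primary = !is_supplementary, ref_name = "chrM_rotated",
             ref_start = ref_start, ref_end = ref_end,
             query_start = query_start, query_end = query_end,
             strand = strand, cigar = cigar, mapq = mapq,
             read_length = read_length, mean_quality = NA_real_,
             stringsAsFactors = FALSE)
}

make_bundle <- function(primary, supplementaries = NULL) {
  structure(list(read_id = primary$read_id,
                 read_length = primary$read_length,
                 mean_quality = NA_real_,
                 primary = primary,
                 supplementaries = if (is.null(supplementaries))
                   make_segment()[0, ] else supplementaries),
            class = "read_bundle")
}

# Independent CIGAR span oracle: plain regex walk, no GenomicAlignments.
oracle_cigar_spans <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  list(ref = sum(lens[ops %in% c("M", "=", "X", "D", "N")]),
       query = sum(lens[ops %in% c("M", "=", "X", "I")]),
       clip_lead = {
         i <- 1L; s <- 0L
         while (i <= length(ops) && ops[i] %in% c("S", "H")) {
           s <- s + lens[i]; i <- i + 1L
         }
         s
       },
       clip_trail = {
         i <- length(ops); s <- 0L
         while (i >= 1L && ops[i] %in% c("S", "H")) {
           s <- s + lens[i]; i <- i - 1L
         }
         s
       })
}

# Independent brute-force chimeric-pair oracle: enumerate every unordered
# segment pair and apply the pairing predicates literally, with no ordering
# or chaining logic shared with the implementation.
oracle_chimeric <- function(segs, min_segment = 200L, max_query_gap = 300L,
                            max_overlap = 50L, min_ref_gap = 100L) {
  out <- list()
  n <- nrow(segs)
  if (n < 2L) return(data.frame(start_rot = integer(0), end_rot = integer(0)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- segs[i, ]; b <- segs[j, ]
    if (a$query_start > b$query_start ||
        (a$query_start == b$query_start && a$query_end > b$query_end)) {
      tmp <- a; a <- b; b <- tmp  # a first on the query
    }
    if (a$strand != b$strand) next
    if (!(a$query_end - a$query_start + 1L > min_segment)) next
    if (!(b$query_end - b$query_start + 1L > min_segment)) next
    qgap <- b$query_start - a$query_end - 1L
    if (!(qgap > -max_overlap && qgap <= max_query_gap)) next
    rov <- min(a$ref_end, b$ref_end) - max(a$ref_start, b$ref_start) + 1L
    if (rov >= max_overlap) next
    left <- if (a$ref_start <= b$ref_start) a else b
    right <- if (a$ref_start <= b$ref_start) b else a
    size <- right$ref_start - left$ref_end - 1L
    if (size <= min_ref_gap) next
    out[[length(out) + 1L]] <- data.frame(start_rot = left$ref_end + 1L,
                                          end_rot = right$ref_start)
  }
  if (length(out) == 0L)
    return(data.frame(start_rot = integer(0), end_rot = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start_rot, res$end_rot), , drop = FALSE]
}

# Random single-supplementary SAM fixture whose geometry straddles every
# pairing threshold; returns the SAM path.
random_chimeric_sam <- function(n_reads = 8, seed = 1,
                                contig = "chrM_rotated", L = 16569) {
  set.seed(seed)
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, L))
  rec <- function(qname, flag, pos, cigar)
    paste(qname, flag, contig, pos, 60L, cigar, "*", 0L, 0L, "*", "*",
          sep = "\t")
  clip_cig <- function(lead, span, trail, op) paste0(
    if (lead > 0L) paste0(lead, op), span, "M",
    if (trail > 0L) paste0(trail, op))
  for (r in seq_len(n_reads)) {
    span1 <- sample(c(150:250, 500:3000), 1)
    span2 <- sample(c(150:250, 500:3000), 1)
    qgap <- sample(c(-80:-40, -10:10, 250:350), 1)
    rgap <- sample(c(-100:150, 1000:9000), 1)
    strand2 <- sample(c("+", "+", "+", "-"), 1)
    qs1 <- sample(1:50, 1); qe1 <- qs1 + span1 - 1L
    qs2 <- qe1 + qgap + 1L; qe2 <- qs2 + span2 - 1L
    if (qs2 < 1L) next
    rl <- qe2 + sample(0:30, 1)
    rs1 <- sample(1:3000, 1); re1 <- rs1 + span1 - 1L
    rs2 <- re1 + rgap + 1L; re2 <- rs2 + span2 - 1L
    if (rs2 < 1L || re2 > L || re1 > L) next
    qn <- sprintf("rnd%03d", r)
    lines <- c(lines,
      rec(qn, 0L, rs1, clip_cig(qs1 - 1L, span1, rl - qe1, "S")),
      rec(qn, if (strand2 == "-") 2064L else 2048L, rs2,
          if (strand2 == "-") clip_cig(rl - qe2, span2, qs2 - 1L, "H")
          else clip_cig(qs2 - 1L, span2, rl - qe2, "H")))
  }
  path <- tempfile(fileext = ".sam")
  writeLines(lines, path)
  path
}
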