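params <- caller_params()

test_that("primary-CIGAR caller applies the strict size floor and merge rule", {
  seg <- function(cigar, pos = 1L)
    make_segment(cigar = cigar, ref_start = pos)

  # simple D run: 2000M 5000D 1000M starting at position 1
  calls <- call_primary_cigar(seg("2000M5000D1000M"), params)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start_rot, 2001L)
  expect_equal(calls$end_rot, 7001L)
  expect_equal(calls$size, 5000L)

  # 100 bp is not > 100 bp
  expect_equal(nrow(call_primary_cigar(seg("1000M100D1000M"), params)), 0)
  expect_equal(nrow(call_primary_cigar(seg("1000M101D1000M"), params)), 1)

  # two D runs 250 bp apart merge into one span-based event
  m <- call_primary_cigar(seg("500M200D250M300D500M"), params)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start_rot, m$end_rot), c(501L, 1251L))
  expect_equal(m$size, 750L)

  # 301 bp apart: two separate events
  s <- call_primary_cigar(seg("500M200D301M300D500M"), params)
  expect_equal(nrow(s), 2)
  expect_equal(s$size, c(200L, 300L))

  # merge oracle: brute-force interval clustering of the D runs
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    d_lens <- sample(c(50L, 150L, 400L), k, replace = TRUE)
    m_lens <- sample(c(100L, 250L, 301L, 600L), k + 1L, replace = TRUE)
    cigar <- paste0(m_lens[1], "M",
                    paste0(d_lens, "D", m_lens[-1], "M", collapse = ""))
    got <- call_primary_cigar(seg(cigar), params)
    # oracle: walk the runs, keep D > 100, merge while retained gap <= 300
    pos <- m_lens[1] + 1L
    cand <- list()
    for (i in seq_len(k)) {
      if (d_lens[i] > 100L)
        cand[[length(cand) + 1L]] <- c(pos, pos + d_lens[i])
      pos <- pos + d_lens[i] + m_lens[i + 1L]
    }
    merged <- list()
    for (cd in cand) {
      n <- length(merged)
      if (n > 0 && cd[1] - merged[[n]][2] <= 300L)
        merged[[n]][2] <- cd[2]
      else merged[[n + 1L]] <- cd
    }
    expect_equal(nrow(got), length(merged))
    if (length(merged)) {
      expect_equal(got$start_rot, vapply(merged, `[`, numeric(1), 1))
      expect_equal(got$end_rot, vapply(merged, `[`, numeric(1), 2))
    }
  }
})

test_that("chimeric pairing applies the contiguity and overlap rules", {
  pair_bundle <- function(q2_start, q2_end, r2_start = 8001L,
                          r2_end = 11000L, strand2 = "+") {
    rl <- q2_end + 10L
    prim <- make_segment(ref_start = 1L, ref_end = 3000L,
                         query_start = 1L, query_end = 3000L,
                         read_length = rl)
    supp <- make_segment(ref_start = r2_start, ref_end = r2_end,
                         query_start = q2_start, query_end = q2_end,
                         strand = strand2, is_supplementary = TRUE,
                         read_length = rl)
    make_bundle(prim, supp)
  }
  # canonical chimeric deletion: 3 kbp + 3 kbp segments, query gap 10,
  # reference jump of 5 kbp
  calls <- call_chimeric(pair_bundle(3011L, 6010L), params)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start_rot, calls$end_rot), c(3001L, 8001L))
  expect_equal(calls$size, 5000L)
  expect_equal(calls$source, "chimeric")

  # query gap 400 > 300: no call
  expect_equal(nrow(call_chimeric(pair_bundle(3401L, 6400L), params)), 0)
  # query gap exactly 300 passes, 301 fails
  expect_equal(nrow(call_chimeric(pair_bundle(3301L, 6300L), params)), 1)
  expect_equal(nrow(call_chimeric(pair_bundle(3302L, 6301L), params)), 0)
  # query overlap 60 >= 50: no call; overlap 49 passes
  expect_equal(nrow(call_chimeric(pair_bundle(2941L, 5940L), params)), 0)
  expect_equal(nrow(call_chimeric(pair_bundle(2952L, 5951L), params)), 1)
  # reference overlap >= 50 rejects
  expect_equal(nrow(call_chimeric(pair_bundle(3011L, 6010L,
                                              r2_start = 2951L,
                                              r2_end = 5950L), params)), 0)
  # opposite strands (inversion-like) reject
  expect_equal(nrow(call_chimeric(pair_bundle(3011L, 6010L,
                                              strand2 = "-"), params)), 0)
  # segments must each exceed 200 bp on the query
  short <- make_bundle(
    make_segment(ref_start = 1L, ref_end = 200L, query_start = 1L,
                 query_end = 200L, read_length = 3400L),
    make_segment(ref_start = 8001L, ref_end = 11000L, query_start = 211L,
                 query_end = 3210L, is_supplementary = TRUE,
                 read_length = 3400L))
  expect_equal(nrow(call_chimeric(short, params)), 0)
  # reference gap at the deletion-size floor: 100 rejected, 101 called
  expect_equal(nrow(call_chimeric(pair_bundle(3011L, 6010L,
                                              r2_start = 3101L,
                                              r2_end = 6100L), params)), 0)
  calls101 <- call_chimeric(pair_bundle(3011L, 6010L, r2_start = 3102L,
                                        r2_end = 6101L), params)
  expect_equal(calls101$size, 101L)
})

test_that("chimeric calls equal the brute-force pair oracle on random fixtures", {
  for (s in 1:25) {
    p <- random_chimeric_sam(n_reads = 8, seed = s)
    segs <- load_alignments(p, "chrM_rotated")
    for (b in bundle_reads(segs)) {
      if (nrow(b$supplementaries) == 0) next
      got <- call_chimeric(b, params)
      want <- oracle_chimeric(rbind(b$primary, b$supplementaries))
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        got <- got[order(got$start_rot, got$end_rot), ]
        expect_equal(got$start_rot, want$start_rot)
        expect_equal(got$end_rot, want$end_rot)
      }
    }
  }
})

test_that("multi-supplementary reads chain adjacent junctions", {
  # three query-contiguous segments with two reference jumps
  prim <- make_segment(ref_start = 1L, ref_end = 1000L, query_start = 1L,
                       query_end = 1000L, read_length = 3000L)
  s1 <- make_segment(ref_start = 3001L, ref_end = 4000L,
                     query_start = 1001L, query_end = 2000L,
                     is_supplementary = TRUE, read_length = 3000L)
  s2 <- make_segment(ref_start = 8001L, ref_end = 9000L,
                     query_start = 2001L, query_end = 3000L,
                     is_supplementary = TRUE, read_length = 3000L)
  calls <- call_chimeric(make_bundle(prim, rbind(s1, s2)), params)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$start_rot, c(1001L, 4001L))
  expect_equal(calls$end_rot, c(3001L, 8001L))
})

test_that("realignment trigger compares read and aligned lengths strictly", {
  seg <- function(rl, span) make_segment(read_length = rl, ref_start = 1L,
                                         ref_end = span)
  expect_true(needs_realignment(seg(5000L, 12000L), params))
  expect_false(needs_realignment(seg(5000L, 5400L), params))
  expect_false(needs_realignment(seg(5000L, 5500L), params))  # 500 not > 500
  expect_true(needs_realignment(seg(5000L, 5501L), params))
  expect_true(needs_realignment(seg(5000L, 4499L), params))   # shorter too
})

test_that("two-pass realignment recovers simulated deletions", {
  # error-free read spanning a 5 kbp deletion: exact breakpoints
  tpl <- make_templates(test_ref, sim_config(deletion_sizes = 5000L))[[1]]
  read <- substr(tpl$sequence, 1500, 5200)
  calls <- call_realign(read, test_ref, params, read_id = "clean")
  expect_equal(c(calls$start_rot, calls$end_rot), c(4000L, 9000L))
  expect_equal(calls$source, "realign")

  # deletion-free read: a single contiguous alignment, no call
  expect_equal(nrow(call_realign(substr(test_ref$sequence, 1500, 5200),
                                 test_ref, params)), 0)

  # reverse-strand noisy reads over a 3 kbp deletion: breakpoints within
  # the 300 bp pairing window of truth
  cfg <- sim_config(deletion_sizes = 3000L, reads_per_template = 2,
                    error_rates = c(mismatch = 0.05, insertion = 0.025,
                                    deletion = 0.025),
                    forward_strand_fraction = 0, start_jitter = 10L,
                    read_length_meanlog = log(5500),
                    read_length_sdlog = 0.1, seed = 31)
  sim <- simulate_reads(make_templates(test_ref, cfg), cfg)
  spanning <- sim$truth[sim$truth$contains_deletion, ]
  expect_gt(nrow(spanning), 0)
  for (i in seq_len(nrow(spanning))) {
    cc <- call_realign(sim$sequences[[spanning$read_id[i]]], test_ref,
                       params, read_id = spanning$read_id[i])
    expect_equal(nrow(cc), 1)
    expect_lt(abs(cc$start_rot - 4000L), 300L)
    expect_lt(abs(cc$end_rot - 7000L), 300L)
  }
})

test_that("combining callers de-duplicates per-read events", {
  p1 <- data.frame(sample_id = "s", read_id = "r1", start_rot = 3001L,
                   end_rot = 8001L, size = 5000L, source = "primary_cigar",
                   stringsAsFactors = FALSE)
  c1 <- data.frame(sample_id = "s", read_id = "r1", start_rot = 3011L,
                   end_rot = 8021L, size = 5010L, source = "chimeric",
                   stringsAsFactors = FALSE)
  comb <- combine_calls(p1, c1)
  expect_equal(nrow(comb), 1)
  expect_equal(c(comb$start_rot, comb$end_rot), c(3001L, 8021L))  # union
  expect_equal(comb$source, "chimeric")  # higher-sensitivity origin

  # same interval on different reads never merges
  c2 <- c1; c2$read_id <- "r2"
  expect_equal(nrow(combine_calls(p1, c2)), 2)

  # empty chimeric set: identity
  expect_equal(combine_calls(p1, p1[0, ])$start_rot, p1$start_rot)

  # far-apart calls on one read stay separate
  c3 <- c1; c3$start_rot <- 12000L; c3$end_rot <- 13000L; c3$size <- 1000L
  expect_equal(nrow(combine_calls(p1, c3)), 2)
})

test_that("annotation adds standard-frame breakpoints and arc classes", {
  calls <- data.frame(sample_id = "s", read_id = "r1", start_rot = 6923L,
                      end_rot = 11931L, size = 5008L,
                      source = "primary_cigar", stringsAsFactors = FALSE)
  ann <- annotate_calls(calls, test_ref)
  expect_equal(ann$start_std, 8470L)  # the common deletion
  expect_equal(ann$end_std, 13477L)
  expect_equal(ann$arc, "major")

  tsv <- tempfile(fileext = ".tsv")
  write_deletion_table(ann, tsv)
  back <- read_deletion_table(tsv)
  expect_equal(back$start_std, ann$start_std)

  bed <- tempfile(fileext = ".bed")
  write_deletion_bed(ann, bed, test_ref)
  b <- utils::read.delim(bed, header = FALSE)
  expect_equal(b$V2, 6922L)  # 0-based start
  expect_equal(b$V3, 11930L)
})
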