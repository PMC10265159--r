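mk_sample <- function(id, age, n_reads, sizes, arcs = NULL,
                      starts = NULL, tissue = "muscle", ddpcr = NA_real_) {
  k <- length(sizes)
  if (is.null(starts)) starts <- rep(5000L, k)
  calls <- data.frame(
    sample_id = rep(id, k), read_id = sprintf("%s_r%04d", id, seq_len(k)),
    start_rot = as.integer(starts),
    end_rot = as.integer(starts + sizes),
    size = as.integer(sizes), source = rep("primary_cigar", k),
    stringsAsFactors = FALSE)
  calls <- annotate_calls(calls, test_ref, test_arc)
  if (!is.null(arcs)) calls$arc <- arcs
  sample_summary(id, age, n_reads, calls, tissue = tissue,
                 ddpcr_frequency = ddpcr)
}

test_that("deletion frequency counts strictly larger calls per read", {
  s <- mk_sample("a", 50, 30000L, sizes = c(rep(3000L, 10), rep(500L, 5)))
  expect_equal(deletion_frequency(s, 2000L), 10 / 30000)
  expect_equal(deletion_frequency(s, 0L), 15 / 30000)
  expect_equal(deletion_frequency(s, 3000L), 0)   # strict >
  expect_equal(deletion_frequency(s, 9000L), 0)
  expect_error(deletion_frequency(mk_sample("z", 1, 0L, integer(0)), 0L),
               "zero mtDNA reads")

  # non-increasing in min_size
  th <- seq(0, 10000, by = 250)
  f <- vapply(th, function(t) deletion_frequency(s, t), numeric(1))
  expect_true(all(diff(f) <= 0))
})

test_that("log-frequency regression recovers generating parameters", {
  cohort <- simulate_cohort(test_ref, seed = 42)
  gen <- attr(cohort, "generating")
  fit <- regress_log_freq(cohort, "age", min_size = 2000L)
  expect_lt(abs(fit$slope - gen$slope), 2 * fit$se_slope)
  expect_gt(fit$r_squared, 0.7)

  # identity case: frequencies equal the ddPCR values exactly
  ident <- lapply(1:6, function(i) {
    k <- 5L * i
    s <- mk_sample(paste0("i", i), 30 + i, 10000L, rep(3000L, k))
    s$ddpcr_frequency <- k / 10000
    s
  })
  fit_id <- suppressWarnings(  # exact fit: lm warns about perfect residuals
    regress_log_freq(ident, "log10_ddpcr", min_size = 2000L))
  expect_equal(fit_id$slope, 1, tolerance = 1e-10)
  expect_equal(fit_id$intercept, 0, tolerance = 1e-10)
  expect_equal(fit_id$r_squared, 1, tolerance = 1e-10)

  # constant frequencies: slope 0, no variance explained
  flat <- lapply(1:5, function(i)
    mk_sample(paste0("f", i), 20 + 10 * i, 10000L, rep(3000L, 7)))
  fit_flat <- regress_log_freq(flat, "age")
  expect_equal(fit_flat$slope, 0, tolerance = 1e-12)
  expect_equal(fit_flat$r_squared, 0)

  expect_error(regress_log_freq(flat[1:2], "age"), "fewer than 3")
})

test_that("threshold sweep finds the signal threshold and reports gaps as NA", {
  cohort <- simulate_cohort(test_ref, seed = 7)
  th <- seq(500L, 12000L, by = 500L)
  sw <- threshold_sweep(cohort, th, "age")
  expect_equal(sw$best_threshold, 2000L)
  # noise deletions (<= 2 kbp) dilute the correlation below the signal floor
  expect_lt(sw$r_squared[sw$thresholds == 500L],
            sw$r_squared[sw$thresholds == 2000L])
  # ties across thresholds with identical event sets resolve to the smallest
  expect_equal(sw$r_squared[sw$thresholds == 2000L],
               sw$r_squared[sw$thresholds == 3000L])
  # at and beyond the signal size no events remain: missing, not zero
  expect_true(all(is.na(sw$r_squared[sw$thresholds >= 9000L])))
  expect_error(threshold_sweep(cohort, integer(0)), "nonempty")

  # single threshold reduces to one regression
  one <- threshold_sweep(cohort, 2000L, "age")
  fit <- regress_log_freq(cohort, "age", min_size = 2000L)
  expect_equal(one$r_squared, fit$r_squared)
})

test_that("density permutation test is exact on identical groups and symmetric", {
  set.seed(5)
  a <- runif(80, 1, 16569)
  res <- density_compare(a, a, n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  b <- runif(120, 1, 16569)
  r1 <- density_compare(a, b, n_permutations = 99, seed = 3)
  r2 <- density_compare(b, a, n_permutations = 99, seed = 3)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 100)

  # power: distributions shifted by 2 kbp are rejected decisively
  x <- rnorm(200, 6000, 500)
  y <- rnorm(200, 8000, 500)
  pw <- density_compare(x, y, n_permutations = 199, seed = 4)
  expect_lte(pw$p_value, 0.01)

  expect_error(density_compare(numeric(0), b), "nonempty")
})

test_that("arc-stratified trends separate signal from noise populations", {
  cohort <- simulate_cohort(test_ref, seed = 11)
  gen <- attr(cohort, "generating")
  major <- arc_frequency_trend(cohort, "major", min_size = 2000L)
  expect_gt(major$r_squared, 0.7)
  expect_lt(abs(major$slope - gen$slope), 2 * major$se_slope)
  minor <- arc_frequency_trend(cohort, "minor", min_size = 0L)
  expect_lt(abs(minor$slope), 2 * minor$se_slope)  # no age signal
  # no "both"-class calls in this cohort: regression unavailable
  expect_error(arc_frequency_trend(cohort, "both", min_size = 0L))
  # the three classes partition the calls
  for (s in cohort)
    expect_equal(sum(s$calls$arc %in% c("minor", "major", "both")),
                 nrow(s$calls))
})

test_that("mean deletion size trend recovers a constructed slope", {
  ages <- seq(20, 80, by = 5)
  set.seed(9)
  samples <- lapply(seq_along(ages), function(i) {
    mu <- 3000 + 40 * ages[i]
    mk_sample(paste0("m", i), ages[i], 10000L,
              sizes = pmax(200L, round(rnorm(40, mu, 400))))
  })
  fit <- mean_size_trend(samples)
  expect_lt(abs(fit$slope - 40), 2 * fit$se_slope)
  expect_gt(fit$r_squared, 0.7)

  flat <- lapply(1:4, function(i)
    mk_sample(paste0("c", i), 20 + i * 10, 1000L, rep(4000L, 5)))
  expect_equal(mean_size_trend(flat)$slope, 0, tolerance = 1e-12)
})

test_that("Welch test matches the closed-form two-value case", {
  idem <- welch_t(c(1e-4, 2e-4), c(1e-4, 2e-4))
  expect_equal(idem$t, 0)
  expect_equal(idem$p_value, 1)

  # hand-computed oracle on raw scale: a = (1, 2), b = (4, 6)
  a <- c(1, 2); b <- c(4, 6)
  got <- welch_t(a, b, log10_transform = FALSE)
  se2 <- var(a) / 2 + var(b) / 2
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 2)^2 / 1 + (var(b) / 2)^2 / 1)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(got$t, t_hand)
  expect_equal(got$df, df_hand)
  expect_equal(got$p_value, p_hand)

  # widely separated groups
  sep <- welch_t(c(1e-5, 1.2e-5, 0.9e-5), c(1e-3, 1.1e-3, 0.95e-3))
  expect_lt(sep$p_value, 0.01)
})

test_that("read subsampling is deterministic, exact and order-preserving", {
  ids <- sprintf("r%05d", 1:50000)
  s1 <- subsample_reads(ids, 30000, seed = 10)
  s2 <- subsample_reads(ids, 30000, seed = 10)
  expect_identical(s1, s2)
  expect_length(unique(s1), 30000)
  expect_false(is.unsorted(match(s1, ids)))
  expect_identical(subsample_reads(ids, 50000, seed = 1), ids)
  expect_warning(out <- subsample_reads(ids[1:10], 20), "available")
  expect_length(out, 10)
})

test_that("sensitivity accounting matches a counting oracle", {
  truth <- data.frame(
    read_id = sprintf("r%d", 1:8),
    del_start = 4000L, del_size = rep(c(2000L, 5000L), each = 4),
    read_start = 1L, span_tpl = 12000L, read_len = 12000L, strand = "+",
    contains_deletion = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  # calls: r1 exact, r2 off by 250 (within tolerance), r3 off by 400 (miss),
  # r5 and r6 exact, r7 wrong end, r8 absent
  calls <- data.frame(
    sample_id = "s",
    read_id = c("r1", "r2", "r3", "r5", "r6", "r7"),
    start_rot = c(4000L, 4250L, 4400L, 4000L, 4010L, 4000L),
    end_rot = c(6000L, 6250L, 6400L, 9000L, 9010L, 12000L),
    size = 0L, source = "x", stringsAsFactors = FALSE)
  calls$size <- calls$end_rot - calls$start_rot
  sens <- sensitivity_by_size(truth, calls, match_tolerance = 300L)
  expect_equal(sens$del_size, c(2000L, 5000L))
  expect_equal(sens$n_spanning, c(3L, 4L))
  expect_equal(sens$n_detected, c(2L, 2L))
  expect_equal(sens$fraction, c(2 / 3, 0.5))

  none <- sensitivity_by_size(truth, calls[0, ])
  expect_equal(none$fraction, c(0, 0))
})
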