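#' Per-sample summary for deletion statistics
#'
#' Bundles everything the downstream statistics need for one sample: the
#' mtDNA read count (denominator of all frequencies), the deletion call
#' table, and metadata (age, tissue, optional ddPCR deletion frequency).
#'
#' @param sample_id sample identifier.
#' @param age donor age in years.
#' @param n_mt_reads number of reads with a primary mtDNA alignment.
#' @param calls deletion call data.frame for this sample.
#' @param tissue tissue label.
#' @param ddpcr_frequency optional orthogonal deletion frequency from ddPCR.
#' @return list of class `sample_summary`.
#' @export
sample_summary <- function(sample_id, age, n_mt_reads, calls,
                           tissue = NA_character_,
                           ddpcr_frequency = NA_real_) {
  if (n_mt_reads < 0) stop("n_mt_reads must be nonnegative")
  structure(list(sample_id = sample_id, age = age, tissue = tissue,
                 n_mt_reads = as.integer(n_mt_reads), calls = calls,
                 ddpcr_frequency = ddpcr_frequency),
            class = "sample_summary")
}

#' Deletion frequency per mtDNA read
#'
#' Number of deletion calls strictly larger than `min_size`, divided by the
#' sample's mtDNA read count.
#'
#' @param sample a [sample_summary()].
#' @param min_size minimum deletion size in bp (strict; 0 counts all calls).
#' @param arc_class optionally restrict to calls of one arc class
#'   (`"minor"`, `"major"`, `"both"`); requires arc-annotated calls.
#' @return proportion.
#' @export
deletion_frequency <- function(sample, min_size = 0L, arc_class = NULL) {
  if (sample$n_mt_reads == 0L)
    stop("deletion frequency undefined for a sample with zero mtDNA reads")
  calls <- sample$calls
  if (!is.null(arc_class)) {
    if (is.null(calls$arc))
      stop("calls lack arc annotation; run annotate_calls() first")
    calls <- calls[calls$arc == arc_class, , drop = FALSE]
  }
  sum(calls$size > min_size) / sample$n_mt_reads
}

.covariate_values <- function(samples, covariate) {
  switch(covariate,
    age = vapply(samples, `[[`, numeric(1), "age"),
    log10_ddpcr = log10(vapply(samples, `[[`, numeric(1),
                               "ddpcr_frequency")),
    stop("unknown covariate: ", covariate))
}

#' Regress log10 deletion frequency on a covariate
#'
#' Ordinary least squares of `log10(frequency)` on donor age or on the
#' log10 ddPCR frequency. Samples with zero qualifying deletions have no
#' defined log frequency and are excluded (no pseudocounts); at least three
#' usable samples are required.
#'
#' @param samples list of [sample_summary()] objects.
#' @param covariate `"age"` or `"log10_ddpcr"`.
#' @param min_size minimum deletion size in bp (strict).
#' @param arc_class optional arc restriction, as in [deletion_frequency()].
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `se_slope`, `n_used`.
#' @export
regress_log_freq <- function(samples, covariate = c("age", "log10_ddpcr"),
                             min_size = 0L, arc_class = NULL) {
  covariate <- match.arg(covariate)
  freqs <- vapply(samples, deletion_frequency, numeric(1),
                  min_size = min_size, arc_class = arc_class)
  x <- .covariate_values(samples, covariate)
  use <- freqs > 0 & is.finite(x)
  if (sum(use) < 3L)
    stop("fewer than 3 samples with nonzero frequency")
  y <- log10(freqs[use])
  if (stats::sd(y) < 1e-12)  # constant response: flat fit, nothing explained
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                p_value = NA_real_, se_slope = 0, n_used = sum(use)))
  fit <- stats::lm(y ~ x[use])
  sm <- summary(fit)
  co <- stats::coef(sm)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0
  list(slope = unname(co[2L, 1L]), intercept = unname(co[1L, 1L]),
       r_squared = r2,
       p_value = unname(co[2L, 4L]), se_slope = unname(co[2L, 2L]),
       n_used = sum(use))
}

#' Sweep minimum deletion size against a covariate
#'
#' Runs [regress_log_freq()] at each minimum-size threshold and reports the
#' threshold attaining the highest R-squared (smallest threshold on ties).
#' Thresholds where fewer than three samples retain a nonzero frequency are
#' reported as `NA`, not zero.
#'
#' @inheritParams regress_log_freq
#' @param thresholds increasing vector of minimum deletion sizes in bp.
#' @return list of class `sweep_result`: `thresholds`, `r_squared`,
#'   `slope`, `n_used` (vectors) and `best_threshold`.
#' @export
threshold_sweep <- function(samples, thresholds,
                            covariate = c("age", "log10_ddpcr"),
                            arc_class = NULL) {
  covariate <- match.arg(covariate)
  if (length(thresholds) == 0L) stop("thresholds must be nonempty")
  thresholds <- sort(thresholds)
  fits <- lapply(thresholds, function(th) {
    tryCatch(regress_log_freq(samples, covariate, min_size = th,
                              arc_class = arc_class),
             error = function(e) NULL)
  })
  r2 <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$r_squared,
               numeric(1))
  slope <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$slope,
                  numeric(1))
  n_used <- vapply(fits, function(f) if (is.null(f)) NA_integer_ else
    as.integer(f$n_used), integer(1))
  best <- if (all(is.na(r2))) NA_real_ else thresholds[which.max(r2)]
  structure(list(thresholds = thresholds, r_squared = r2, slope = slope,
                 n_used = n_used, best_threshold = best,
                 covariate = covariate),
            class = "sweep_result")
}

#' Permutation test of equality of breakpoint densities
#'
#' Compares two samples of genomic breakpoint positions via Gaussian kernel
#' density estimates with a common smoothing parameter `h` (the kernel
#' standard deviation, 50 bp by default), evaluated on a fixed grid of
#' `grid_n` points spanning `xlim`. The test statistic is the integrated
#' squared difference of the two density estimates. The null distribution is
#' built by pooling both samples and randomly reassigning group labels,
#' preserving group sizes; the p-value is
#' `(1 + #permuted T >= observed T) / (1 + n_permutations)`.
#'
#' The procedure is label-symmetric: swapping the two groups (with the same
#' seed) leaves the statistic and p-value unchanged.
#'
#' @param breakpoints_a,breakpoints_b numeric vectors of breakpoint
#'   positions (standard or rotated frame, as long as both use the same).
#' @param h kernel standard deviation in bp.
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @param grid_n grid resolution.
#' @param xlim evaluation range; defaults to the human mitochondrial genome.
#' @return list of class `density_test`: `statistic`, `p_value`,
#'   `n_permutations`, `bandwidth`, `grid_n`.
#' @export
density_compare <- function(breakpoints_a, breakpoints_b, h = 50,
                            n_permutations = 1000L, seed = NULL,
                            grid_n = 512L, xlim = c(1, 16569)) {
  a <- as.numeric(breakpoints_a); b <- as.numeric(breakpoints_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both breakpoint samples must be nonempty")
  dx <- diff(xlim) / (grid_n - 1L)
  kde <- function(x) stats::density(x, bw = h, from = xlim[1L],
                                    to = xlim[2L], n = grid_n)$y
  tstat <- function(g1, g2) sum((kde(g1) - kde(g2))^2) * dx
  t_obs <- tstat(a, b)
  pool <- sort(c(a, b))
  n <- length(pool)
  m <- min(length(a), length(b))  # draw the smaller group: label-symmetric
  t_perm <- .with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(n, m)
    tstat(pool[idx], pool[-idx])
  }, numeric(1)))
  p <- (1 + sum(t_perm >= t_obs)) / (1 + n_permutations)
  structure(list(statistic = t_obs, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 bandwidth = h, grid_n = as.integer(grid_n)),
            class = "density_test")
}

#' Age trend of deletion frequency within an arc class
#'
#' [regress_log_freq()] restricted to deletions of one arc class; used to
#' contrast the age-stable minor-arc deletion frequency with the strongly
#' age-correlated major-arc frequency.
#'
#' @inheritParams regress_log_freq
#' @param arc_class `"minor"`, `"major"` or `"both"`.
#' @return as [regress_log_freq()].
#' @export
arc_frequency_trend <- function(samples, arc_class, min_size = 0L,
                                covariate = "age") {
  regress_log_freq(samples, covariate, min_size = min_size,
                   arc_class = arc_class)
}

#' Age trend of mean deletion size
#'
#' OLS of the per-sample mean deletion size on donor age; samples without
#' any qualifying call are excluded.
#'
#' @inheritParams regress_log_freq
#' @param min_size minimum deletion size in bp (strict).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `se_slope`, `n_used`.
#' @export
mean_size_trend <- function(samples, min_size = 0L) {
  mean_sizes <- vapply(samples, function(s) {
    sz <- s$calls$size[s$calls$size > min_size]
    if (length(sz) == 0L) NA_real_ else mean(sz)
  }, numeric(1))
  age <- vapply(samples, `[[`, numeric(1), "age")
  use <- !is.na(mean_sizes)
  if (sum(use) < 3L) stop("fewer than 3 samples with calls")
  if (stats::sd(mean_sizes[use]) < 1e-9)
    return(list(slope = 0, intercept = mean(mean_sizes[use]), r_squared = 0,
                p_value = NA_real_, se_slope = 0, n_used = sum(use)))
  fit <- stats::lm(mean_sizes[use] ~ age[use])
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co[2L, 1L]), intercept = unname(co[1L, 1L]),
       r_squared = sm$r.squared, p_value = unname(co[2L, 4L]),
       se_slope = unname(co[2L, 2L]), n_used = sum(use))
}

#' Welch's unequal-variance t-test on group frequencies
#'
#' Two-sided Welch's t-test comparing per-sample deletion frequencies
#' between two groups, on the log10 scale by default (frequencies span
#' orders of magnitude). Degenerate input with zero variance in both groups
#' and equal means returns `t = 0`, `p = 1`.
#'
#' @param freqs_a,freqs_b numeric vectors of per-sample frequencies
#'   (each of length >= 2).
#' @param log10_transform compare log10-transformed frequencies.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(freqs_a, freqs_b, log10_transform = TRUE) {
  if (length(freqs_a) < 2L || length(freqs_b) < 2L)
    stop("each group needs at least 2 values")
  a <- if (log10_transform) log10(freqs_a) else as.numeric(freqs_a)
  b <- if (log10_transform) log10(freqs_b) else as.numeric(freqs_b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p_value = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_,
                p_value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Uniform random subsample of reads
#'
#' Deterministic under a fixed seed; used to normalize read depth across
#' samples before plotting or density comparisons. If `n` exceeds the number
#' of available reads, everything is returned with a warning.
#'
#' @param x a list of read bundles, or any vector (e.g. read ids).
#' @param n subsample size.
#' @param seed integer seed.
#' @return subset of `x`, in original order.
#' @export
subsample_reads <- function(x, n, seed = 1L) {
  total <- length(x)
  if (n >= total) {
    if (n > total)
      warning("requested ", n, " reads but only ", total, " available")
    return(x)
  }
  idx <- .with_seed(seed, sort(sample.int(total, n)))
  x[idx]
}

#' Detection sensitivity by expected deletion size
#'
#' Benchmarks a call set against simulator ground truth: a truth deletion
#' counts as detected when its read carries a call whose start and end are
#' each within `match_tolerance` of the true junction. Fractions are
#' computed per expected size over deletion-spanning reads only.
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param calls deletion call data.frame (rotated-frame coordinates).
#' @param match_tolerance breakpoint tolerance in bp.
#' @return data.frame with `del_size`, `n_spanning`, `n_detected`,
#'   `fraction`.
#' @export
sensitivity_by_size <- function(truth, calls, match_tolerance = 300L) {
  span <- truth[truth$contains_deletion, , drop = FALSE]
  sizes <- sort(unique(span$del_size))
  detected <- logical(nrow(span))
  if (nrow(calls) > 0L) {
    by_read <- split(calls, calls$read_id)
    for (i in seq_len(nrow(span))) {
      cc <- by_read[[span$read_id[i]]]
      if (is.null(cc)) next
      exp_start <- span$del_start[i]
      exp_end <- span$del_start[i] + span$del_size[i]
      detected[i] <- any(abs(cc$start_rot - exp_start) <= match_tolerance &
                         abs(cc$end_rot - exp_end) <= match_tolerance)
    }
  }
  out <- do.call(rbind, lapply(sizes, function(s) {
    sel <- span$del_size == s
    data.frame(del_size = s, n_spanning = sum(sel),
               n_detected = sum(detected[sel]),
               fraction = sum(detected[sel]) / sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Read a sample metadata sheet
#'
#' TSV with columns `sample_id`, `age`, optionally `tissue` and
#' `ddpcr_frequency`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
  sheet
}
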