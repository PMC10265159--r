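#' Simulate a synthetic sample cohort for the statistics layer
#'
#' Generates per-sample deletion-call tables with a known generating model,
#' for validating the frequency/regression/sweep machinery without
#' sequencing data. Two deletion populations are drawn per sample:
#'
#' * an age-dependent "signal" population in the major arc, with expected
#'   per-read frequency `10^(intercept + slope * age + N(0, sigma))` and
#'   sizes uniform on `signal_sizes` (a fixed 9 kbp by default);
#' * an age-independent "noise" population in the minor arc at a constant
#'   per-read rate, with sizes uniform on `noise_sizes` (all at most
#'   2 kbp), diluting the age correlation at smaller thresholds.
#'
#' The sharp size separation between the populations makes the cohort a
#' clean validation target for [threshold_sweep()]: every minimum-size
#' threshold from 2 kbp up to just below the signal size retains the
#' identical, complete signal set (so their regressions tie exactly and the
#' sweep's tie-break reports the smallest such threshold, 2000 bp), while
#' thresholds below 2 kbp admit the age-independent noise and thresholds at
#' or above the signal size retain nothing.
#'
#' Defaults are anchored to observed muscle aging: a deletion frequency of
#' 4.3e-5 per read at age 25 rising 59-fold by age 75 (slope
#' `log10(59)/50` per year). The default read depth (2e5 per sample, the
#' order of magnitude of a targeted nanopore run) keeps Poisson counting
#' noise subdominant to the biological scatter `sigma`, so the ordinary
#' least-squares standard error is a calibrated measure of the slope
#' uncertainty even in the youngest, lowest-count samples.
#'
#' @param ref a [rotate_reference()] used to annotate arcs and standard
#'   coordinates.
#' @param ages donor ages in years (one sample per age).
#' @param n_reads mtDNA reads per sample.
#' @param slope,intercept generating coefficients of
#'   `log10(frequency) ~ age` for the signal population.
#' @param sigma SD of the per-sample lognormal scatter (log10 units).
#' @param noise_rate constant per-read frequency of the noise population.
#' @param signal_sizes,noise_sizes inclusive size ranges in bp.
#' @param tissue tissue label stored in each sample.
#' @param seed integer seed.
#' @return list of [sample_summary()] objects with arc-annotated calls; the
#'   generating parameters are attached as attribute `generating`.
#' @export
simulate_cohort <- function(ref,
                            ages = round(seq(20, 81, length.out = 15)),
                            n_reads = 200000L,
                            slope = log10(59) / 50,
                            intercept = log10(4.3e-5) - 25 * log10(59) / 50,
                            sigma = 0.15,
                            noise_rate = 3e-3,
                            signal_sizes = c(9000L, 9000L),
                            noise_sizes = c(300L, 2000L),
                            tissue = "muscle",
                            seed = 1L) {
  arc <- arc_model(ref)
  # rotated-frame start windows keeping each population inside one arc
  major_lo <- arc$major[1L, 1L]
  minor_hi <- arc$minor[1L, 2L]
  .with_seed(seed, {
    samples <- lapply(seq_along(ages), function(i) {
      age <- ages[i]
      lf <- intercept + slope * age + stats::rnorm(1L, 0, sigma)
      n_sig <- stats::rpois(1L, n_reads * 10^lf)
      n_noise <- stats::rpois(1L, n_reads * noise_rate)
      runi <- function(lo, hi, n)  # uniform integers on [lo, hi]
        lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
      sz_sig <- runi(signal_sizes[1L], signal_sizes[2L], n_sig)
      st_sig <- runi(major_lo + 100L, major_lo + 700L, n_sig)
      sz_noise <- runi(noise_sizes[1L], noise_sizes[2L], n_noise)
      st_noise <- runi(200L, minor_hi - noise_sizes[2L] - 1L, n_noise)
      id <- sprintf("%s%02d", substr(tissue, 1L, 1L), i)
      k <- n_sig + n_noise
      calls <- .calls_df(
        read_id = sprintf("%s_read%06d", id, seq_len(max(k, 0L))),
        start_rot = c(st_sig, st_noise),
        end_rot = c(st_sig + sz_sig, st_noise + sz_noise),
        source = "primary_cigar", sample_id = id)
      calls <- annotate_calls(calls, ref, arc)
      sample_summary(id, age, n_reads, calls, tissue = tissue,
                     ddpcr_frequency = 10^lf)
    })
    attr(samples, "generating") <- list(
      slope = slope, intercept = intercept, sigma = sigma,
      noise_rate = noise_rate, signal_min_size = signal_sizes[1L],
      ages = ages, n_reads = n_reads, seed = seed)
    samples
  })
}
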