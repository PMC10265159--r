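#' Run the simulation benchmark workflow
#'
#' Builds deletion-bearing templates from the rotated reference, simulates
#' reads, and writes everything a benchmark needs: the rotated reference
#' FASTA, the simulated FASTQ, the ground-truth TSV, one SAM fixture per
#' requested style, and a JSON manifest recording parameters and seed so the
#' run can be reproduced bit-for-bit.
#'
#' @param ref a [rotate_reference()] object.
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param styles SAM fixture styles to write (see [write_sam_fixture()]).
#' @return invisibly, a list with the simulated reads, truth table and
#'   output paths.
#' @export
cmd_simulate <- function(ref, config = sim_config(), out_dir,
                         styles = c("cigar_D", "chimeric", "mixed")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  templates <- make_templates(ref, config)
  sim <- simulate_reads(templates, config)
  paths <- list(
    reference = file.path(out_dir, "reference_rotated.fa"),
    fastq = file.path(out_dir, "reads.fastq"),
    truth = file.path(out_dir, "truth.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_reference_fasta(ref, paths$reference)
  write_fastq(sim, paths$fastq)
  write_truth_tsv(sim$truth, paths$truth)
  for (st in styles) {
    p <- file.path(out_dir, sprintf("fixture_%s.sam", st))
    write_sam_fixture(sim$truth, ref, style = st, seed = config$seed,
                      path = p)
    paths[[paste0("sam_", st)]] <- p
  }
  manifest <- list(
    tool = "mtdelscan", version = as.character(utils::packageVersion("mtdelscan")),
    r_version = R.version.string,
    reference = list(name = ref$name, length = ref$length,
                     rotation_offset = ref$offset),
    config = unclass(config), styles = styles,
    n_reads = length(sim$sequences))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sim = sim, templates = templates, paths = paths))
}

#' Run all deletion callers on an alignment file
#'
#' Loads alignments to the rotated reference, applies the read-level filters
#' uniformly (one read population, hence one denominator for all frequency
#' statistics), runs the enabled callers, combines their calls per read, and
#' annotates standard-frame breakpoints and arc classes.
#'
#' The realignment caller runs only when `fastq` is supplied, and only on
#' reads whose aligned span diverges from the read length by more than the
#' realignment trigger.
#'
#' @param sam_path SAM/BAM file aligned to the rotated reference.
#' @param ref a [rotate_reference()].
#' @param params a [caller_params()].
#' @param sample_id sample label recorded in the calls.
#' @param callers subset of `c("primary_cigar", "chimeric", "realign")`.
#' @param fastq optional FASTQ path with the read sequences (required for
#'   the realign caller).
#' @param apply_filters apply the >400 / <17,000 bp read filters.
#' @param min_quality minimum mean base quality (when qualities are present).
#' @param out_tsv optional path for the deletion table.
#' @return annotated call data.frame with attributes `n_reads_total`,
#'   `n_reads_pass` (the frequency denominator), and `caller_counts`.
#' @export
cmd_call <- function(sam_path, ref, params = caller_params(),
                     sample_id = "sample",
                     callers = c("primary_cigar", "chimeric"),
                     fastq = NULL, apply_filters = TRUE, min_quality = 5,
                     out_tsv = NULL) {
  callers <- match.arg(callers,
                       c("primary_cigar", "chimeric", "realign"),
                       several.ok = TRUE)
  segs <- load_alignments(sam_path, target_contig = ref$name)
  bundles <- bundle_reads(segs)
  n_total <- length(bundles)
  if (apply_filters) {
    keep <- vapply(bundles, passes_read_filters, logical(1),
                   min_quality = min_quality)
    bundles <- bundles[keep]
  }
  n_pass <- length(bundles)

  primary <- .empty_calls()
  if ("primary_cigar" %in% callers && n_pass > 0L) {
    prim_segs <- do.call(rbind, lapply(bundles, `[[`, "primary"))
    primary <- call_primary_cigar_all(prim_segs, params)
  }
  chimeric <- .empty_calls()
  if ("chimeric" %in% callers) {
    ch <- lapply(bundles, function(b) {
      if (nrow(b$supplementaries) == 0L) return(NULL)
      call_chimeric(b, params)
    })
    ch <- ch[!vapply(ch, is.null, logical(1))]
    if (length(ch) > 0L) chimeric <- do.call(rbind, ch)
  }
  realign <- .empty_calls()
  if ("realign" %in% callers) {
    if (is.null(fastq))
      stop("the realign caller needs the read sequences; supply `fastq`")
    reads <- read_fastq(fastq)
    rl <- lapply(bundles, function(b) {
      if (!needs_realignment(b$primary, params)) return(NULL)
      if (!b$read_id %in% names(reads)) return(NULL)
      seq <- reads[[b$read_id]]
      call_realign(seq, ref, params, read_id = b$read_id)
    })
    rl <- rl[!vapply(rl, is.null, logical(1))]
    if (length(rl) > 0L) realign <- do.call(rbind, rl)
  }
  combined <- combine_calls(primary, chimeric, realign,
                            merge_window = params$merge_window)
  combined$sample_id <- if (nrow(combined)) sample_id else character(0)
  combined <- annotate_calls(combined, ref)
  attr(combined, "n_reads_total") <- n_total
  attr(combined, "n_reads_pass") <- n_pass
  attr(combined, "caller_counts") <- c(primary_cigar = nrow(primary),
                                       chimeric = nrow(chimeric),
                                       realign = nrow(realign),
                                       combined = nrow(combined))
  if (!is.null(out_tsv)) write_deletion_table(combined, out_tsv)
  combined
}

#' Extract breakpoint positions from a call table
#'
#' @param calls annotated call data.frame.
#' @param which `"both"` pools start and end breakpoints (default, since
#'   density comparisons concern all breakpoints), `"starts"` or `"ends"`.
#' @param frame `"std"` (requires [annotate_calls()]) or `"rot"`.
#' @param min_size restrict to deletions strictly larger than this.
#' @return numeric vector of positions.
#' @export
breakpoints_from_calls <- function(calls, which = c("both", "starts", "ends"),
                                   frame = c("std", "rot"), min_size = 0L) {
  which <- match.arg(which); frame <- match.arg(frame)
  calls <- calls[calls$size > min_size, , drop = FALSE]
  s <- if (frame == "std") calls$start_std else calls$start_rot
  e <- if (frame == "std") calls$end_std else calls$end_rot
  switch(which, both = c(s, e), starts = s, ends = e)
}

#' Run the cohort statistics workflow
#'
#' Per-sample deletion frequencies over a threshold grid, the minimum-size
#' threshold sweep against age (and against log10 ddPCR frequency when
#' available), arc-stratified age trends, the mean-size trend, pairwise
#' tissue comparisons (Welch's t on log10 frequencies and the breakpoint
#' density permutation test), and an optional circular arc plot.
#'
#' @param samples list of [sample_summary()] objects.
#' @param thresholds minimum-size grid in bp for sweeps and the frequency
#'   table.
#' @param freq_min_size threshold used for group comparisons and the plot.
#' @param h,n_permutations,seed density-test settings (see
#'   [density_compare()]).
#' @param out_dir if non-NULL, writes `frequencies.tsv`, `sweep_age.tsv`,
#'   `stats.json` and `arc_plot.svg` there.
#' @param ref a [rotate_reference()] (needed for the arc plot; optional).
#' @return list with elements `frequencies`, `sweep_age`, `sweep_ddpcr`,
#'   `arc_trends`, `mean_size_trend`, `tissue_welch`, `tissue_density`.
#' @export
cmd_stats <- function(samples, thresholds = seq(500L, 8000L, by = 500L),
                      freq_min_size = 2000L, h = 50,
                      n_permutations = 1000L, seed = 1L, out_dir = NULL,
                      ref = NULL) {
  if (length(samples) < 1L) stop("need at least one sample")
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  freq_tab <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, age = s$age, tissue = s$tissue,
               n_mt_reads = s$n_mt_reads,
               min_size = thresholds,
               frequency = vapply(thresholds, function(th)
                 deletion_frequency(s, th), numeric(1)))
  }))
  try_fit <- function(expr) tryCatch(expr, error = function(e) NULL)
  sweep_age <- try_fit(threshold_sweep(samples, thresholds, "age"))
  has_ddpcr <- all(is.finite(vapply(samples, `[[`, numeric(1),
                                    "ddpcr_frequency")))
  sweep_ddpcr <- if (has_ddpcr)
    try_fit(threshold_sweep(samples, thresholds, "log10_ddpcr")) else NULL
  if (!has_ddpcr)
    message("ddPCR frequencies absent for some samples; ",
            "ddPCR regressions skipped")
  arc_trends <- lapply(c(minor = "minor", major = "major", both = "both"),
                       function(cl) try_fit(
                         arc_frequency_trend(samples, cl,
                                             min_size = freq_min_size)))
  msize <- try_fit(mean_size_trend(samples))

  tissues <- unique(vapply(samples, `[[`, character(1), "tissue"))
  tissues <- tissues[!is.na(tissues)]
  tissue_welch <- NULL
  tissue_density <- list()
  if (length(tissues) >= 2L) {
    for (i in seq_len(length(tissues) - 1L)) for (j in (i + 1L):length(tissues)) {
      sa <- samples[vapply(samples, `[[`, character(1), "tissue") == tissues[i]]
      sb <- samples[vapply(samples, `[[`, character(1), "tissue") == tissues[j]]
      key <- paste(tissues[i], tissues[j], sep = "_vs_")
      if (length(sa) >= 2L && length(sb) >= 2L) {
        fa <- vapply(sa, deletion_frequency, numeric(1), freq_min_size)
        fb <- vapply(sb, deletion_frequency, numeric(1), freq_min_size)
        # log-scale comparison: samples without qualifying events excluded
        fa <- fa[fa > 0]; fb <- fb[fb > 0]
        if (length(fa) >= 2L && length(fb) >= 2L)
          tissue_welch[[key]] <- welch_t(fa, fb)
      }
      bp_a <- unlist(lapply(sa, function(s)
        breakpoints_from_calls(s$calls, min_size = freq_min_size)))
      bp_b <- unlist(lapply(sb, function(s)
        breakpoints_from_calls(s$calls, min_size = freq_min_size)))
      if (length(bp_a) > 0L && length(bp_b) > 0L)
        tissue_density[[key]] <- density_compare(
          bp_a, bp_b, h = h, n_permutations = n_permutations, seed = seed)
    }
  }
  out <- list(frequencies = freq_tab, sweep_age = sweep_age,
              sweep_ddpcr = sweep_ddpcr, arc_trends = arc_trends,
              mean_size_trend = msize, tissue_welch = tissue_welch,
              tissue_density = tissue_density)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(freq_tab, file.path(out_dir, "frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sweep_age))
      utils::write.table(
        data.frame(threshold = sweep_age$thresholds,
                   r_squared = sweep_age$r_squared,
                   slope = sweep_age$slope, n_used = sweep_age$n_used),
        file.path(out_dir, "sweep_age.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    json <- list(
      sweep_age = if (!is.null(sweep_age)) unclass(sweep_age),
      sweep_ddpcr = if (!is.null(sweep_ddpcr)) unclass(sweep_ddpcr),
      arc_trends = arc_trends, mean_size_trend = msize,
      tissue_welch = tissue_welch,
      tissue_density = lapply(tissue_density, unclass),
      seed = seed)
    jsonlite::write_json(json, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    if (!is.null(ref)) {
      all_calls <- do.call(rbind, lapply(samples, `[[`, "calls"))
      arc_plot(all_calls, ref, min_size = freq_min_size,
               path = file.path(out_dir, "arc_plot.svg"))
    }
  }
  out
}

#' Circular arc plot of deletion calls
#'
#' Basic circular-layout plot: the mitochondrial genome as a circle in
#' standard coordinates (position 1 at the top, clockwise), with one chord
#' per deletion linking its two breakpoints. Calls matching the human
#' "common deletion" (standard 8470-13477, within 50 bp) are drawn in red.
#'
#' @param calls annotated call data.frame.
#' @param ref a [rotate_reference()].
#' @param min_size plot deletions strictly larger than this (default 2000).
#' @param path if non-NULL, writes an SVG there instead of drawing on the
#'   active device.
#' @param main plot title.
#' @return invisibly, the number of chords drawn.
#' @export
arc_plot <- function(calls, ref, min_size = 2000L, path = NULL,
                     main = "mtDNA deletions") {
  calls <- calls[calls$size > min_size, , drop = FALSE]
  if (!is.null(path)) {
    grDevices::svg(path, width = 6, height = 6)
    on.exit(grDevices::dev.off())
  }
  L <- ref$length
  theta <- function(pos) pi / 2 - 2 * pi * (pos - 1) / L  # clockwise from top
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.15, 1.15), ylim = c(-1.15, 1.15),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  tt <- seq(0, 2 * pi, length.out = 512)
  graphics::lines(cos(tt), sin(tt), col = "grey40")
  ticks <- seq(0, L - 1, by = 2000)
  graphics::text(1.1 * cos(theta(ticks + 1)), 1.1 * sin(theta(ticks + 1)),
                 labels = ticks / 1000, cex = 0.6, col = "grey30")
  if (nrow(calls) > 0L) {
    is_common <- abs(calls$start_std - 8470) <= 50 &
      abs(calls$end_std - 13477) <= 50
    a1 <- theta(calls$start_std); a2 <- theta(calls$end_std)
    graphics::segments(cos(a1), sin(a1), cos(a2), sin(a2),
                       col = ifelse(is_common, "red", "#00000033"))
  }
  invisible(nrow(calls))
}
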