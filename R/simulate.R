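#' Simulator configuration
#'
#' Parameters of the nCATS-style read simulator. Defaults reproduce the
#' benchmark design used throughout the package: ten template genomes, each
#' carrying one deletion starting at rotated position 4000 and extending
#' 1-10 kbp, with 500 reads per template. Reads begin at the cut site
#' (template position 1, plus a small start jitter), are predominantly
#' forward-strand, and carry independent per-base mismatch/insertion/deletion
#' errors.
#'
#' Read lengths are lognormal (`meanlog`, `sdlog` in log-bp), truncated at the
#' template length: an nCATS read cannot be longer than the linearized
#' molecule it comes from. The default length distribution (median 7 kbp,
#' sdlog 0.55) gives a read population in which most reads span a junction at
#' 4 kbp, comparable to targeted nanopore runs on mtDNA.
#'
#' @param deletion_start rotated-frame position of the first deleted base in
#'   every template (default 4000).
#' @param deletion_sizes integer vector of deletion sizes in bp
#'   (default 1000, 2000, ..., 10000), one template per size.
#' @param reads_per_template reads simulated from each template (default 500).
#' @param read_length_meanlog,read_length_sdlog lognormal read-length
#'   parameters in log-bp.
#' @param error_rates named numeric vector with elements `mismatch`,
#'   `insertion`, `deletion`: independent per-base probabilities.
#' @param forward_strand_fraction probability a read is forward-strand
#'   (default 0.85, matching the strand bias downstream of the Cas9 PAM).
#' @param start_jitter maximum shift of the read start from template
#'   position 1, in bp (uniform on `0..start_jitter`).
#' @param base_quality constant Phred quality written to FASTQ.
#' @param seed integer seed; all randomness in [simulate_reads()] derives
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(deletion_start = 4000L,
                       deletion_sizes = seq(1000L, 10000L, by = 1000L),
                       reads_per_template = 500L,
                       read_length_meanlog = log(7000),
                       read_length_sdlog = 0.55,
                       error_rates = c(mismatch = 0.04, insertion = 0.02,
                                       deletion = 0.02),
                       forward_strand_fraction = 0.85,
                       start_jitter = 50L,
                       base_quality = 12L,
                       seed = 1L) {
  er <- error_rates
  if (!all(c("mismatch", "insertion", "deletion") %in% names(er)))
    stop("error_rates must name mismatch, insertion and deletion")
  if (any(er < 0) || any(er > 1))
    stop("error rates must be probabilities in [0, 1]")
  if (forward_strand_fraction < 0 || forward_strand_fraction > 1)
    stop("forward_strand_fraction must be in [0, 1]")
  reads_per_template <- .as_count(reads_per_template, "reads_per_template")
  if (reads_per_template < 1L)
    stop("reads_per_template must be >= 1")
  if (any(deletion_sizes != round(deletion_sizes)))
    stop("deletion_sizes must be integers")
  structure(
    list(deletion_start = .as_count(deletion_start, "deletion_start"),
         deletion_sizes = as.integer(deletion_sizes),
         reads_per_template = reads_per_template,
         read_length_meanlog = read_length_meanlog,
         read_length_sdlog = read_length_sdlog,
         error_rates = er[c("mismatch", "insertion", "deletion")],
         forward_strand_fraction = forward_strand_fraction,
         start_jitter = .as_count(start_jitter, "start_jitter"),
         base_quality = .as_count(base_quality, "base_quality"),
         seed = if (is.null(seed)) NULL else .as_count(seed, "seed")),
    class = "sim_config")
}

#' Build deletion-bearing template genomes
#'
#' One template per requested deletion size: the rotated reference with the
#' interval `[deletion_start, deletion_start + size)` excised, so each
#' template is `L - size` bp long.
#'
#' @param ref a [rotate_reference()] object.
#' @param config a [sim_config()].
#' @return A list of templates; each is a list with `template_id`,
#'   `sequence`, `del_start`, `del_size`, `length`.
#' @export
make_templates <- function(ref, config = sim_config()) {
  stopifnot(inherits(ref, "rotated_reference"))
  sizes <- config$deletion_sizes
  start <- config$deletion_start
  if (any(sizes < 1L))
    stop("deletion sizes must be >= 1 bp")
  if (start < 2L)
    stop("deletion_start must leave at least one base before the junction")
  if (start + max(sizes) > ref$length)
    stop("deletion extends beyond the reference")
  lapply(sizes, function(s) {
    seq_tpl <- paste0(substr(ref$sequence, 1L, start - 1L),
                      substr(ref$sequence, start + s, ref$length))
    list(template_id = sprintf("del%d_s%d", start, s),
         sequence = seq_tpl, del_start = start, del_size = as.integer(s),
         length = nchar(seq_tpl))
  })
}

#' Deletion-free template from the rotated reference
#'
#' Companion to [make_templates()] for specificity experiments: reads
#' simulated from it carry no deletion and their truth rows have
#' `contains_deletion = FALSE`.
#'
#' @inheritParams make_templates
#' @return A single-template list in the [make_templates()] format.
#' @export
template_from_reference <- function(ref) {
  stopifnot(inherits(ref, "rotated_reference"))
  list(list(template_id = "no_deletion", sequence = ref$sequence,
            del_start = 0L, del_size = 0L, length = ref$length))
}

#' Simulate nCATS-style reads with ground truth
#'
#' Generates `reads_per_template` reads from each template. Read starts,
#' lengths and strands are drawn once per read ordinal and reused across
#' templates (a paired design: read ordinal j has the same geometry on every
#' template, so detection differences between deletion sizes are driven by
#' the deletion size, not by resampled read populations). Sequencing errors
#' are drawn independently per read.
#'
#' A truth row's `contains_deletion` is `TRUE` exactly when the read's
#' template span covers the deletion junction (at least one template base on
#' each side of it).
#'
#' @param templates list from [make_templates()] (and/or
#'   [template_from_reference()]).
#' @param config a [sim_config()]; `config$seed` controls all randomness.
#' @return A list of class `sim_reads`: `sequences` (named character vector,
#'   reverse-strand reads reverse-complemented), `truth` (data.frame with
#'   columns `read_id`, `template_id`, `del_start`, `del_size`, `read_start`,
#'   `span_tpl`, `read_len`, `strand`, `contains_deletion`, `read_index`),
#'   and `base_quality`.
#' @export
simulate_reads <- function(templates, config = sim_config()) {
  n <- config$reads_per_template
  er <- config$error_rates
  .with_seed(config$seed, {
    # shared read geometry across templates (paired design)
    lens <- pmax(50L, as.integer(round(stats::rlnorm(
      n, config$read_length_meanlog, config$read_length_sdlog))))
    starts <- 1L + sample.int(config$start_jitter + 1L, n, replace = TRUE) - 1L
    strands <- ifelse(stats::runif(n) < config$forward_strand_fraction,
                      "+", "-")
    out_seq <- character(0)
    truth <- vector("list", length(templates))
    for (k in seq_along(templates)) {
      tpl <- templates[[k]]
      ends <- pmin(starts + lens - 1L, tpl$length)
      spans <- ends - starts + 1L
      ids <- sprintf("%s_r%04d", tpl$template_id, seq_len(n))
      seqs <- character(n)
      for (j in seq_len(n)) {
        raw <- substr(tpl$sequence, starts[j], ends[j])
        noisy <- .apply_errors(raw, er)
        if (strands[j] == "-") noisy <- .revcomp(noisy)
        seqs[j] <- noisy
      }
      names(seqs) <- ids
      contains <- tpl$del_size > 0L & starts <= tpl$del_start - 1L &
        ends >= tpl$del_start
      truth[[k]] <- data.frame(
        read_id = ids, template_id = tpl$template_id,
        del_start = tpl$del_start, del_size = tpl$del_size,
        read_start = starts, span_tpl = spans, read_len = nchar(seqs),
        strand = strands, contains_deletion = contains,
        read_index = seq_len(n), stringsAsFactors = FALSE)
      out_seq <- c(out_seq, seqs)
    }
    structure(list(sequences = out_seq,
                   truth = do.call(rbind, truth),
                   base_quality = config$base_quality),
              class = "sim_reads")
  })
}

# iid per-base error model: deletions drop template bases, mismatches
# substitute, insertions add one random base after a kept base
.apply_errors <- function(seq_str, rates) {
  if (all(rates == 0)) return(seq_str)
  bases <- strsplit(seq_str, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  keep <- stats::runif(n) >= rates[["deletion"]]
  b <- bases[keep]
  m <- length(b)
  if (m == 0L) return("")
  mis <- stats::runif(m) < rates[["mismatch"]]
  if (any(mis)) {
    acgt <- c("A", "C", "G", "T")
    code <- match(b[mis], acgt)
    ok <- !is.na(code)  # ambiguity codes are left untouched
    shift <- sample.int(3L, sum(mis), replace = TRUE)
    b[mis][ok] <- acgt[((code[ok] - 1L + shift[ok]) %% 4L) + 1L]
  }
  ins <- stats::runif(m) < rates[["insertion"]]
  if (any(ins)) {
    out <- character(m + sum(ins))
    orig_pos <- seq_len(m) + cumsum(ins) - ins
    out[orig_pos] <- b
    out[-orig_pos] <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
    b <- out
  }
  paste(b, collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write simulated reads as FASTQ
#'
#' @param sim a `sim_reads` object.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  stopifnot(inherits(sim, "sim_reads"))
  reads <- Biostrings::DNAStringSet(sim$sequences)
  quals <- Biostrings::BStringSet(vapply(nchar(sim$sequences), function(w)
    strrep(rawToChar(as.raw(sim$base_quality + 33L)), w), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read simulated reads back from FASTQ
#'
#' @param path FASTQ path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(reads)
  names(out) <- sub("\\s.*$", "", names(reads))
  out
}

#' Write / read the simulator ground-truth table
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param path TSV path.
#' @return `path` (writer) or the truth data.frame (reader).
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
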