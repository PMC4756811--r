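# Shared fixtures and independent oracles.

# Per-base coverage oracle: logical vector per chromosome marking covered
# bases (0-based positions 0..length-1). Brute force by construction; used
# to check the interval algebra independently of GenomicRanges.
bases_covered <- function(regions, genome) {
  out <- lapply(stats::setNames(genome$length, genome$chrom), function(len) {
    logical(len)
  })
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    idx <- seq(regions$start[i] + 1, regions$end[i])
    out[[chrom]][idx] <- TRUE
  }
  out
}

# Random unnormalized interval set on a toy genome
random_regions <- function(genome, n, max_len = 5000) {
  idx <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, pmax(1, genome$length[idx] - len)))
  tibble::tibble(
    chrom = genome$chrom[idx], start = start, end = start + len
  )
}

toy_genome <- function(lengths = c(chr1 = 50000, chr2 = 30000)) {
  tibble::tibble(chrom = names(lengths), length = unname(lengths))
}

# Small beta matrix with named dims
toy_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("p%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- rlang::`%||%`

# Brute-force sliding-window oracle: recompute each window mean by direct
# filtering
brute_force_windows <- function(values, genome, bin, step) {
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chrom[ci]
    len <- genome$length[ci]
    starts <- seq(0, len - 1, by = step)
    for (s in starts) {
      e <- min(s + bin, len)
      v <- values$value[values$chrom == chrom & values$pos >= s & values$pos < e]
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chrom, start = s, end = e,
        n_probes = length(v),
        mean_value = if (length(v)) mean(v) else NA_real_
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# A reduced cohort spec for fast module tests
small_spec <- function(seed = 11, ...) {
  args <- list(
    seed = seed,
    genome = tibble::tibble(
      chrom = c("chr1", "chr2", "chrX"),
      length = c(4e6, 3e6, 5e5)
    ),
    n_genes = 80, n_cgi = 100, n_tf_sites = 50,
    n_dnase = 60, n_enhancer = 30, n_repeats = 120,
    n_probes = c(cgi = 400, backbone = 400, other = 150),
    n_flagged_probes = c(snp = 40, repeats = 40, sex = 20),
    n_normal = 30,
    tumor_blocks = list(
      tumor_block("T1", n_tumors = 30, cgi_shift = 0.10, backbone_shift = 0.05)
    )
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(cohort_spec, args)
}

# Default cohort (full acceptance-scale conditions), generated once per run
default_cohort_cache <- new.env(parent = emptyenv())
get_default_cohort <- function() {
  if (is.null(default_cohort_cache$cohort)) {
    default_cohort_cache$cohort <- simulate_cohort(cohort_spec(seed = 1))
  }
  default_cohort_cache$cohort
}

# QC + summarization shorthand used by several test files
summarize_cohort <- function(cohort, ...) {
  retained <- filter_probes(cohort$manifest)
  beta <- mask_detection(
    cohort$beta[retained$probe_id, , drop = FALSE],
    cohort$detection_p[retained$probe_id, , drop = FALSE]
  )
  assignment <- assign_regions(retained, cohort$taxonomy)
  list(
    manifest = retained, beta = beta, assignment = assignment,
    summary = summarize_samples(beta, assignment,
      sample_info = cohort$clinical, ...
    )
  )
}
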