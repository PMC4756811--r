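# Sliding-window methylation tracks and repressive-domain contrasts.
#
# Windows of width `bin` are anchored at 0 on each chromosome and advance by
# `step` (defaults 2 Mb / 1 Mb), so with step < bin each probe contributes
# to every window covering it. Large hypomethylated blocks in tumors
# coincide with lamina-associated domains (LADs) / partially methylated
# domains; lad_contrast() quantifies that by comparing methylation change
# inside vs. outside a domain track.

#' Sliding-window means of a per-probe track
#'
#' Averages a per-probe value (beta or methylation change) within sliding
#' windows. Window `k` on a chromosome covers
#' `[k*step, min(k*step + bin, chrom_length))` (half-open membership); the
#' final partial windows are retained. Windows containing no probe carry
#' `NA`.
#'
#' @param values Tibble with `chrom`, `pos` and a `value` column (override
#'   with `value`); typically one row per probe.
#' @param genome Genome tibble (`chrom`, `length`).
#' @param bin Window width in bp (default 2e6).
#' @param step Window step in bp (default 1e6).
#' @param value Name of the value column (default `"value"`).
#' @return A tibble with `chrom`, `start`, `end`, `n_probes`, `mean_value`,
#'   tiling every chromosome of `genome`.
#' @export
window_means <- function(values, genome, bin = 2e6, step = 1e6, value = "value") {
  validate_genome(genome)
  if (!all(c("chrom", "pos", value) %in% names(values))) {
    abort(sprintf("`values` must have columns chrom, pos and %s", value))
  }
  if (bin <= 0 || step <= 0) abort("`bin` and `step` must be positive")
  if (any(values$pos < 0)) abort("probe positions must be non-negative")
  windows <- purrr::pmap(genome, function(chrom, length, ...) {
    k <- seq(0, max(0, ceiling((length - 1) / step) * step), by = step)
    k <- k[k < length]
    tibble(chrom = chrom, start = k, end = pmin(k + bin, length))
  })
  windows <- bind_rows(windows)
  # expand each probe to the windows covering it: k in
  # [max(0, floor((pos - bin)/step) + 1), floor(pos/step)]
  probes <- values[values$chrom %in% genome$chrom, c("chrom", "pos", value)]
  names(probes)[3] <- ".value"
  if (nrow(probes) > 0) {
    k_hi <- floor(probes$pos / step)
    k_lo <- pmax(0, floor((probes$pos - bin) / step) + 1)
    reps <- k_hi - k_lo + 1
    expanded <- tibble(
      chrom = rep(probes$chrom, reps),
      start = (k_lo[rep(seq_len(nrow(probes)), reps)] +
        sequence(reps) - 1) * step,
      .value = rep(probes$.value, reps)
    )
    agg <- expanded |>
      group_by(.data$chrom, .data$start) |>
      summarise(
        n_probes = sum(!is.na(.data$.value)),
        mean_value = mean(.data$.value, na.rm = TRUE),
        .groups = "drop"
      )
    agg$mean_value[agg$n_probes == 0] <- NA_real_
  } else {
    agg <- tibble(
      chrom = character(), start = numeric(),
      n_probes = integer(), mean_value = numeric()
    )
  }
  out <- left_join(windows, agg, by = c("chrom", "start"))
  out$n_probes[is.na(out$n_probes)] <- 0L
  out <- arrange(out, .data$chrom, .data$start)
  class(out) <- c("meth_window_track", class(out))
  out
}

#' Methylation change inside vs. outside repressive domains
#'
#' Computes the mean per-probe methylation change (tumor minus normal mean,
#' or raw beta when no normals exist) separately for probes inside and
#' outside a domain track (LADs or PMDs), for the CGI and backbone probe
#' classes.
#'
#' @param probe_values Tibble with `probe_id`, `chrom`, `pos` and `value`
#'   (typically the per-probe mean change across a tumor cohort).
#' @param domains Region tibble of domains (e.g. LADs); normalized
#'   internally.
#' @param assignment Probe-region assignment from [assign_regions()] with
#'   `cgi` and `backbone` columns.
#' @param classes Region classes to contrast (default CGI and backbone).
#' @return A tibble with one row per class: `region`, `n_inside`,
#'   `n_outside`, `mean_inside`, `mean_outside` and `difference`
#'   (inside - outside; `NA` when the domains cover everything).
#' @export
lad_contrast <- function(probe_values, domains, assignment,
                         classes = c("cgi", "backbone")) {
  if (!all(c("probe_id", "chrom", "pos", "value") %in% names(probe_values))) {
    abort("`probe_values` must have columns probe_id, chrom, pos, value")
  }
  domains <- region_normalize(domains)
  probe_gr <- GenomicRanges::GRanges(
    seqnames = probe_values$chrom,
    ranges = IRanges::IRanges(start = probe_values$pos + 1, width = 1)
  )
  inside <- if (nrow(domains) > 0) {
    suppressWarnings(IRanges::overlapsAny(probe_gr, regions_to_gr(domains)))
  } else {
    rep(FALSE, nrow(probe_values))
  }
  if (!any(inside)) abort("no probes fall inside the domain track")
  res <- purrr::map(classes, function(cl) {
    if (!cl %in% names(assignment)) {
      abort(sprintf("region class '%s' not in assignment", cl))
    }
    member <- probe_values$probe_id %in%
      assignment$probe_id[assignment[[cl]]]
    v <- probe_values$value[member]
    ins <- inside[member]
    mean_inside <- if (any(ins)) mean(v[ins], na.rm = TRUE) else NA_real_
    mean_outside <- if (any(!ins)) mean(v[!ins], na.rm = TRUE) else NA_real_
    tibble(
      region = cl,
      n_inside = sum(ins), n_outside = sum(!ins),
      mean_inside = mean_inside, mean_outside = mean_outside,
      difference = mean_inside - mean_outside
    )
  })
  bind_rows(res)
}

#' Per-probe methylation change versus the normal mean
#'
#' Convenience builder of the `probe_values` input to [lad_contrast()] and
#' [window_means()]: the mean across the chosen samples of
#' (beta - normal mean) per probe, or of raw beta when `normal_mean` is
#' `NULL`.
#'
#' @param beta Probes x samples beta matrix.
#' @param manifest Probe manifest (`probe_id`, `chrom`, `pos`).
#' @param samples Columns of `beta` to average over (default all).
#' @param normal_mean Optional named per-probe normal means from
#'   [normal_reference()].
#' @return Tibble with `probe_id`, `chrom`, `pos`, `value`, `n_samples`.
#' @export
probe_change <- function(beta, manifest, samples = colnames(beta),
                         normal_mean = NULL) {
  validate_manifest(manifest)
  common <- intersect(manifest$probe_id, rownames(beta))
  sub <- beta[common, samples, drop = FALSE]
  if (!is.null(normal_mean)) {
    ref <- normal_mean[common]
    sub <- sub - ref
  }
  out <- tibble(
    probe_id = common,
    value = rowMeans(sub, na.rm = TRUE),
    n_samples = rowSums(!is.na(sub))
  )
  out$value[out$n_samples == 0] <- NA_real_
  left_join(
    out,
    manifest[c("probe_id", "chrom", "pos")],
    by = "probe_id"
  )[, c("probe_id", "chrom", "pos", "value", "n_samples")]
}
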