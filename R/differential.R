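# Per-sample differential CpG calling against the normal-tissue mean, and
# TF-binding-site enrichment of the calls.
#
# A CpG is hypermethylated in a sample when beta - normal_mean > 0.2 and
# hypomethylated when normal_mean - beta > 0.2 (strict inequalities). For a
# TF the enrichment rate is
#   (DM CpGs inside TF sites / CpGs inside TF sites) /
#   (DM CpGs outside TF sites / CpGs outside TF sites),
# computed per sample and per direction over the universe of retained,
# annotated probes.

#' Per-probe mean methylation of normal samples
#'
#' @param beta Probes x samples beta matrix (`NA` = masked).
#' @param normal_ids Sample ids (columns of `beta`) of the normal cohort.
#' @param min_normals Minimum unmasked normal values a probe needs before a
#'   mean is reported (default 2).
#' @return Named numeric vector of per-probe normal means; probes with fewer
#'   than `min_normals` usable normals are `NA`.
#' @export
normal_reference <- function(beta, normal_ids, min_normals = 2) {
  missing_ids <- setdiff(normal_ids, colnames(beta))
  if (length(missing_ids) > 0) {
    abort(sprintf("normal ids not in beta matrix: %s", paste(missing_ids, collapse = ", ")))
  }
  if (length(normal_ids) < min_normals) {
    abort(sprintf("need at least %d normal samples", min_normals))
  }
  sub <- beta[, normal_ids, drop = FALSE]
  n_ok <- rowSums(!is.na(sub))
  m <- rowMeans(sub, na.rm = TRUE)
  m[n_ok < min_normals] <- NA_real_
  m
}

#' Call differentially methylated CpGs per sample
#'
#' Compares each sample's unmasked beta values to the per-probe normal mean
#' and calls probes with change strictly greater than `threshold` in either
#' direction. Probes masked in the sample or lacking a normal mean are
#' excluded from the universe.
#'
#' @param beta Probes x samples beta matrix (`NA` = masked).
#' @param normal_mean Named per-probe normal means from
#'   [normal_reference()].
#' @param samples Sample ids to call (default: all columns of `beta`).
#' @param threshold Minimum absolute methylation change (default 0.2,
#'   strict `>`).
#' @return A tibble with `sample_id`, `probe_id`, `delta`
#'   (beta - normal mean) and `direction` (`"hyper"`/`"hypo"`), one row per
#'   call; the per-sample universe sizes are in the `"universe_size"`
#'   attribute.
#' @export
call_differential <- function(beta, normal_mean, samples = colnames(beta),
                              threshold = 0.2) {
  common <- intersect(rownames(beta), names(normal_mean))
  if (length(common) == 0) abort("no probes shared between beta and normal_mean")
  ref <- normal_mean[common]
  sub <- beta[common, samples, drop = FALSE]
  delta <- sub - ref
  usable <- !is.na(delta)
  calls <- purrr::map(samples, function(s) {
    d <- delta[, s]
    idx <- which(!is.na(d) & abs(d) > threshold)
    if (length(idx) == 0) {
      return(tibble(
        sample_id = character(), probe_id = character(),
        delta = numeric(), direction = character()
      ))
    }
    tibble(
      sample_id = s, probe_id = common[idx], delta = unname(d[idx]),
      direction = ifelse(d[idx] > 0, "hyper", "hypo")
    )
  })
  out <- bind_rows(calls)
  attr(out, "universe_size") <- stats::setNames(colSums(usable), samples)
  attr(out, "threshold") <- threshold
  out
}

#' TF-binding-site enrichment rate
#'
#' The ratio of the differentially methylated fraction among probes inside a
#' TF's binding sites to the fraction among probes outside:
#' `(dm_in/total_in) / (dm_out/total_out)`. All arguments are vectorized.
#'
#' @param dm_in,total_in Differentially methylated and total probe counts
#'   inside the TF sites.
#' @param dm_out,total_out The same counts outside the TF sites.
#' @return Numeric enrichment rate; `NA` when `dm_out` is 0 (the ratio is
#'   undefined rather than infinite) and 0 when only `dm_in` is 0.
#' @examples
#' enrichment_rate(10, 100, 50, 1000) # 2
#' @export
enrichment_rate <- function(dm_in, total_in, dm_out, total_out) {
  n <- max(length(dm_in), length(total_in), length(dm_out), length(total_out))
  dm_in <- rep_len(dm_in, n)
  total_in <- rep_len(total_in, n)
  dm_out <- rep_len(dm_out, n)
  total_out <- rep_len(total_out, n)
  if (any(total_in <= 0 | total_out <= 0, na.rm = TRUE)) {
    abort("total_in and total_out must be positive")
  }
  if (any(dm_in > total_in | dm_out > total_out, na.rm = TRUE)) {
    abort("differentially methylated counts cannot exceed totals")
  }
  out <- (dm_in / total_in) / (dm_out / total_out)
  out[dm_out == 0] <- NA_real_
  out
}

#' Per-sample TF enrichment profile
#'
#' Computes, for every sample and TF, the enrichment rate of hyper- and
#' hypomethylated CpGs inside the TF's binding sites relative to outside.
#' The probe universe is the set of probes in `manifest` (retained, annotated
#' probes) that had a usable comparison in the sample.
#'
#' @param calls Differential calls from [call_differential()].
#' @param tf_sites Region tibble of TF-binding sites with a `name` column
#'   identifying the factor (BED6-style).
#' @param manifest Probe manifest restricted to the analysis universe
#'   (`probe_id`, `chrom`, `pos`).
#' @return A tibble with one row per sample x TF x direction: `sample_id`,
#'   `tf`, `direction`, `dm_in`, `total_in`, `dm_out`, `total_out`, `rate`.
#'   TFs whose sites contain no universe probe are dropped.
#' @export
tf_enrichment <- function(calls, tf_sites, manifest) {
  validate_manifest(manifest)
  validate_regions(tf_sites, "tf_sites")
  if (!"name" %in% names(tf_sites)) {
    abort("`tf_sites` must have a name column identifying the factor")
  }
  probe_gr <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos + 1, width = 1)
  )
  tf_names <- unique(tf_sites$name)
  in_tf <- purrr::map(tf_names, function(tf) {
    sites <- tf_sites[tf_sites$name == tf, c("chrom", "start", "end")]
    suppressWarnings(IRanges::overlapsAny(probe_gr, regions_to_gr(sites)))
  })
  names(in_tf) <- tf_names
  empty_tfs <- tf_names[vapply(in_tf, sum, numeric(1)) == 0]
  if (length(empty_tfs) > 0) {
    rlang::inform(sprintf(
      "skipping %d TF(s) with no probes in their sites: %s",
      length(empty_tfs), paste(empty_tfs, collapse = ", ")
    ))
    in_tf <- in_tf[setdiff(tf_names, empty_tfs)]
  }
  if (length(in_tf) == 0) abort("no TF has any probe in its sites")
  universe_size <- attr(calls, "universe_size")
  samples <- if (!is.null(universe_size)) names(universe_size) else unique(calls$sample_id)
  probe_in_universe <- manifest$probe_id
  grid <- tidyr::expand_grid(
    sample_id = samples, tf = names(in_tf), direction = c("hyper", "hypo")
  )
  res <- purrr::pmap(grid, function(sample_id, tf, direction) {
    member <- in_tf[[tf]]
    dm_probes <- calls$probe_id[calls$sample_id == sample_id &
      calls$direction == direction]
    dm_member <- probe_in_universe %in% dm_probes
    dm_in <- sum(member & dm_member)
    dm_out <- sum(!member & dm_member)
    total_in <- sum(member)
    total_out <- sum(!member)
    rate <- if (total_in == 0 || total_out == 0) {
      NA_real_
    } else {
      enrichment_rate(dm_in, total_in, dm_out, total_out)
    }
    tibble(
      sample_id = sample_id, tf = tf, direction = direction,
      dm_in = dm_in, total_in = total_in,
      dm_out = dm_out, total_out = total_out, rate = rate
    )
  })
  bind_rows(res)
}
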