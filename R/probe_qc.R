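# Probe-level quality control for array-style methylation data.
#
# The manifest is a tibble with one row per probe:
#   probe_id, chrom, pos (single CpG coordinate, 0-based),
#   snp_dist (bp to nearest common SNP, NA when none nearby),
#   repeat_within_15bp (0/1 flag precomputed against a repeat track),
#   type ("I"/"II", metadata only).
# Beta and detection-p matrices are probes x samples; a masked beta cell
# is NA.

validate_manifest <- function(manifest) {
  req <- c("probe_id", "chrom", "pos")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "manifest must have columns probe_id/chrom/pos (missing: %s)",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(manifest$probe_id)) abort("duplicate probe ids in manifest")
  if (any(manifest$pos < 0, na.rm = TRUE)) abort("manifest has negative positions")
  if ("snp_dist" %in% names(manifest) &&
    any(manifest$snp_dist < 0, na.rm = TRUE)) {
    abort("manifest has negative SNP distances")
  }
  invisible(manifest)
}

#' Apply global probe masks
#'
#' Removes probes that are unreliable in every sample: probes with a common
#' SNP within `snp_window` bp of the interrogated CpG, probes whose
#' `repeat_within_15bp` flag marks a repeat element within the repeat window,
#' and probes on sex chromosomes. Both distance rules are inclusive
#' (distance <= threshold removes the probe).
#'
#' @param manifest Probe manifest tibble (see Details in
#'   [assign_regions()]); needs `probe_id`, `chrom`, and optionally
#'   `snp_dist` and `repeat_within_15bp`.
#' @param snp_window Maximum tolerated SNP distance in bp (default 10);
#'   probes at distance <= `snp_window` are removed.
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return The retained subset of `manifest`, with a `"n_removed"` attribute
#'   giving per-rule removal counts (a probe can fall under several rules).
#' @examples
#' m <- tibble::tibble(
#'   probe_id = c("p1", "p2", "p3"), chrom = c("chr1", "chrX", "chr1"),
#'   pos = c(100, 200, 300), snp_dist = c(8, NA, 11),
#'   repeat_within_15bp = c(0, 0, 0)
#' )
#' filter_probes(m) # keeps only p3
#' @export
filter_probes <- function(manifest, snp_window = 10,
                          sex_chroms = c("chrX", "chrY", "X", "Y")) {
  validate_manifest(manifest)
  snp_hit <- if ("snp_dist" %in% names(manifest)) {
    !is.na(manifest$snp_dist) & manifest$snp_dist <= snp_window
  } else {
    rep(FALSE, nrow(manifest))
  }
  repeat_hit <- if ("repeat_within_15bp" %in% names(manifest)) {
    !is.na(manifest$repeat_within_15bp) & manifest$repeat_within_15bp > 0
  } else {
    rep(FALSE, nrow(manifest))
  }
  sex_hit <- manifest$chrom %in% sex_chroms
  keep <- !(snp_hit | repeat_hit | sex_hit)
  out <- manifest[keep, , drop = FALSE]
  attr(out, "n_removed") <- c(
    snp = sum(snp_hit), repeat_element = sum(repeat_hit),
    sex_chrom = sum(sex_hit), total = sum(!keep)
  )
  out
}

#' Mask beta values by detection p-value
#'
#' Sets to `NA` (masked) every cell whose detection p-value is strictly
#' greater than the cutoff; a probe that fails detection in one sample stays
#' usable in the others. Already-masked cells stay masked, so masking is
#' monotone.
#'
#' @param beta Numeric probes x samples matrix of beta values; `NA` = masked.
#' @param detection_p Numeric matrix of the same dimensions, rownames and
#'   colnames.
#' @param cutoff Detection p-value threshold (default 0.05, strict `>`).
#' @return `beta` with failing cells set to `NA`.
#' @export
mask_detection <- function(beta, detection_p, cutoff = 0.05) {
  if (!identical(dim(beta), dim(detection_p))) {
    abort("`beta` and `detection_p` must have identical dimensions")
  }
  if (!is.null(rownames(beta)) && !is.null(rownames(detection_p)) &&
    !identical(rownames(beta), rownames(detection_p))) {
    abort("`beta` and `detection_p` have different probe ids")
  }
  if (!is.null(colnames(beta)) && !is.null(colnames(detection_p)) &&
    !identical(colnames(beta), colnames(detection_p))) {
    abort("`beta` and `detection_p` have different sample ids")
  }
  beta[!is.na(detection_p) & detection_p > cutoff] <- NA_real_
  beta
}

#' Assign probes to region classes
#'
#' Tests each probe's CpG coordinate for membership in every supplied region
#' class using half-open interval membership (`start <= pos < end`). A probe
#' may carry several functional labels; the `backbone` label (when the
#' backbone set is supplied) is exclusive by construction, since the backbone
#' is the complement of all other classes. Probes falling in no supplied
#' region are flagged `unannotated`.
#'
#' @param manifest Probe manifest tibble with `probe_id`, `chrom`, `pos`.
#' @param regions Named list of normalized region tibbles, e.g. from
#'   [build_region_taxonomy()]; names become label columns.
#' @return A tibble with `probe_id`, `chrom`, `pos`, one logical column per
#'   region class, and a logical `unannotated` column.
#' @export
assign_regions <- function(manifest, regions) {
  validate_manifest(manifest)
  if (is.null(names(regions)) || any(names(regions) == "")) {
    abort("`regions` must be a named list of region tibbles")
  }
  probe_gr <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos + 1, width = 1)
  )
  out <- tibble(
    probe_id = manifest$probe_id,
    chrom = manifest$chrom,
    pos = manifest$pos
  )
  for (class_name in names(regions)) {
    reg <- regions[[class_name]]
    validate_regions(reg, class_name)
    hit <- rep(FALSE, nrow(manifest))
    if (nrow(reg) > 0) {
      reg_gr <- regions_to_gr(reg[c("chrom", "start", "end")])
      shared <- intersect(
        GenomeInfoDb::seqlevels(probe_gr), GenomeInfoDb::seqlevels(reg_gr)
      )
      if (length(shared) > 0) {
        hit <- suppressWarnings(IRanges::overlapsAny(probe_gr, reg_gr))
      }
    }
    out[[class_name]] <- hit
  }
  out$unannotated <- rowSums(as.matrix(out[names(regions)])) == 0
  out
}

#' Count retained probes per region class
#'
#' @param assignment Output of [assign_regions()].
#' @return A tibble with `region` and `n_probes`, one row per class.
#' @export
region_probe_counts <- function(assignment) {
  classes <- setdiff(names(assignment), c("probe_id", "chrom", "pos", "unannotated"))
  tibble(
    region = classes,
    n_probes = vapply(classes, function(cl) sum(assignment[[cl]]), integer(1))
  )
}
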