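# Per-sample methylation summaries and HC/NC x LB/NB classification.
#
# The two axes of the analysis are each sample's average beta over CpG-island
# probes (avg_cgi) and over backbone probes (avg_backbone). In normal tissue
# the two sit in narrow windows (CGI ~0.18-0.24 hypomethylated, backbone
# ~0.78-0.82 hypermethylated); tumors deviate toward CGI hypermethylation
# (HC) and/or backbone hypomethylation (LB).

#' Average methylation over a region class
#'
#' Arithmetic mean of the unmasked beta values of all probes carrying the
#' given class label, per sample (pairwise-complete: masked cells contribute
#' nothing). Samples with fewer than `min_probes` usable probes get `NA`.
#'
#' @param beta Probes x samples beta matrix (`NA` = masked).
#' @param assignment Probe-region assignment from [assign_regions()].
#' @param region_class Name of a logical label column in `assignment`.
#' @param min_probes Minimum unmasked probes required per sample
#'   (default 100).
#' @return A tibble with `sample_id`, `avg` and `n_used`.
#' @export
average_region_methylation <- function(beta, assignment, region_class,
                                       min_probes = 100) {
  if (!region_class %in% names(assignment)) {
    abort(sprintf("region class '%s' not in assignment", region_class))
  }
  probes <- assignment$probe_id[assignment[[region_class]]]
  probes <- intersect(probes, rownames(beta))
  sub <- beta[probes, , drop = FALSE]
  n_used <- colSums(!is.na(sub))
  avg <- colMeans(sub, na.rm = TRUE)
  avg[n_used < min_probes] <- NA_real_
  avg[is.nan(avg)] <- NA_real_
  tibble(sample_id = colnames(beta), avg = unname(avg), n_used = unname(n_used))
}

#' Classify samples on the CGI and backbone axes
#'
#' A sample is HC (high CGI methylation) when its average CGI beta exceeds
#' `cgi_cut`, otherwise NC; it is LB (low backbone methylation) when its
#' average backbone beta falls below `backbone_cut`, otherwise NB. Both
#' boundaries belong to the normal classes (`<= cgi_cut` is NC,
#' `>= backbone_cut` is NB). The default cutoffs 0.24 and 0.78 are the edges
#' of the normal-tissue windows; see [calibrate_cutoffs()] to re-derive them
#' from a normal cohort.
#'
#' @param avg_cgi,avg_backbone Numeric vectors of per-sample averages
#'   (`NA` allowed; the class on that axis is then `NA`).
#' @param cgi_cut HC threshold on average CGI methylation (default 0.24).
#' @param backbone_cut LB threshold on average backbone methylation
#'   (default 0.78).
#' @return A tibble with `cgi_class` (`"HC"`/`"NC"`) and `backbone_class`
#'   (`"LB"`/`"NB"`).
#' @examples
#' classify_methylation(c(0.24, 0.25), c(0.78, 0.77))
#' @export
classify_methylation <- function(avg_cgi, avg_backbone,
                                 cgi_cut = 0.24, backbone_cut = 0.78) {
  if (length(avg_cgi) != length(avg_backbone)) {
    abort("`avg_cgi` and `avg_backbone` must have equal length")
  }
  tibble(
    cgi_class = ifelse(is.na(avg_cgi), NA_character_,
      ifelse(avg_cgi > cgi_cut, "HC", "NC")
    ),
    backbone_class = ifelse(is.na(avg_backbone), NA_character_,
      ifelse(avg_backbone < backbone_cut, "LB", "NB")
    )
  )
}

#' Summarize a cohort's methylation per sample
#'
#' Computes each sample's average CGI and backbone methylation over unmasked
#' probes and classifies it on both axes.
#'
#' @param beta Probes x samples beta matrix (`NA` = masked).
#' @param assignment Probe-region assignment from [assign_regions()]; must
#'   contain `cgi` and `backbone` label columns.
#' @param sample_info Optional tibble with `sample_id` and any of `tissue`,
#'   `tumor_type`; joined onto the result.
#' @inheritParams classify_methylation
#' @inheritParams average_region_methylation
#' @return A `meth_summary` tibble with one row per sample: `sample_id`,
#'   optional `tissue`/`tumor_type`, `avg_cgi`, `avg_backbone`, `n_cgi`,
#'   `n_backbone`, `cgi_class`, `backbone_class`.
#' @export
summarize_samples <- function(beta, assignment, sample_info = NULL,
                              cgi_cut = 0.24, backbone_cut = 0.78,
                              min_probes = 100) {
  cgi <- average_region_methylation(beta, assignment, "cgi", min_probes)
  bb <- average_region_methylation(beta, assignment, "backbone", min_probes)
  out <- tibble(
    sample_id = cgi$sample_id,
    avg_cgi = cgi$avg, avg_backbone = bb$avg,
    n_cgi = cgi$n_used, n_backbone = bb$n_used
  )
  out <- dplyr::bind_cols(
    out,
    classify_methylation(out$avg_cgi, out$avg_backbone, cgi_cut, backbone_cut)
  )
  if (!is.null(sample_info)) {
    keep <- intersect(c("sample_id", "tissue", "tumor_type"), names(sample_info))
    out <- left_join(out, sample_info[keep], by = "sample_id")
    out <- out[, c(
      "sample_id", intersect(c("tissue", "tumor_type"), names(out)),
      "avg_cgi", "avg_backbone", "n_cgi", "n_backbone",
      "cgi_class", "backbone_class"
    )]
  }
  class(out) <- c("meth_summary", class(out))
  out
}

#' Recalibrate classification cutoffs from a normal cohort
#'
#' The default cutoffs are the edges of the observed normal windows; given a
#' normal cohort, this re-derives them the same way: the HC threshold is the
#' maximum normal average CGI methylation and the LB threshold the minimum
#' normal average backbone methylation.
#'
#' @param normal_summary A [summarize_samples()] tibble of normal samples.
#' @return A list with `cgi_cut` and `backbone_cut`.
#' @export
calibrate_cutoffs <- function(normal_summary) {
  if (nrow(normal_summary) == 0 || all(is.na(normal_summary$avg_cgi))) {
    abort("no usable normal samples to calibrate from")
  }
  list(
    cgi_cut = max(normal_summary$avg_cgi, na.rm = TRUE),
    backbone_cut = min(normal_summary$avg_backbone, na.rm = TRUE)
  )
}

#' Cross-platform concordance of average methylation
#'
#' Pearson correlation between per-sample average methylation computed from
#' the array and from a paired second platform (e.g. WGBS), pooling the CGI
#' and backbone axes as one point set, with per-axis correlations reported
#' alongside.
#'
#' @param array_summary Tibble with `sample_id`, `avg_cgi`, `avg_backbone`
#'   (array-derived).
#' @param other_summary Tibble with `sample_id` and paired averages; columns
#'   named by `cols` (default `wgbs_cgi`, `wgbs_backbone`).
#' @param cols Length-2 named character vector mapping `avg_cgi`/
#'   `avg_backbone` to the paired columns.
#' @return A `meth_concordance` object (list) with `n_pairs`, `r_pooled`,
#'   `r_cgi`, `r_backbone` and the paired data; see [tidy()] / [glance()].
#' @export
concordance <- function(array_summary, other_summary,
                        cols = c(avg_cgi = "wgbs_cgi", avg_backbone = "wgbs_backbone")) {
  if (!all(c("avg_cgi", "avg_backbone") %in% names(cols))) {
    abort("`cols` must name wgbs columns for avg_cgi and avg_backbone")
  }
  paired <- inner_join(
    array_summary[c("sample_id", "avg_cgi", "avg_backbone")],
    other_summary[c("sample_id", unname(cols))],
    by = "sample_id"
  )
  paired <- paired[stats::complete.cases(paired), , drop = FALSE]
  if (nrow(paired) < 3) {
    abort(sprintf("need at least 3 complete paired samples, got %d", nrow(paired)))
  }
  x_pool <- c(paired$avg_cgi, paired$avg_backbone)
  y_pool <- c(paired[[cols[["avg_cgi"]]]], paired[[cols[["avg_backbone"]]]])
  out <- list(
    n_pairs = nrow(paired),
    r_pooled = stats::cor(x_pool, y_pool),
    r_cgi = stats::cor(paired$avg_cgi, paired[[cols[["avg_cgi"]]]]),
    r_backbone = stats::cor(paired$avg_backbone, paired[[cols[["avg_backbone"]]]]),
    paired = as_tibble(paired)
  )
  class(out) <- "meth_concordance"
  out
}

#' @export
print.meth_concordance <- function(x, ...) {
  cat(sprintf(
    "Cross-platform concordance over %d paired samples\n  pooled r = %.3f (CGI r = %.3f, backbone r = %.3f)\n",
    x$n_pairs, x$r_pooled, x$r_cgi, x$r_backbone
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concordance result
#'
#' @param x A `meth_concordance` object.
#' @param ... Unused.
#' @return One row per axis (`pooled`, `cgi`, `backbone`) with the Pearson
#'   correlation and the number of paired samples.
#' @exportS3Method generics::tidy
tidy.meth_concordance <- function(x, ...) {
  tibble(
    axis = c("pooled", "cgi", "backbone"),
    r = c(x$r_pooled, x$r_cgi, x$r_backbone),
    n_pairs = x$n_pairs
  )
}

#' @rdname tidy.meth_concordance
#' @return For `glance()`: a one-row tibble with `r_pooled`, `r_cgi`,
#'   `r_backbone`, `n_pairs`.
#' @exportS3Method generics::glance
glance.meth_concordance <- function(x, ...) {
  tibble(
    r_pooled = x$r_pooled, r_cgi = x$r_cgi,
    r_backbone = x$r_backbone, n_pairs = x$n_pairs
  )
}
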