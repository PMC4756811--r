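# Association battery between per-sample methylation averages and clinical /
# molecular variables.
#
# Scale determines the test: Wilcoxon rank-sum for binary variables,
# Kruskal-Wallis for categorical ones, Kendall rank correlation (tau-b) for
# continuous ones; clinical variables additionally get a linear model
# adjusted for age and sex. Every scan applies Benjamini-Hochberg correction
# over its declared family of comparisons.

assoc_row <- function(variable, outcome, test, estimate = NA_real_,
                      statistic = NA_real_, p_value = NA_real_,
                      n_used = NA_integer_, note = NA_character_) {
  tibble(
    variable = variable, outcome = outcome, test = test,
    estimate = estimate, statistic = statistic, p_value = p_value,
    n_used = as.integer(n_used), note = note
  )
}

#' Benjamini-Hochberg adjustment over a declared family
#'
#' Standard step-up BH q-values. The family size defaults to the number of
#' non-missing p-values but can be declared explicitly (e.g. the total
#' number of genes attempted in a genome-wide scan, whether or not each test
#' returned a value).
#'
#' @param p Numeric vector of raw p-values (`NA` allowed).
#' @param m Family size; default `sum(!is.na(p))`.
#' @return Vector of q-values, `NA` where `p` is `NA`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p, m = NULL) {
  m <- m %||% sum(!is.na(p))
  if (m < sum(!is.na(p))) {
    abort("family size m cannot be smaller than the number of p-values")
  }
  stats::p.adjust(p, method = "BH", n = max(m, 1L))
}

#' Age- and sex-adjusted clinical association
#'
#' Fits, for each requested clinical variable and methylation outcome, the
#' linear model `outcome ~ variable + age + sex` and reports the variable
#' coefficient with its two-sided p-value. Sex is dropped from the model
#' when the cohort is single-sex ("wherever applicable"), and age likewise
#' when constant. Degenerate designs (constant or collinear variable)
#' return a missing result with a diagnostic note.
#'
#' @param summary A [summarize_samples()] tibble (or any tibble with
#'   `sample_id` and the outcome columns).
#' @param clinical Tibble with `sample_id`, `age`, `sex` and numeric-coded
#'   clinical variables (ordinal variables as monotone codes, categorical
#'   ones dummy-coded).
#' @param variables Character vector of clinical variable columns to test.
#' @param outcomes Methylation outcome columns
#'   (default `avg_cgi` and `avg_backbone`, tested separately).
#' @param covariates Adjustment covariates (default age and sex).
#' @return A `meth_assoc` tibble with one row per variable x outcome:
#'   `variable`, `outcome`, `test`, `estimate` (slope), `statistic` (t),
#'   `p_value`, `q_value` (BH within this scan), `n_used`, `note`.
#' @export
assoc_clinical <- function(summary, clinical, variables,
                           outcomes = c("avg_cgi", "avg_backbone"),
                           covariates = c("age", "sex")) {
  dat <- inner_join(as_tibble(summary), as_tibble(clinical), by = "sample_id")
  missing_vars <- setdiff(c(variables, intersect(covariates, "age")), names(dat))
  if (length(missing_vars) > 0) {
    abort(sprintf("clinical columns not found: %s", paste(missing_vars, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(variable = variables, outcome = outcomes)
  res <- purrr::pmap(grid, function(variable, outcome) {
    d <- dat[, unique(c(outcome, variable, intersect(covariates, names(dat))))]
    names(d)[1:2] <- c(".y", ".x")
    d <- d[stats::complete.cases(d), , drop = FALSE]
    n <- nrow(d)
    if (n < 4 || length(unique(d$.x)) < 2) {
      return(assoc_row(variable, outcome, "linear_adjusted",
        n_used = n, note = "constant variable or too few samples"
      ))
    }
    covs <- setdiff(names(d), c(".y", ".x"))
    # single-sex cohorts (and any other constant covariate) drop out
    covs <- covs[vapply(covs, function(cv) length(unique(d[[cv]])) > 1, logical(1))]
    form <- stats::reformulate(c(".x", covs), response = ".y")
    fit <- stats::lm(form, data = d)
    # any aliased coefficient means the variable is confounded with a
    # covariate (R drops whichever term comes later); the adjusted effect is
    # not identifiable either way
    if (anyNA(stats::coef(fit))) {
      return(assoc_row(variable, outcome, "linear_adjusted",
        n_used = n, note = "variable collinear with covariates"
      ))
    }
    co <- stats::coef(summary(fit))
    assoc_row(variable, outcome, "linear_adjusted",
      estimate = co[".x", "Estimate"], statistic = co[".x", "t value"],
      p_value = co[".x", "Pr(>|t|)"], n_used = n
    )
  })
  out <- bind_rows(res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[, c(
    "variable", "outcome", "test", "estimate", "statistic",
    "p_value", "q_value", "n_used", "note"
  )]
  class(out) <- c("meth_assoc", class(out))
  out
}

#' Rank-based molecular association
#'
#' Applies the scale-appropriate rank test between a methylation average and
#' molecular variables: Wilcoxon rank-sum for binary variables (e.g.
#' mutation present/absent), Kruskal-Wallis for categorical ones (e.g.
#' cluster labels), and Kendall rank correlation (tau-b) for continuous ones
#' (e.g. copy-number log2-ratios).
#'
#' @param summary A [summarize_samples()] tibble.
#' @param data Tibble with `sample_id` and the molecular variable columns.
#' @param variables Character vector of columns of `data` to test.
#' @param scale One of `"binary"`, `"categorical"`, `"continuous"`; applies
#'   to all `variables` in this call.
#' @param outcomes Methylation outcome columns (tested separately).
#' @return A `meth_assoc` tibble (one row per variable x outcome) with the
#'   test statistic, an effect summary in `estimate` (location shift for
#'   Wilcoxon, tau for Kendall), raw `p_value`, `q_value` (BH within this
#'   scan), `n_used` and `note`.
#' @export
assoc_molecular <- function(summary, data, variables,
                            scale = c("binary", "categorical", "continuous"),
                            outcomes = c("avg_cgi", "avg_backbone")) {
  scale <- match.arg(scale)
  dat <- inner_join(as_tibble(summary), as_tibble(data), by = "sample_id")
  missing_vars <- setdiff(variables, names(dat))
  if (length(missing_vars) > 0) {
    abort(sprintf("molecular columns not found: %s", paste(missing_vars, collapse = ", ")))
  }
  test_name <- switch(scale,
    binary = "wilcoxon", categorical = "kruskal_wallis", continuous = "kendall"
  )
  grid <- tidyr::expand_grid(variable = variables, outcome = outcomes)
  res <- purrr::pmap(grid, function(variable, outcome) {
    y <- dat[[outcome]]
    x <- dat[[variable]]
    ok <- !is.na(y) & !is.na(x)
    y <- y[ok]
    x <- x[ok]
    n <- length(y)
    if (n < 3 || length(unique(x)) < 2) {
      return(assoc_row(variable, outcome, test_name,
        n_used = n, note = "constant variable or too few samples"
      ))
    }
    if (scale == "binary") {
      groups <- sort(unique(x))
      if (length(groups) != 2) {
        return(assoc_row(variable, outcome, test_name,
          n_used = n, note = "binary variable does not have 2 levels"
        ))
      }
      if (min(table(x)) < 2) {
        return(assoc_row(variable, outcome, test_name,
          n_used = n, note = "group with fewer than 2 samples"
        ))
      }
      ht <- suppressWarnings(stats::wilcox.test(y[x == groups[2]], y[x == groups[1]]))
      est <- stats::median(y[x == groups[2]]) - stats::median(y[x == groups[1]])
      assoc_row(variable, outcome, test_name,
        estimate = est, statistic = unname(ht$statistic),
        p_value = ht$p.value, n_used = n
      )
    } else if (scale == "categorical") {
      ht <- stats::kruskal.test(y, factor(x))
      assoc_row(variable, outcome, test_name,
        statistic = unname(ht$statistic), p_value = ht$p.value, n_used = n
      )
    } else {
      ht <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
      assoc_row(variable, outcome, test_name,
        estimate = unname(ht$estimate), statistic = unname(ht$statistic),
        p_value = ht$p.value, n_used = n
      )
    }
  })
  out <- bind_rows(res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[, c(
    "variable", "outcome", "test", "estimate", "statistic",
    "p_value", "q_value", "n_used", "note"
  )]
  class(out) <- c("meth_assoc", class(out))
  out
}

#' Gene-level copy-number association scan
#'
#' For each gene, a Kendall rank correlation between its copy-number
#' log2-ratio and a per-sample methylation average, BH-corrected over the
#' whole scan with family size equal to the number of genes attempted (the
#' genome-wide convention: m is the gene count, not the count of tests that
#' converged). Results are ordered by genomic position for positional
#' plotting.
#'
#' @param summary A [summarize_samples()] tibble.
#' @param cn Samples x genes numeric matrix of copy-number log2-ratios with
#'   sample rownames and gene colnames.
#' @param gene_coords Tibble with `name`, `chrom`, `start` (and optionally
#'   `end`) giving gene positions; genes without coordinates are placed
#'   last.
#' @param outcome Methylation outcome column (default `avg_backbone`).
#' @return A `meth_assoc`-style tibble ordered by chromosome and start, one
#'   row per gene: `gene`, `chrom`, `start`, `tau`, `statistic`, `p_value`,
#'   `q_value`, `n_used`, `note`.
#' @export
scna_scan <- function(summary, cn, gene_coords = NULL, outcome = "avg_backbone") {
  summary <- as_tibble(summary)
  if (is.null(rownames(cn))) abort("`cn` must have sample rownames")
  common <- intersect(summary$sample_id, rownames(cn))
  if (length(common) < 3) abort("fewer than 3 samples shared between summary and cn")
  y <- summary[[outcome]][match(common, summary$sample_id)]
  genes <- colnames(cn)
  res <- purrr::map(genes, function(g) {
    x <- cn[common, g]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || length(unique(x[ok])) < 2) {
      return(tibble(
        gene = g, tau = NA_real_, statistic = NA_real_,
        p_value = NA_real_, n_used = n,
        note = "constant log2ratio or too few samples"
      ))
    }
    ht <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "kendall"))
    tibble(
      gene = g, tau = unname(ht$estimate), statistic = unname(ht$statistic),
      p_value = ht$p.value, n_used = n, note = NA_character_
    )
  })
  out <- bind_rows(res)
  out$q_value <- bh_adjust(out$p_value, m = length(genes))
  if (!is.null(gene_coords)) {
    out <- left_join(out, gene_coords[c("name", "chrom", "start")],
      by = c(gene = "name")
    )
    out <- arrange(out, is.na(.data$chrom), .data$chrom, .data$start)
  } else {
    out$chrom <- NA_character_
    out$start <- NA_real_
  }
  out <- out[, c(
    "gene", "chrom", "start", "tau", "statistic",
    "p_value", "q_value", "n_used", "note"
  )]
  class(out) <- c("meth_assoc", class(out))
  out
}

#' Cross-tumor percentile summary of scan p-values
#'
#' Summarizes per-gene corrected p-values across tumor types by their 10th,
#' 20th, 30th and 40th percentiles (linear interpolation between closest
#' ranks), so that loci recurrently associated across tumor types stand out
#' when plotted along the genome.
#'
#' @param scans Tibble concatenating per-tumor-type [scna_scan()] outputs,
#'   with columns `tumor_type`, `gene`, `chrom`, `start` and the p-value
#'   column named by `p_col` (default `q_value`).
#' @param probs Percentiles to report (default 0.1, 0.2, 0.3, 0.4).
#' @param p_col Column summarized across tumor types.
#' @return A tibble with one row per gene (present in >= 2 tumor types):
#'   `gene`, `chrom`, `start`, `n_types` and one `p<percentile>` column per
#'   requested percentile, ordered by position.
#' @export
cross_tumor_percentiles <- function(scans, probs = c(0.1, 0.2, 0.3, 0.4),
                                    p_col = "q_value") {
  if (!all(c("tumor_type", "gene", p_col) %in% names(scans))) {
    abort(sprintf("`scans` must have columns tumor_type, gene and %s", p_col))
  }
  if (length(unique(scans$tumor_type)) < 2) {
    abort("need scans from at least 2 tumor types")
  }
  out <- scans |>
    filter(!is.na(.data[[p_col]])) |>
    group_by(.data$gene) |>
    summarise(
      chrom = dplyr::first(.data$chrom),
      start = dplyr::first(.data$start),
      n_types = dplyr::n_distinct(.data$tumor_type),
      value = list(stats::quantile(.data[[p_col]], probs = probs, type = 7, names = FALSE)),
      .groups = "drop"
    ) |>
    filter(.data$n_types >= 2)
  pct <- do.call(rbind, out$value)
  colnames(pct) <- paste0("p", round(probs * 100))
  out <- dplyr::bind_cols(select(out, -"value"), as_tibble(pct))
  arrange(out, .data$chrom, .data$start)
}

#' Gene-body methylation vs. expression correlation
#'
#' Rank correlation (Spearman) per gene between the mean gene-body backbone
#' methylation and expression across paired samples.
#'
#' @param body_meth Genes x samples matrix of mean gene-body backbone beta
#'   values.
#' @param expression Genes x samples matrix of expression values, same
#'   rownames and compatible colnames.
#' @return A tibble with one row per gene: `gene`, `rho`, `p_value`,
#'   `n_used`, `note`; genes with constant expression or methylation are
#'   missing with a note.
#' @export
body_expression_correlation <- function(body_meth, expression) {
  genes <- intersect(rownames(body_meth), rownames(expression))
  samples <- intersect(colnames(body_meth), colnames(expression))
  if (length(genes) == 0 || length(samples) < 3) {
    abort("need shared genes and at least 3 shared samples")
  }
  res <- purrr::map(genes, function(g) {
    x <- body_meth[g, samples]
    y <- expression[g, samples]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
      return(tibble(
        gene = g, rho = NA_real_, p_value = NA_real_, n_used = n,
        note = "constant values or too few samples"
      ))
    }
    ht <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    tibble(
      gene = g, rho = unname(ht$estimate), p_value = ht$p.value,
      n_used = n, note = NA_character_
    )
  })
  bind_rows(res)
}

#' Tidy an association table
#'
#' `meth_assoc` results are already tidy; `tidy()` strips the class and
#' `glance()` summarizes the scan.
#'
#' @param x A `meth_assoc` tibble.
#' @param ... Unused.
#' @return For `tidy()`: the underlying tibble. For `glance()`: a one-row
#'   tibble with `n_tests`, `n_missing` and `n_significant`
#'   (q < `alpha`).
#' @param alpha Significance level for `glance()`'s `n_significant`
#'   (default 0.05).
#' @exportS3Method generics::tidy
tidy.meth_assoc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "meth_assoc")
  as_tibble(out)
}

#' @rdname tidy.meth_assoc
#' @exportS3Method generics::glance
glance.meth_assoc <- function(x, alpha = 0.05, ...) {
  tibble(
    n_tests = nrow(x),
    n_missing = sum(is.na(x$p_value)),
    n_significant = sum(x$q_value < alpha, na.rm = TRUE)
  )
}
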