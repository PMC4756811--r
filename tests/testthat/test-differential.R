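test_that("differential calls use strict 0.2 change versus the normal mean", {
  beta <- toy_beta(
    matrix(c(0.45, 0.55, 0.40, 0.5, 0.5, 0.5), ncol = 2),
    probes = c("pA", "pB", "pC"), samples = c("t1", "n1")
  )
  ref <- c(pA = 0.20, pB = 0.80, pC = 0.20)
  calls <- call_differential(beta, ref, samples = "t1")
  expect_equal(
    unname(calls$direction[match(c("pA", "pB"), calls$probe_id)]),
    c("hyper", "hypo")
  )
  # delta exactly 0.2 (pC) is not called
  expect_false("pC" %in% calls$probe_id)
  expect_equal(attr(calls, "universe_size")[["t1"]], 3)
  # masked cells and probes without a reference leave the universe
  beta["pA", "t1"] <- NA
  calls2 <- call_differential(beta, ref[c("pA", "pB")], samples = "t1")
  expect_equal(attr(calls2, "universe_size")[["t1"]], 1)
})

test_that("normal reference requires enough unmasked normals per probe", {
  beta <- toy_beta(matrix(c(0.1, NA, 0.2, NA, 0.3, 0.8), nrow = 2),
    probes = c("pA", "pB"), samples = c("n1", "n2", "n3")
  )
  ref <- normal_reference(beta, c("n1", "n2", "n3"))
  expect_equal(ref[["pA"]], mean(c(0.1, 0.2, 0.3)))
  expect_true(is.na(ref[["pB"]])) # only one usable normal
  expect_error(normal_reference(beta, "n1"), "at least 2")
})

test_that("enrichment rate matches hand arithmetic on random count quadruples", {
  expect_equal(enrichment_rate(10, 100, 50, 1000), 2.0)
  expect_equal(enrichment_rate(5, 50, 10, 100), 1.0)
  expect_equal(enrichment_rate(0, 100, 50, 1000), 0.0)
  expect_true(is.na(enrichment_rate(3, 100, 0, 1000)))
  expect_error(enrichment_rate(1, 0, 1, 10), "positive")
  expect_error(enrichment_rate(11, 10, 1, 10), "exceed")
  withr::with_seed(8, {
    total_in <- sample(1:500, 200, replace = TRUE)
    total_out <- sample(1:5000, 200, replace = TRUE)
    dm_in <- vapply(total_in, function(t) sample(0:t, 1), numeric(1))
    dm_out <- vapply(total_out, function(t) sample(1:t, 1), numeric(1))
    got <- enrichment_rate(dm_in, total_in, dm_out, total_out)
    manual <- (dm_in / total_in) / (dm_out / total_out)
    expect_equal(got, manual)
    # identities: equal fractions give 1; scaling all counts is invariant
    expect_equal(enrichment_rate(dm_out, total_out, dm_out, total_out), rep(1, 200))
    expect_equal(
      enrichment_rate(3 * dm_in, 3 * total_in, 3 * dm_out, 3 * total_out),
      got
    )
  })
})

test_that("planted 5x TF enrichment is recovered from probe-level calls", {
  withr::with_seed(13, {
    n <- 20000
    manifest <- tibble::tibble(
      probe_id = sprintf("p%05d", 1:n),
      chrom = "chr1", pos = seq(0, by = 250, length.out = n)
    )
    # factor A occupies a contiguous 10% of probe positions
    in_a <- manifest$pos < quantile(manifest$pos, 0.1)
    tf_sites <- tibble::tibble(
      chrom = "chr1", start = 0,
      end = max(manifest$pos[in_a]) + 1, name = "A"
    )
    p_out <- 0.05
    dm <- runif(n) < ifelse(in_a, 5 * p_out, p_out)
    calls <- tibble::tibble(
      sample_id = "t1", probe_id = manifest$probe_id[dm],
      delta = 0.3, direction = "hyper"
    )
    attr(calls, "universe_size") <- c(t1 = n)
    res <- tf_enrichment(calls, tf_sites, manifest)
    rate_a <- res$rate[res$tf == "A" & res$direction == "hyper"]
    expect_gt(rate_a, 4)
    expect_lt(rate_a, 6)
    # hypo direction has no calls: rate 0 or missing, never positive
    hypo <- res$rate[res$direction == "hypo"]
    expect_false(isTRUE(hypo > 0))
  })
})

test_that("random calls give near-null rates and empty calls give none positive", {
  withr::with_seed(14, {
    n <- 3000
    manifest <- tibble::tibble(
      probe_id = sprintf("p%04d", 1:n),
      chrom = "chr1", pos = sample(0:1e6, n)
    )
    tfs <- purrr::map(1:10, function(i) {
      idx <- sample.int(n, 300)
      tibble::tibble(
        chrom = "chr1", start = manifest$pos[idx],
        end = manifest$pos[idx] + 1, name = sprintf("TF%02d", i)
      )
    })
    tf_sites <- dplyr::bind_rows(tfs)
    dm <- sample.int(n, 600) # random 20% of probes called
    calls <- tibble::tibble(
      sample_id = "t1", probe_id = manifest$probe_id[dm],
      delta = 0.3, direction = "hyper"
    )
    attr(calls, "universe_size") <- c(t1 = n)
    res <- tf_enrichment(calls, tf_sites, manifest)
    rates <- res$rate[res$direction == "hyper"]
    expect_gte(mean(rates > 0.5 & rates < 2), 0.95)
  })
})

test_that("polycomb-like enrichment grows with planted CGI methylation across samples", {
  co <- get_default_cohort()
  qc <- summarize_cohort(co)
  normal_ids <- qc$summary$sample_id[qc$summary$tissue == "normal"]
  tumor_ids <- qc$summary$sample_id[
    !is.na(qc$summary$tumor_type) & qc$summary$tumor_type == "CIMP_like"
  ]
  ref <- normal_reference(qc$beta, normal_ids)
  calls <- call_differential(qc$beta, ref, samples = tumor_ids)
  annotated <- qc$manifest[
    qc$manifest$probe_id %in% qc$assignment$probe_id[!qc$assignment$unannotated],
  ]
  enr <- suppressMessages(
    tf_enrichment(calls, co$annotations$tf_sites, annotated)
  )
  pc <- enr[enr$tf == "POLYCOMB" & enr$direction == "hyper", ]
  pc <- pc[match(tumor_ids, pc$sample_id), ]
  smry_t <- qc$summary[match(tumor_ids, qc$summary$sample_id), ]
  # hypermethylation concentrates strongly inside polycomb-like sites
  expect_gt(median(pc$rate, na.rm = TRUE), 2)
  # the inside-site DM fraction tracks a sample's CGI methylation tightly;
  # the ratio itself carries small-count noise in its denominator (outside
  # calls are rare by design), so its rank correlation is positive but looser
  frac_in <- pc$dm_in / pc$total_in
  expect_gt(cor(smry_t$avg_cgi, frac_in, method = "spearman"), 0.8)
  ok <- !is.na(pc$rate)
  expect_gt(cor(smry_t$avg_cgi[ok], pc$rate[ok], method = "spearman"), 0.4)
})
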