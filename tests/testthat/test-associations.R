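test_that("BH adjustment matches hand step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # declared family larger than the observed p-values
  expect_equal(bh_adjust(c(0.01, 0.02), m = 4), c(0.04, 0.04))
  expect_error(bh_adjust(c(0.01, 0.02), m = 1), "family size")
  # monotone in p and bounded by 1
  withr::with_seed(2, {
    p <- runif(100)
    q <- bh_adjust(p)
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p))
  })
})

test_that("adjusted linear model recovers a planted stage effect", {
  withr::with_seed(51, {
    hits <- 0
    est_ok <- 0
    for (i in 1:25) {
      n <- 200
      stage <- sample(1:4, n, replace = TRUE)
      age <- runif(n, 30, 80)
      sex <- sample(c("M", "F"), n, replace = TRUE)
      y <- 0.2 + 0.02 * stage + rnorm(n, 0, 0.02)
      smry <- tibble::tibble(sample_id = as.character(1:n), avg_cgi = y)
      clin <- tibble::tibble(
        sample_id = as.character(1:n), age = age, sex = sex, stage = stage
      )
      res <- assoc_clinical(smry, clin, "stage", outcomes = "avg_cgi")
      hits <- hits + (res$p_value < 0.01)
      est_ok <- est_ok + (abs(res$estimate - 0.02) < 0.01)
    }
    expect_gte(hits / 25, 0.9)
    expect_gte(est_ok / 25, 0.9)
  })
})

test_that("adjusted linear model flags degenerate designs", {
  smry <- tibble::tibble(sample_id = as.character(1:20), avg_cgi = runif(20))
  clin <- tibble::tibble(
    sample_id = as.character(1:20),
    age = 1:20, sex = "F", stage = 1:20 # stage collinear with age
  )
  res <- assoc_clinical(smry, clin, "stage", outcomes = "avg_cgi")
  expect_true(is.na(res$p_value))
  expect_match(res$note, "collinear")
  # constant variable
  clin$stage <- 2
  res2 <- assoc_clinical(smry, clin, "stage", outcomes = "avg_cgi")
  expect_match(res2$note, "constant")
  # single-sex cohorts simply drop the sex covariate
  clin$stage <- rep(1:4, 5)
  res3 <- assoc_clinical(smry, clin, "stage", outcomes = "avg_cgi")
  expect_false(is.na(res3$p_value))
})

test_that("molecular tests pick the scale-appropriate statistic", {
  smry <- tibble::tibble(
    sample_id = as.character(1:12),
    avg_cgi = c(1:12) / 20, avg_backbone = 0.8
  )
  # Kendall on perfectly concordant pairs -> tau 1
  dat <- tibble::tibble(sample_id = as.character(1:12), x = 1:12)
  res <- assoc_molecular(smry, dat, "x", scale = "continuous", outcomes = "avg_cgi")
  expect_equal(res$estimate, 1.0)
  # three identical groups -> Kruskal-Wallis statistic ~ 0, p ~ 1
  smry2 <- tibble::tibble(
    sample_id = as.character(1:12), avg_cgi = rep(c(0.1, 0.2, 0.3, 0.4), 3)
  )
  dat2 <- tibble::tibble(sample_id = as.character(1:12), g = rep(1:3, each = 4))
  res2 <- assoc_molecular(smry2, dat2, "g", scale = "categorical", outcomes = "avg_cgi")
  expect_lt(res2$statistic, 1e-8)
  expect_gt(res2$p_value, 0.99)
  # groups below size 2 are missing with a note
  dat3 <- tibble::tibble(sample_id = as.character(1:12), m = c(1, rep(0, 11)))
  res3 <- assoc_molecular(smry, dat3, "m", scale = "binary", outcomes = "avg_cgi")
  expect_true(is.na(res3$p_value))
})

test_that("a planted mutation shift is detected by the Wilcoxon test", {
  withr::with_seed(52, {
    hits <- 0
    for (i in 1:20) {
      n <- 100
      mut <- rep(0:1, each = 50)
      y <- 0.2 + 0.1 * mut + rnorm(n, 0, 0.03)
      smry <- tibble::tibble(sample_id = as.character(1:n), avg_cgi = y)
      dat <- tibble::tibble(sample_id = as.character(1:n), mut = mut)
      res <- assoc_molecular(smry, dat, "mut", scale = "binary", outcomes = "avg_cgi")
      hits <- hits + (res$p_value < 1e-5)
    }
    expect_gte(hits / 20, 0.95)
  })
})

test_that("rank tests are invariant to monotone transformation of the outcome", {
  withr::with_seed(53, {
    n <- 40
    y <- runif(n, 0.1, 0.9)
    x <- rnorm(n)
    smry1 <- tibble::tibble(sample_id = as.character(1:n), avg_cgi = y)
    smry2 <- tibble::tibble(sample_id = as.character(1:n), avg_cgi = qlogis(y))
    dat <- tibble::tibble(
      sample_id = as.character(1:n), x = x,
      m = rep(0:1, n / 2), g = rep(1:4, n / 4)
    )
    for (sc in c("binary", "categorical", "continuous")) {
      v <- switch(sc, binary = "m", categorical = "g", continuous = "x")
      p1 <- assoc_molecular(smry1, dat, v, scale = sc, outcomes = "avg_cgi")$p_value
      p2 <- assoc_molecular(smry2, dat, v, scale = sc, outcomes = "avg_cgi")$p_value
      expect_equal(p1, p2)
    }
  })
})

test_that("the copy-number scan flags a planted locus and not null genes", {
  withr::with_seed(54, {
    n <- 100
    n_genes <- 120
    cn <- matrix(rnorm(n * n_genes, 0, 0.3),
      nrow = n,
      dimnames = list(as.character(1:n), sprintf("g%03d", 1:n_genes))
    )
    noise <- rnorm(n, 0, 0.01)
    y <- 0.75 + 0.03 * cn[, "g050"] + noise
    smry <- tibble::tibble(sample_id = as.character(1:n), avg_backbone = y)
    coords <- tibble::tibble(
      name = colnames(cn), chrom = "chr1",
      start = seq(1e5, 1.2e7, length.out = n_genes)
    )
    scan <- scna_scan(smry, cn, coords)
    expect_lt(scan$q_value[scan$gene == "g050"], 0.05)
    null_q <- scan$q_value[scan$gene != "g050"]
    expect_gte(mean(null_q >= 0.05), 0.95)
    # ordered by position
    expect_equal(scan$start, sort(scan$start))
    # permuting sample labels destroys the planted signal: the formerly
    # coupled gene behaves like any null gene (across several permutations,
    # since any single draw can land in the tail)
    perm_p <- replicate(5, {
      smry_perm <- smry
      smry_perm$avg_backbone <- sample(smry_perm$avg_backbone)
      scan_perm <- scna_scan(smry_perm, cn, coords)
      scan_perm$p_value[scan_perm$gene == "g050"]
    })
    expect_gte(sum(perm_p > 0.01), 4)
  })
})

test_that("the scan on one gene reduces to the continuous molecular test", {
  withr::with_seed(55, {
    n <- 60
    cn <- matrix(rnorm(n),
      nrow = n,
      dimnames = list(as.character(1:n), "gene1")
    )
    smry <- tibble::tibble(
      sample_id = as.character(1:n), avg_backbone = runif(n)
    )
    scan <- scna_scan(smry, cn)
    dat <- tibble::tibble(sample_id = as.character(1:n), gene1 = cn[, 1])
    mol <- assoc_molecular(smry, dat, "gene1",
      scale = "continuous",
      outcomes = "avg_backbone"
    )
    expect_equal(scan$tau, mol$estimate)
    expect_equal(scan$p_value, mol$p_value)
  })
})

test_that("cross-tumor percentiles follow order-statistic interpolation", {
  scans <- tidyr::expand_grid(
    tumor_type = sprintf("tt%02d", 1:21), gene = c("gA", "gB")
  )
  scans$chrom <- "chr1"
  scans$start <- ifelse(scans$gene == "gA", 100, 200)
  # gA: constant p; gB: p = 1..21 scaled into (0,1]
  scans$q_value <- ifelse(scans$gene == "gA", 0.5,
    as.numeric(factor(scans$tumor_type)) / 21
  )
  pct <- cross_tumor_percentiles(scans)
  a <- pct[pct$gene == "gA", ]
  expect_equal(unlist(a[c("p10", "p20", "p30", "p40")], use.names = FALSE), rep(0.5, 4))
  b <- pct[pct$gene == "gB", ]
  want <- unname(quantile((1:21) / 21, c(0.1, 0.2, 0.3, 0.4), type = 7))
  expect_equal(unlist(b[c("p10", "p20", "p30", "p40")], use.names = FALSE), want)
  # a locus recurrently low in a handful of tumor types surfaces in the low
  # percentiles while the 40th stays at 1 (with 21 types and linear
  # interpolation the 10th percentile sits on the 3rd order statistic)
  scans2 <- scans[scans$gene == "gA", ]
  scans2$q_value <- c(rep(1e-8, 5), rep(1, 16))
  pct2 <- cross_tumor_percentiles(scans2)
  expect_lt(pct2$p10, 0.01)
  expect_equal(pct2$p40, 1)
  # genes in fewer than two tumor types are dropped
  one <- scans[scans$tumor_type == "tt01", ]
  expect_error(cross_tumor_percentiles(one), "2 tumor types")
})

test_that("gene-body methylation/expression correlation recovers planted dependence", {
  withr::with_seed(56, {
    n_genes <- 40
    n <- 100
    meth <- matrix(runif(n_genes * n, 0.3, 0.9),
      nrow = n_genes,
      dimnames = list(sprintf("g%02d", 1:n_genes), as.character(1:n))
    )
    # expression = increasing function of methylation + noise at rho ~ 0.5
    expr <- meth + matrix(rnorm(n_genes * n, 0, sd(meth) * sqrt(3)), nrow = n_genes)
    dimnames(expr) <- dimnames(meth)
    res <- body_expression_correlation(meth, expr)
    expect_gt(median(res$rho), 0.3)
    # independent expression: median correlation near zero
    expr0 <- matrix(rnorm(n_genes * n), nrow = n_genes, dimnames = dimnames(meth))
    res0 <- body_expression_correlation(meth, expr0)
    expect_lt(abs(median(res0$rho)), 0.05)
    # noiseless monotone pairing: rho exactly 1
    res1 <- body_expression_correlation(meth, meth^3)
    expect_true(all(res1$rho == 1))
    # constant expression is missing
    exprc <- matrix(1, n_genes, n, dimnames = dimnames(meth))
    resc <- body_expression_correlation(meth, exprc)
    expect_true(all(is.na(resc$rho)))
  })
})

test_that("association tables expose tidy and glance methods", {
  smry <- tibble::tibble(
    sample_id = as.character(1:30), avg_cgi = runif(30), avg_backbone = runif(30)
  )
  dat <- tibble::tibble(sample_id = as.character(1:30), x = rnorm(30))
  res <- assoc_molecular(smry, dat, "x", scale = "continuous")
  expect_s3_class(res, "meth_assoc")
  expect_false(inherits(tidy(res), "meth_assoc"))
  g <- glance(res)
  expect_equal(g$n_tests, 2)
})
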