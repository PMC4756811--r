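test_that("normalize merges overlapping intervals and preserves covered bases", {
  merged <- region_normalize(region_tbl("chr1", c(100, 150), c(200, 300)))
  expect_equal(merged, region_tbl("chr1", 100, 300))

  # empty set and idempotence on an already disjoint sorted set
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  expect_equal(nrow(region_normalize(empty)), 0)
  disjoint <- region_tbl("chr1", c(10, 50), c(20, 60))
  expect_equal(region_normalize(disjoint), disjoint)

  # order independence + per-base oracle on random sets
  genome <- toy_genome()
  withr::with_seed(42, {
    for (i in 1:10) {
      r <- random_regions(genome, 30)
      norm <- region_normalize(r)
      shuffled <- region_normalize(r[sample.int(nrow(r)), ])
      expect_equal(norm, shuffled)
      expect_equal(region_normalize(norm), norm)
      expect_equal(bases_covered(norm, genome), bases_covered(r, genome))
      # non-overlapping, non-abutting, sorted within chromosome
      by_chrom <- split(norm, norm$chrom)
      for (b in by_chrom) {
        if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
      }
    }
  })
})

test_that("malformed intervals are rejected", {
  expect_error(region_tbl("chr1", 100, 100), "end <= start")
  expect_error(region_tbl("chr1", -5, 100), "start < 0")
  expect_error(
    region_normalize(tibble::tibble(chrom = "chr1", start = 10, end = 5)),
    "end <= start"
  )
})

test_that("shores flank CGIs by 2 kb, exclude CGI bases, and clip to bounds", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  shores <- region_shores(region_tbl("chr1", 10000, 10500), genome)
  expect_equal(shores, region_tbl("chr1", c(8000, 10500), c(10000, 12500)))

  # CGI near the chromosome start: left shore clipped to 0
  clipped <- region_shores(region_tbl("chr1", 500, 1000), genome)
  expect_equal(clipped$start[1], 0)
  expect_equal(clipped$end[1], 500)

  # two CGIs 1 kb apart: inter-CGI bases counted once, never inside a CGI
  cgis <- region_tbl("chr1", c(10000, 11500), c(10500, 12000))
  shores2 <- region_shores(cgis, genome)
  cov_shore <- bases_covered(shores2, genome)$chr1
  cov_cgi <- bases_covered(cgis, genome)$chr1
  expect_false(any(cov_shore & cov_cgi))
  # oracle: flank bases minus CGI bases
  expected <- logical(1e6)
  for (i in seq_len(nrow(cgis))) {
    expected[max(1, cgis$start[i] - 2000 + 1):(cgis$end[i] + 2000)] <- TRUE
  }
  expected[cov_cgi] <- FALSE
  expect_equal(cov_shore, expected)
})

test_that("promoters are 1.5 kb upstream of the strand-appropriate TSS", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  plus <- region_promoters(region_tbl("chr1", 5000, 8000, strand = "+"), genome)
  expect_equal(plus$start, 3500)
  expect_equal(plus$end, 5000)
  minus <- region_promoters(region_tbl("chr1", 5000, 8000, strand = "-"), genome)
  expect_equal(minus$start, 8000)
  expect_equal(minus$end, 9500)
  # clipping at chromosome start
  near0 <- region_promoters(region_tbl("chr1", 1000, 4000, strand = "+"), genome)
  expect_equal(c(near0$start, near0$end), c(0, 1000))
  # unstranded genes are an error
  expect_error(
    region_promoters(region_tbl("chr1", 5000, 8000, strand = "."), genome),
    "strand"
  )
})

test_that("5'-body is the floored first 10% of the gene from its 5' end", {
  plus <- region_five_prime_body(region_tbl("chr1", 5000, 8000, strand = "+"))
  expect_equal(c(plus$start, plus$end), c(5000, 5300))
  minus <- region_five_prime_body(region_tbl("chr1", 5000, 8000, strand = "-"))
  expect_equal(c(minus$start, minus$end), c(7700, 8000))
  # minimal gene: 1 bp body
  tiny <- region_five_prime_body(region_tbl("chr1", 100, 110, strand = "+"))
  expect_equal(tiny$end - tiny$start, 1)
})

test_that("promoter and 5'-body obey strand reflection symmetry", {
  genome <- tibble::tibble(chrom = "chr1", length = 100000)
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- sample(2000:50000, 1)
      e <- s + sample(100:20000, 1)
      g_plus <- region_tbl("chr1", s, e, strand = "+")
      # reflect coordinates through the chromosome: x -> L - x
      g_minus <- region_tbl("chr1", 100000 - e, 100000 - s, strand = "-")
      p1 <- region_promoters(g_plus, genome)
      p2 <- region_promoters(g_minus, genome)
      expect_equal(p2$start, 100000 - p1$end)
      expect_equal(p2$end, 100000 - p1$start)
      b1 <- region_five_prime_body(g_plus)
      b2 <- region_five_prime_body(g_minus)
      expect_equal(b2$start, 100000 - b1$end)
      expect_equal(b2$end, 100000 - b1$start)
    }
  })
})

test_that("backbone is the exact genome complement of the union", {
  genome <- tibble::tibble(chrom = "chr1", length = 1000)
  bb <- region_backbone(genome, list(region_tbl("chr1", 100, 300)))
  expect_equal(bb, region_tbl("chr1", c(0, 300), c(100, 1000)))
  # empty union -> whole genome; full union -> empty backbone
  expect_equal(
    region_backbone(genome, list()),
    region_tbl("chr1", 0, 1000)
  )
  expect_equal(
    nrow(region_backbone(genome, list(region_tbl("chr1", 0, 1000)))),
    0
  )
})

test_that("backbone partition is disjoint and conserves coverage", {
  withr::with_seed(99, {
    for (i in 1:10) {
      genome <- toy_genome(c(chr1 = sample(2e4:5e4, 1), chr2 = sample(1e4:3e4, 1)))
      functional <- list(
        random_regions(genome, 15),
        random_regions(genome, 10)
      )
      repeats <- random_regions(genome, 8, max_len = 2000)
      bb <- region_backbone(genome, functional, repeats)
      union_cov <- bases_covered(
        region_union(c(functional, list(repeats))), genome
      )
      bb_cov <- bases_covered(bb, genome)
      for (chrom in genome$chrom) {
        expect_false(any(bb_cov[[chrom]] & union_cov[[chrom]]))
        expect_true(all(bb_cov[[chrom]] | union_cov[[chrom]]))
      }
      expect_equal(
        region_width(bb) + region_width(region_union(c(functional, list(repeats)))),
        sum(genome$length)
      )
    }
  })
})

test_that("taxonomy tracks are normalized and the backbone avoids them all", {
  genome <- toy_genome(c(chr1 = 50000))
  genes <- region_tbl("chr1", c(10000, 30000), c(15000, 36000),
    strand = c("+", "-"), name = c("g1", "g2")
  )
  tax <- build_region_taxonomy(
    genome = genome,
    cgi = region_tbl("chr1", c(9500, 20000), c(10600, 20400)),
    genes = genes,
    exons = region_tbl("chr1", c(10000, 30500), c(10200, 30800)),
    repeats = region_tbl("chr1", 40000, 41000)
  )
  expect_setequal(
    names(tax),
    c(
      "cgi", "shore", "promoter", "five_prime_body", "exon", "dnase",
      "tf", "enhancer", "repeat", "backbone"
    )
  )
  bb_cov <- bases_covered(tax$backbone, genome)$chr1
  for (nm in setdiff(names(tax), "backbone")) {
    if (nrow(tax[[nm]]) > 0) {
      expect_false(any(bb_cov & bases_covered(tax[[nm]], genome)$chr1))
    }
  }
})
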