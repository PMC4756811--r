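# Synthetic-cohort generator.
#
# Produces a fully self-contained toy study on a ~20 Mb genome: annotation
# tracks with the full region taxonomy, an array-style probe manifest with
# QC flags, beta and detection-p matrices for a normal cohort plus
# tumor-type blocks with planted CGI hypermethylation / backbone
# hypomethylation, clinical covariates, mutation and copy-number tables with
# planted couplings, and paired noisy WGBS-like averages. Everything is
# deterministic given the seed.
#
# Noise model: a beta value at probe i in sample j is drawn from
# Beta(mu * kappa, (1 - mu) * kappa), a mean-preserving two-parameter family
# on [0,1] with concentration kappa. The mean mu combines a probe-level
# baseline (itself beta-distributed around the compartment mean), a
# per-sample offset, and the planted sample-level shifts. Planted covariate,
# mutation and copy-number effects are applied centred so they do not move
# cohort means; the LAD factor redistributes (rather than inflates) the
# backbone shift so a planted shift delta is recovered exactly as a
# delta change in cohort-mean average backbone methylation.

#' Describe a synthetic tumor-type block
#'
#' @param name Tumor-type label.
#' @param n_tumors Number of tumor samples.
#' @param cgi_shift Mean increase of CGI-probe methylation (beta units,
#'   >= 0), concentrated at polycomb-like TF-site CGIs via
#'   `polycomb_weight`.
#' @param backbone_shift Mean decrease of backbone-probe methylation
#'   (>= 0), redistributed into LADs via `lad_factor`.
#' @param lad_extra_shift Additional uncentred backbone decrease applied
#'   only inside LADs (default 0).
#' @param lad_factor Relative weight of the backbone shift inside LADs
#'   (default 1.5; weights are normalized to mean 1 over backbone probes so
#'   the cohort-mean shift stays `backbone_shift`).
#' @param polycomb_weight Relative weight of the CGI shift at probes inside
#'   polycomb-like TF sites (default 2, normalized likewise).
#' @param het_sd Between-tumor heterogeneity: each tumor scales its planted
#'   shifts by a factor centred at 1 with this spread (default 0.15).
#' @param age_backbone_slope Planted slope of average backbone methylation
#'   on age, beta units per year (default -3e-4: older patients slightly
#'   more demethylated).
#' @param stage_cgi_slope Planted slope of average CGI methylation per stage
#'   unit (default 0.005).
#' @param mutation_effects List of planted mutation effects, each a list
#'   with `gene`, `prevalence`, `effect_cgi`, `effect_backbone` (effects are
#'   the mutated-minus-wildtype difference in the per-sample average).
#' @param scna_coupling `NULL`, or a list with `target_tau` (Kendall
#'   correlation between the coupled gene's log2-ratio and average backbone
#'   methylation) and optionally `gene` (default: the first copy-number gene
#'   on the second chromosome).
#' @return A `tumor_block` list.
#' @export
tumor_block <- function(name, n_tumors = 100, cgi_shift = 0, backbone_shift = 0,
                        lad_extra_shift = 0, lad_factor = 1.5,
                        polycomb_weight = 2, het_sd = 0.15,
                        age_backbone_slope = -3e-4, stage_cgi_slope = 0.005,
                        mutation_effects = list(), scna_coupling = NULL) {
  if (cgi_shift < 0 || backbone_shift < 0) {
    abort("planted shifts must be non-negative")
  }
  structure(
    list(
      name = name, n_tumors = n_tumors, cgi_shift = cgi_shift,
      backbone_shift = backbone_shift, lad_extra_shift = lad_extra_shift,
      lad_factor = lad_factor, polycomb_weight = polycomb_weight,
      het_sd = het_sd, age_backbone_slope = age_backbone_slope,
      stage_cgi_slope = stage_cgi_slope,
      mutation_effects = mutation_effects, scna_coupling = scna_coupling
    ),
    class = "tumor_block"
  )
}

#' Specify a synthetic cohort
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' observed geometry of real cohorts: normal tissues with average CGI
#' methylation ~0.21 and average backbone methylation ~0.80 inside narrow
#' windows (0.18-0.24 and 0.78-0.82), and tumor blocks deviating toward CGI
#' hypermethylation and/or backbone hypomethylation.
#'
#' @param seed Integer seed; the whole generation path is deterministic
#'   given it.
#' @param genome Genome tibble; the default is four chromosomes (~21 Mb)
#'   including one sex chromosome.
#' @param n_genes,n_cgi,n_dnase,n_enhancer,n_repeats Feature counts.
#' @param n_tf_sites Binding sites per TF factor.
#' @param tf_factors TF names; the first is the polycomb-like factor whose
#'   sites are planted at CpG islands.
#' @param cgi_at_promoter_fraction Fraction of genes whose promoter carries
#'   a CpG island.
#' @param polycomb_cgi_fraction Fraction of CpG islands overlapped by a
#'   polycomb-like TF site.
#' @param lad_fraction Approximate fraction of each autosome covered by
#'   LADs.
#' @param n_probes Named vector: probes placed in the `cgi`, `backbone` and
#'   `other` (shore/exon/DNase) compartments.
#' @param n_flagged_probes Named vector: extra probes destined for QC
#'   removal (`snp` within 10 bp, `repeat` within 15 bp, `sex` chromosome).
#' @param normal_means Named vector of normal-tissue compartment means
#'   (defaults 0.21 / 0.80 / 0.50, the midpoints of the normal windows for
#'   the two analysis axes).
#' @param probe_kappa Concentration of probe-level baseline means around the
#'   compartment mean.
#' @param kappa Concentration of the per-cell beta noise.
#' @param sample_sd Standard deviation of the per-sample offset on each
#'   axis (beta units).
#' @param n_normal Number of normal samples.
#' @param detection_fail_rate Fraction of cells given a detection p-value
#'   above 0.05.
#' @param wgbs_r Target theoretical array-WGBS correlation; the WGBS noise
#'   sd is calibrated per axis as `sd(avg) * sqrt(1/r^2 - 1)` unless
#'   `wgbs_sigma` is given.
#' @param wgbs_sigma Optional fixed WGBS noise sd (beta units).
#' @param n_cn_genes Number of genes with copy-number log2-ratios.
#' @param cn_log2_sd Spread of the simulated log2-ratios.
#' @param tumor_blocks List of [tumor_block()]s; the default is one
#'   CIMP-like block (strong CGI shift) and one demethylated block (strong
#'   backbone shift with a planted copy-number coupling), 100 tumors each.
#' @return A `cohort_spec` list accepted by [simulate_annotations()] and
#'   [simulate_cohort()].
#' @export
cohort_spec <- function(seed = 1,
                        genome = tibble(
                          chrom = c("chr1", "chr2", "chr3", "chrX"),
                          length = c(8e6, 6e6, 6e6, 1e6)
                        ),
                        n_genes = 240, n_cgi = 300,
                        n_tf_sites = 150,
                        tf_factors = c("POLYCOMB", paste0("TF", 2:8)),
                        cgi_at_promoter_fraction = 0.6,
                        polycomb_cgi_fraction = 0.7,
                        n_dnase = 200, n_enhancer = 100, n_repeats = 400,
                        lad_fraction = 0.3,
                        n_probes = c(cgi = 2000, backbone = 2000, other = 1000),
                        n_flagged_probes = c(snp = 150, repeats = 150, sex = 100),
                        normal_means = c(cgi = 0.21, backbone = 0.80, other = 0.50),
                        probe_kappa = 200, kappa = 80, sample_sd = 0.005,
                        n_normal = 100, detection_fail_rate = 0.005,
                        wgbs_r = 0.84, wgbs_sigma = NULL,
                        n_cn_genes = 60, cn_log2_sd = 0.3,
                        tumor_blocks = list(
                          tumor_block("CIMP_like",
                            n_tumors = 100,
                            cgi_shift = 0.10, backbone_shift = 0.03,
                            mutation_effects = list(list(
                              gene = "MUT1", prevalence = 0.3,
                              effect_cgi = 0.08, effect_backbone = 0
                            ))
                          ),
                          tumor_block("Demethylated",
                            n_tumors = 100,
                            cgi_shift = 0.03, backbone_shift = 0.10,
                            scna_coupling = list(target_tau = 0.4)
                          )
                        )) {
  validate_genome(genome)
  spec <- list(
    seed = as.integer(seed), genome = genome,
    sex_chroms = c("chrX", "chrY"),
    n_genes = n_genes, n_cgi = n_cgi, n_tf_sites = n_tf_sites,
    tf_factors = tf_factors,
    cgi_at_promoter_fraction = cgi_at_promoter_fraction,
    polycomb_cgi_fraction = polycomb_cgi_fraction,
    n_dnase = n_dnase, n_enhancer = n_enhancer, n_repeats = n_repeats,
    lad_fraction = lad_fraction,
    n_probes = n_probes, n_flagged_probes = n_flagged_probes,
    normal_means = normal_means, probe_kappa = probe_kappa, kappa = kappa,
    sample_sd = sample_sd, n_normal = n_normal,
    detection_fail_rate = detection_fail_rate,
    wgbs_r = wgbs_r, wgbs_sigma = wgbs_sigma,
    n_cn_genes = n_cn_genes, cn_log2_sd = cn_log2_sd,
    tumor_blocks = tumor_blocks
  )
  if (any(n_probes <= 0) || n_normal <= 0) abort("counts must be positive")
  if (kappa <= 0 || probe_kappa <= 0) abort("concentrations must be positive")
  class(spec) <- "cohort_spec"
  spec
}

# Beta draw parameterized by (mean, concentration)
rbeta_mean <- function(n, mean, kappa) {
  stats::rbeta(n, shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
}

# n random non-overlapping intervals on the given chromosomes, placed on a
# slot grid so they cannot collide
place_intervals <- function(genome, chroms, n, min_len, max_len, slot = NULL) {
  slot <- slot %||% (max_len + 1000)
  slots <- bind_rows(purrr::pmap(
    genome[genome$chrom %in% chroms, ],
    function(chrom, length, ...) {
      starts <- seq(0, length - slot, by = slot)
      tibble(chrom = chrom, slot_start = starts)
    }
  ))
  if (n > nrow(slots)) {
    abort(sprintf("genome too small: %d features requested, %d slots available", n, nrow(slots)))
  }
  pick <- slots[sort(sample.int(nrow(slots), n)), ]
  len <- floor(stats::runif(n, min_len, max_len))
  offset <- floor(stats::runif(n, 0, slot - len))
  tibble(chrom = pick$chrom, start = pick$slot_start + offset, end = pick$slot_start + offset + len)
}

# n random intervals (overlap allowed)
scatter_intervals <- function(genome, chroms, n, min_len, max_len) {
  g <- genome[genome$chrom %in% chroms, ]
  if (n == 0 || nrow(g) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  idx <- sample.int(nrow(g), n, replace = TRUE, prob = g$length)
  len <- floor(stats::runif(n, min_len, max_len))
  start <- floor(stats::runif(n, 0, g$length[idx] - len))
  tibble(chrom = g$chrom[idx], start = start, end = start + len)
}

# n positions uniform over the bases of a normalized region set
sample_positions_in <- function(regions, n) {
  if (nrow(regions) == 0) abort("cannot place probes in an empty region set")
  w <- regions$end - regions$start
  idx <- sample.int(nrow(regions), n, replace = TRUE, prob = w)
  tibble(
    chrom = regions$chrom[idx],
    pos = regions$start[idx] + floor(stats::runif(n) * w[idx])
  )
}

#' Generate synthetic annotation tracks
#'
#' Builds a non-degenerate region taxonomy on the toy genome: genes with
#' exons, CpG islands placed at a subset of promoters (plus intergenic
#' ones), TF-binding-site clusters with one polycomb-like factor planted at
#' CpG islands, DNase sites, enhancers, scattered repeats and megabase-scale
#' LAD blocks. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `genome`, `genes` (name/strand), `exons`, `cgi`,
#'   `tf_sites` (name = factor), `dnase`, `enhancer`, `repeats`, `lads`.
#' @export
simulate_annotations <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    genome <- spec$genome
    autosomes <- setdiff(genome$chrom, spec$sex_chroms)
    genes <- place_intervals(genome, autosomes, spec$n_genes,
      min_len = 2000, max_len = 20000, slot = 25000
    )
    genes$strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
    genes$name <- sprintf("gene%03d", seq_len(spec$n_genes))

    exons <- bind_rows(purrr::pmap(genes, function(chrom, start, end, strand, name) {
      n_ex <- sample(2:6, 1)
      len <- end - start
      ex_len <- pmin(floor(stats::runif(n_ex, 100, 400)), len)
      ex_start <- start + floor(stats::runif(n_ex, 0, len - ex_len))
      tibble(chrom = chrom, start = ex_start, end = ex_start + ex_len, name = name)
    }))

    # CGIs: one at the promoter-side TSS of a fraction of genes, the rest
    # intergenic
    n_prom_cgi <- round(spec$cgi_at_promoter_fraction * min(spec$n_cgi, spec$n_genes))
    prom_genes <- genes[sample.int(nrow(genes), n_prom_cgi), ]
    tss <- ifelse(prom_genes$strand == "+", prom_genes$start, prom_genes$end)
    cgi_prom <- tibble(
      chrom = prom_genes$chrom,
      start = pmax(0, tss - 400), end = tss + 600
    )
    n_free_cgi <- spec$n_cgi - n_prom_cgi
    cgi_free <- scatter_intervals(genome, autosomes, n_free_cgi, 300, 1500)
    cgi <- region_normalize(bind_rows(cgi_prom, cgi_free))

    # TF sites: the first factor is polycomb-like, parked on CGIs
    n_pc <- round(spec$polycomb_cgi_fraction * nrow(cgi))
    pc_cgi <- cgi[sample.int(nrow(cgi), n_pc), ]
    pc_sites <- tibble(
      chrom = pc_cgi$chrom,
      start = pmax(0, pc_cgi$start - 100),
      end = pc_cgi$end + 100,
      name = spec$tf_factors[1]
    )
    other_sites <- bind_rows(purrr::map(spec$tf_factors[-1], function(tf) {
      out <- scatter_intervals(genome, autosomes, spec$n_tf_sites, 200, 800)
      out$name <- tf
      out
    }))
    tf_sites <- bind_rows(pc_sites, other_sites)

    dnase <- scatter_intervals(genome, autosomes, spec$n_dnase, 150, 500)
    enhancer <- scatter_intervals(genome, autosomes, spec$n_enhancer, 200, 1000)
    repeats <- if (spec$n_repeats > 0) {
      scatter_intervals(genome, autosomes, spec$n_repeats, 200, 2000)
    } else {
      tibble(chrom = character(), start = numeric(), end = numeric())
    }

    # LADs: alternating megabase blocks covering ~lad_fraction per autosome
    lads <- bind_rows(purrr::map2(
      autosomes, genome$length[match(autosomes, genome$chrom)],
      function(chrom, chrom_len) {
        pos <- floor(stats::runif(1, 0, 1e6))
        out <- list()
        while (pos < chrom_len) {
          lad_len <- floor(stats::runif(1, 1e6, 2e6))
          lad_end <- min(pos + lad_len, chrom_len)
          if (lad_end - pos >= 2e5) {
            out[[length(out) + 1]] <- tibble(chrom = chrom, start = pos, end = lad_end)
          }
          gap <- lad_len * (1 - spec$lad_fraction) / spec$lad_fraction
          pos <- lad_end + floor(stats::runif(1, 0.8, 1.2) * gap)
        }
        bind_rows(out)
      }
    ))

    list(
      genome = genome, genes = genes, exons = exons, cgi = cgi,
      tf_sites = tf_sites, dnase = dnase, enhancer = enhancer,
      repeats = repeats, lads = lads
    )
  })
}

#' Generate a synthetic cohort
#'
#' Places probes in the taxonomy built from the annotation tracks, draws
#' normal and tumor beta values under the generator's noise model, injects
#' detection-p failures, planted clinical/mutation/copy-number couplings and
#' paired WGBS-like measurements. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param annotations Output of [simulate_annotations()] for the same spec
#'   (regenerated when omitted).
#' @return A `meth_cohort` list with elements `spec`, `annotations`,
#'   `taxonomy` (from [build_region_taxonomy()]), `manifest`, `beta`,
#'   `detection_p`, `clinical`, `mutations` (tumor samples x genes),
#'   `copy_number` (list: `log2` matrix, `gene_coords`), `wgbs`, and
#'   `truth` (per-sample planted shifts, probe compartments, coupling
#'   coefficients).
#' @export
simulate_cohort <- function(spec, annotations = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ann <- annotations %||% simulate_annotations(spec)
  taxonomy <- build_region_taxonomy(
    genome = ann$genome, cgi = ann$cgi, genes = ann$genes, exons = ann$exons,
    dnase = ann$dnase, tf = ann$tf_sites, enhancer = ann$enhancer,
    repeats = ann$repeats
  )
  withr::with_seed(spec$seed + 1L, {
    autosomes <- setdiff(spec$genome$chrom, spec$sex_chroms)

    # --- probes ---------------------------------------------------------
    other_regions <- region_union(list(taxonomy$shore, taxonomy$exon, taxonomy$dnase))
    probes <- bind_rows(
      mutate(sample_positions_in(taxonomy$cgi, spec$n_probes[["cgi"]]), compartment = "cgi"),
      mutate(sample_positions_in(taxonomy$backbone, spec$n_probes[["backbone"]]), compartment = "backbone"),
      mutate(sample_positions_in(other_regions, spec$n_probes[["other"]]), compartment = "other")
    )
    flagged <- bind_rows(
      mutate(
        scatter_intervals(spec$genome, autosomes, spec$n_flagged_probes[["snp"]], 1, 2)[, c("chrom", "start")],
        flag = "snp"
      ),
      mutate(
        scatter_intervals(spec$genome, autosomes, spec$n_flagged_probes[["repeats"]], 1, 2)[, c("chrom", "start")],
        flag = "repeats"
      ),
      mutate(
        scatter_intervals(
          spec$genome, intersect(spec$genome$chrom, spec$sex_chroms),
          spec$n_flagged_probes[["sex"]], 1, 2
        )[, c("chrom", "start")],
        flag = "sex"
      )
    )
    flagged <- rename(flagged, pos = "start")
    flagged$compartment <- "flagged"
    probes$flag <- "none"
    probes <- bind_rows(probes, flagged)
    n_probe <- nrow(probes)
    manifest <- tibble(
      probe_id = sprintf("cg%06d", seq_len(n_probe)),
      chrom = probes$chrom,
      pos = probes$pos,
      snp_dist = ifelse(probes$flag == "snp", sample(0:10, n_probe, replace = TRUE),
        sample(50:5000, n_probe, replace = TRUE)
      ),
      repeat_within_15bp = as.integer(probes$flag == "repeats"),
      type = sample(c("I", "II"), n_probe, replace = TRUE, prob = c(0.3, 0.7))
    )
    compartment <- probes$compartment

    # --- probe baselines and weights ------------------------------------
    base_mean <- spec$normal_means[ifelse(compartment %in% names(spec$normal_means),
      compartment, "other"
    )]
    probe_mean <- rbeta_mean(n_probe, base_mean, spec$probe_kappa)

    pc_sites <- ann$tf_sites[ann$tf_sites$name == spec$tf_factors[1], ]
    probe_gr <- GenomicRanges::GRanges(
      seqnames = manifest$chrom,
      ranges = IRanges::IRanges(start = manifest$pos + 1, width = 1)
    )
    in_polycomb <- suppressWarnings(
      IRanges::overlapsAny(probe_gr, regions_to_gr(pc_sites[c("chrom", "start", "end")]))
    )
    in_lad <- suppressWarnings(
      IRanges::overlapsAny(probe_gr, regions_to_gr(region_normalize(ann$lads)))
    )
    is_cgi <- compartment == "cgi"
    is_bb <- compartment == "backbone"

    # --- samples ---------------------------------------------------------
    blocks <- spec$tumor_blocks
    block_names <- vapply(blocks, function(b) b$name, character(1))
    n_tumor <- vapply(blocks, function(b) b$n_tumors, numeric(1))
    sample_id <- c(
      sprintf("N%03d", seq_len(spec$n_normal)),
      unlist(purrr::map2(block_names, n_tumor, function(nm, n) {
        sprintf("T_%s_%03d", nm, seq_len(n))
      }))
    )
    n_sample <- length(sample_id)
    tissue <- c(rep("normal", spec$n_normal), rep("tumor", sum(n_tumor)))
    tumor_type <- c(rep("NORMAL", spec$n_normal), rep(block_names, n_tumor))

    clinical <- tibble(
      sample_id = sample_id, tissue = tissue, tumor_type = tumor_type,
      age = round(stats::runif(n_sample, 30, 80)),
      sex = sample(c("M", "F"), n_sample, replace = TRUE),
      stage = ifelse(tissue == "tumor", sample(1:4, n_sample, replace = TRUE), NA),
      grade = ifelse(tissue == "tumor", sample(1:3, n_sample, replace = TRUE), NA),
      msi = ifelse(tissue == "tumor",
        sample(0:2, n_sample, replace = TRUE, prob = c(0.7, 0.15, 0.15)), NA
      )
    )

    # --- molecular tables ------------------------------------------------
    tumor_ids <- sample_id[tissue == "tumor"]
    mut_genes <- unique(c(
      unlist(purrr::map(blocks, function(b) {
        vapply(b$mutation_effects, function(e) e$gene, character(1))
      })),
      c("MUTNULL1", "MUTNULL2")
    ))
    mutations <- matrix(
      stats::rbinom(length(tumor_ids) * length(mut_genes), 1, 0.3),
      nrow = length(tumor_ids),
      dimnames = list(tumor_ids, mut_genes)
    )
    # planted-effect genes use their declared prevalence within their block
    for (b in blocks) {
      ids_b <- sample_id[tumor_type == b$name]
      for (e in b$mutation_effects) {
        mutations[ids_b, e$gene] <- stats::rbinom(length(ids_b), 1, e$prevalence)
      }
    }
    cn_gene_rows <- ann$genes[
      round(seq(1, nrow(ann$genes), length.out = spec$n_cn_genes)),
    ]
    cn_log2 <- matrix(
      stats::rnorm(length(tumor_ids) * spec$n_cn_genes, 0, spec$cn_log2_sd),
      nrow = length(tumor_ids),
      dimnames = list(tumor_ids, cn_gene_rows$name)
    )

    # --- sample-level planted shifts ------------------------------------
    cgi_add <- stats::setNames(numeric(n_sample), sample_id)
    bb_sub <- stats::setNames(numeric(n_sample), sample_id)
    truth_coupling <- list()
    for (b in blocks) {
      ids <- sample_id[tumor_type == b$name]
      nb <- length(ids)
      raw <- stats::rnorm(nb, 0, b$het_sd)
      s <- pmax(0.2, 1 + raw - mean(raw))
      add <- b$cgi_shift * s
      sub <- b$backbone_shift * s
      stage_b <- clinical$stage[match(ids, clinical$sample_id)]
      add <- add + b$stage_cgi_slope * (stage_b - mean(stage_b))
      age_b <- clinical$age[match(ids, clinical$sample_id)]
      sub <- sub - b$age_backbone_slope * (age_b - mean(age_b))
      for (e in b$mutation_effects) {
        mut <- mutations[ids, e$gene]
        add <- add + e$effect_cgi * (mut - mean(mut))
        sub <- sub - e$effect_backbone * (mut - mean(mut))
      }
      if (!is.null(b$scna_coupling)) {
        cpl <- b$scna_coupling
        gene <- cpl$gene %||% {
          on_chr2 <- cn_gene_rows$name[cn_gene_rows$chrom == autosomes[2]]
          if (length(on_chr2) > 0) on_chr2[1] else cn_gene_rows$name[1]
        }
        rho <- sin(pi * cpl$target_tau / 2)
        other_sd <- sqrt(spec$sample_sd^2 + (b$backbone_shift * b$het_sd)^2)
        lr <- cn_log2[ids, gene]
        coef <- other_sd * rho / sqrt(1 - rho^2) / stats::sd(lr)
        # higher copy number -> higher backbone methylation (deletions couple
        # with demethylation)
        sub <- sub - coef * (lr - mean(lr))
        truth_coupling[[b$name]] <- list(
          block = b$name, gene = gene, coef = coef, target_tau = cpl$target_tau
        )
      }
      cgi_add[ids] <- add
      bb_sub[ids] <- sub
    }

    # --- probe-level shift weights (normalized to mean 1 per class) ------
    pc_weight <- if (length(blocks) > 0) blocks[[1]]$polycomb_weight else 1
    lad_factor <- if (length(blocks) > 0) blocks[[1]]$lad_factor else 1
    pc_w <- rep(1, n_probe)
    pc_w[is_cgi & in_polycomb] <- pc_weight
    pc_w[is_cgi] <- pc_w[is_cgi] / mean(pc_w[is_cgi])
    lad_w <- rep(1, n_probe)
    lad_w[is_bb & in_lad] <- lad_factor
    lad_w[is_bb] <- lad_w[is_bb] / mean(lad_w[is_bb])

    lad_extra <- stats::setNames(
      vapply(blocks, function(b) b$lad_extra_shift, numeric(1)), block_names
    )
    extra_by_sample <- ifelse(tissue == "tumor", lad_extra[tumor_type], 0)

    # --- beta matrix -----------------------------------------------------
    offset_cgi <- stats::rnorm(n_sample, 0, spec$sample_sd)
    offset_bb <- stats::rnorm(n_sample, 0, spec$sample_sd)
    offset_other <- stats::rnorm(n_sample, 0, spec$sample_sd)
    offset_m <- rbind(cgi = offset_cgi, backbone = offset_bb, other = offset_other)
    comp_key <- ifelse(compartment %in% c("cgi", "backbone"), compartment, "other")
    mu <- outer(probe_mean, rep(1, n_sample)) +
      offset_m[comp_key, , drop = FALSE] +
      (pc_w * is_cgi) %o% cgi_add -
      (lad_w * is_bb) %o% bb_sub -
      (as.numeric(is_bb & in_lad)) %o% extra_by_sample
    if (any(mu < 0 | mu > 1)) {
      warn(sprintf(
        "%d probe means pushed outside [0,1] by planted shifts; clipped",
        sum(mu < 0 | mu > 1)
      ))
    }
    mu <- pmin(pmax(mu, 0.005), 0.995)
    beta <- matrix(
      rbeta_mean(length(mu), as.vector(mu), spec$kappa),
      nrow = n_probe,
      dimnames = list(manifest$probe_id, sample_id)
    )

    detection_p <- matrix(
      stats::runif(n_probe * n_sample, 0, 0.04),
      nrow = n_probe, dimnames = list(manifest$probe_id, sample_id)
    )
    fail <- stats::runif(n_probe * n_sample) < spec$detection_fail_rate
    detection_p[fail] <- stats::runif(sum(fail), 0.05, 1)

    # --- paired WGBS-like averages --------------------------------------
    avg_cgi_true <- colMeans(beta[is_cgi, , drop = FALSE])
    avg_bb_true <- colMeans(beta[is_bb, , drop = FALSE])
    sigma_cgi <- spec$wgbs_sigma %||%
      (stats::sd(avg_cgi_true) * sqrt(1 / spec$wgbs_r^2 - 1))
    sigma_bb <- spec$wgbs_sigma %||%
      (stats::sd(avg_bb_true) * sqrt(1 / spec$wgbs_r^2 - 1))
    wgbs <- tibble(
      sample_id = sample_id,
      wgbs_cgi = avg_cgi_true + stats::rnorm(n_sample, 0, sigma_cgi),
      wgbs_backbone = avg_bb_true + stats::rnorm(n_sample, 0, sigma_bb)
    )

    out <- list(
      spec = spec, annotations = ann, taxonomy = taxonomy,
      manifest = manifest, beta = beta, detection_p = detection_p,
      clinical = clinical, mutations = mutations,
      copy_number = list(
        log2 = cn_log2,
        gene_coords = cn_gene_rows[c("name", "chrom", "start", "end")]
      ),
      wgbs = wgbs,
      truth = list(
        compartment = stats::setNames(compartment, manifest$probe_id),
        in_polycomb = stats::setNames(in_polycomb, manifest$probe_id),
        in_lad = stats::setNames(in_lad, manifest$probe_id),
        probe_mean = stats::setNames(probe_mean, manifest$probe_id),
        cgi_add = cgi_add, bb_sub = bb_sub,
        scna_coupling = truth_coupling,
        wgbs_sigma = c(cgi = sigma_cgi, backbone = sigma_bb)
      )
    )
    class(out) <- "meth_cohort"
    out
  })
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic methylation cohort: %d probes x %d samples (%d normal, %d tumor in %d block(s))\n",
    nrow(x$beta), ncol(x$beta), sum(x$clinical$tissue == "normal"),
    sum(x$clinical$tissue == "tumor"), length(x$spec$tumor_blocks)
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact plain-text formats the pipeline reads: BED tracks and a
#' genome file for the annotations, TSV matrices for beta and detection
#' p-values, and TSV tables for the manifest, clinical, mutation,
#' copy-number and WGBS data.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- cohort$annotations
  write_genome(ann$genome, file.path(dir, "genome.txt"))
  write_bed(ann$cgi, file.path(dir, "cgi.bed"))
  write_bed(ann$genes[c("chrom", "start", "end", "name", "strand")] |>
    mutate(score = 0, .before = "strand"), file.path(dir, "genes.bed"))
  write_bed(ann$exons, file.path(dir, "exons.bed"))
  write_bed(ann$tf_sites, file.path(dir, "tf_sites.bed"))
  write_bed(ann$dnase, file.path(dir, "dnase.bed"))
  write_bed(ann$enhancer, file.path(dir, "enhancer.bed"))
  write_bed(ann$repeats, file.path(dir, "repeats.bed"))
  write_bed(ann$lads, file.path(dir, "lads.bed"))
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(cohort$detection_p, file.path(dir, "detection_p.tsv"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
  write_matrix_tsv(cohort$mutations, file.path(dir, "mutations.tsv"), id_col = "sample_id")
  write_matrix_tsv(cohort$copy_number$log2, file.path(dir, "copy_number.tsv"), id_col = "sample_id")
  readr::write_tsv(cohort$copy_number$gene_coords, file.path(dir, "cn_genes.tsv"), progress = FALSE)
  readr::write_tsv(cohort$wgbs, file.path(dir, "wgbs.tsv"), progress = FALSE)
  invisible(dir)
}
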