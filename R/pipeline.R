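# End-to-end orchestration: simulate (or read) -> region taxonomy -> probe
# QC -> per-sample summaries -> differential calls + TF enrichment ->
# window/LAD tracks -> association battery, with every stage output written
# to a run directory and recorded in a manifest.

#' Default pipeline configuration
#'
#' All numeric thresholds of the analysis with their standard values: HC
#' cutoff 0.24 and LB cutoff 0.78 on the two methylation axes, differential
#' threshold 0.2, detection-p cutoff 0.05, SNP window 10 bp, repeat window
#' 15 bp, shore flank 2 kb, promoter length 1.5 kb, 5'-body fraction 0.1,
#' and 2 Mb / 1 Mb sliding windows.
#'
#' @param seed Seed for the simulation stage.
#' @param out_dir Run directory for stage outputs.
#' @param simulate Whether to generate the inputs with [simulate_cohort()]
#'   (`TRUE`) or read them from `input_dir` (written by [write_cohort()]).
#' @param input_dir Directory of input files when `simulate = FALSE`.
#' @param ... Overrides for any config entry (e.g. `cgi_cut = 0.3`,
#'   `window_bin = 1e6`, `min_normals = 5`).
#' @return A named list of configuration values.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("backbone_run_"),
                       simulate = TRUE, input_dir = NULL, ...) {
  config <- list(
    seed = seed, out_dir = out_dir, simulate = simulate, input_dir = input_dir,
    cgi_cut = 0.24, backbone_cut = 0.78, dm_threshold = 0.2,
    detection_p_cut = 0.05, snp_window = 10, repeat_window = 15,
    shore_flank = 2000, promoter_length = 1500, body_fraction = 0.1,
    window_bin = 2e6, window_step = 1e6, min_probes = 100, min_normals = 10
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config entries: %s", paste(unknown, collapse = ", ")))
  }
  config[names(overrides)] <- overrides
  numeric_keys <- c(
    "cgi_cut", "backbone_cut", "dm_threshold", "detection_p_cut",
    "snp_window", "repeat_window", "shore_flank", "promoter_length",
    "body_fraction", "window_bin", "window_step"
  )
  if (any(unlist(config[numeric_keys]) <= 0)) {
    abort("all thresholds must be positive")
  }
  config
}

read_cohort_inputs <- function(dir) {
  list(
    genome = read_genome(file.path(dir, "genome.txt")),
    cgi = read_bed(file.path(dir, "cgi.bed")),
    genes = read_bed(file.path(dir, "genes.bed")),
    exons = read_bed(file.path(dir, "exons.bed")),
    tf_sites = read_bed(file.path(dir, "tf_sites.bed")),
    dnase = read_bed(file.path(dir, "dnase.bed")),
    enhancer = read_bed(file.path(dir, "enhancer.bed")),
    repeats = read_bed(file.path(dir, "repeats.bed")),
    lads = read_bed(file.path(dir, "lads.bed")),
    manifest = readr::read_tsv(file.path(dir, "manifest.tsv"),
      col_types = readr::cols(), progress = FALSE
    ),
    beta = read_matrix_tsv(file.path(dir, "beta.tsv")),
    detection_p = read_matrix_tsv(file.path(dir, "detection_p.tsv")),
    clinical = readr::read_tsv(file.path(dir, "clinical.tsv"),
      col_types = readr::cols(), progress = FALSE
    ),
    mutations = read_matrix_tsv(file.path(dir, "mutations.tsv")),
    copy_number = read_matrix_tsv(file.path(dir, "copy_number.tsv")),
    cn_genes = readr::read_tsv(file.path(dir, "cn_genes.tsv"),
      col_types = readr::cols(), progress = FALSE
    ),
    wgbs = readr::read_tsv(file.path(dir, "wgbs.tsv"),
      col_types = readr::cols(), progress = FALSE
    )
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated or file-based cohort and writes the
#' stage outputs (TSV/BED/bedGraph) plus a JSON run manifest recording the
#' configuration, seed and per-stage row counts. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()] list.
#' @return The run manifest (list), invisibly; outputs are under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  if (isTRUE(config$simulate)) {
    cohort <- run_stage("simulate", {
      simulate_cohort(cohort_spec(seed = config$seed))
    })
    inputs <- list(
      genome = cohort$annotations$genome,
      cgi = cohort$annotations$cgi,
      genes = cohort$annotations$genes,
      exons = cohort$annotations$exons,
      tf_sites = cohort$annotations$tf_sites,
      dnase = cohort$annotations$dnase,
      enhancer = cohort$annotations$enhancer,
      repeats = cohort$annotations$repeats,
      lads = cohort$annotations$lads,
      manifest = cohort$manifest,
      beta = cohort$beta, detection_p = cohort$detection_p,
      clinical = cohort$clinical,
      mutations = cohort$mutations,
      copy_number = cohort$copy_number$log2,
      cn_genes = cohort$copy_number$gene_coords,
      wgbs = cohort$wgbs
    )
  } else {
    if (is.null(config$input_dir)) abort("config$input_dir required when simulate = FALSE")
    inputs <- run_stage("read-inputs", read_cohort_inputs(config$input_dir))
  }

  taxonomy <- run_stage("build-regions", {
    build_region_taxonomy(
      genome = inputs$genome, cgi = inputs$cgi, genes = inputs$genes,
      exons = inputs$exons, dnase = inputs$dnase, tf = inputs$tf_sites,
      enhancer = inputs$enhancer, repeats = inputs$repeats,
      shore_flank = config$shore_flank,
      promoter_length = config$promoter_length,
      body_fraction = config$body_fraction
    )
  })
  for (nm in names(taxonomy)) {
    write_bed(taxonomy[[nm]], file.path(config$out_dir, paste0("region_", nm, ".bed")))
  }

  qc <- run_stage("qc", {
    retained <- filter_probes(inputs$manifest, snp_window = config$snp_window)
    beta <- mask_detection(
      inputs$beta[retained$probe_id, , drop = FALSE],
      inputs$detection_p[retained$probe_id, , drop = FALSE],
      cutoff = config$detection_p_cut
    )
    assignment <- assign_regions(retained, taxonomy)
    list(manifest = retained, beta = beta, assignment = assignment)
  })
  readr::write_tsv(region_probe_counts(qc$assignment),
    file.path(config$out_dir, "probe_counts.tsv"),
    progress = FALSE
  )

  summary <- run_stage("summarize", {
    summarize_samples(qc$beta, qc$assignment,
      sample_info = inputs$clinical,
      cgi_cut = config$cgi_cut, backbone_cut = config$backbone_cut,
      min_probes = config$min_probes
    )
  })
  readr::write_tsv(summary, file.path(config$out_dir, "summary.tsv"), progress = FALSE)

  conc <- run_stage("concordance", {
    if (!is.null(inputs$wgbs)) tidy(concordance(summary, inputs$wgbs)) else NULL
  })
  if (!is.null(conc)) {
    readr::write_tsv(conc, file.path(config$out_dir, "concordance.tsv"), progress = FALSE)
  }

  normal_ids <- summary$sample_id[!is.na(summary$tissue) & summary$tissue == "normal"]
  enrichment <- NULL
  calls <- NULL
  if (length(normal_ids) >= config$min_normals) {
    diff_res <- run_stage("differential", {
      ref <- normal_reference(qc$beta, normal_ids)
      tumor_ids <- setdiff(colnames(qc$beta), normal_ids)
      calls <- call_differential(qc$beta, ref,
        samples = tumor_ids,
        threshold = config$dm_threshold
      )
      annotated <- qc$manifest[
        qc$manifest$probe_id %in% qc$assignment$probe_id[!qc$assignment$unannotated],
      ]
      enr <- tf_enrichment(calls, inputs$tf_sites, annotated)
      list(ref = ref, calls = calls, enrichment = enr)
    })
    calls <- diff_res$calls
    enrichment <- diff_res$enrichment
    readr::write_tsv(calls, file.path(config$out_dir, "differential_calls.tsv"),
      progress = FALSE
    )
    readr::write_tsv(enrichment, file.path(config$out_dir, "tf_enrichment.tsv"),
      progress = FALSE
    )
  }

  windows <- run_stage("windows", {
    tumor_ids <- setdiff(colnames(qc$beta), normal_ids)
    ref <- if (length(normal_ids) >= 2) normal_reference(qc$beta, normal_ids) else NULL
    change <- probe_change(qc$beta, qc$manifest, samples = tumor_ids, normal_mean = ref)
    bb_change <- change[change$probe_id %in%
      qc$assignment$probe_id[qc$assignment$backbone], ]
    track <- window_means(bb_change, inputs$genome,
      bin = config$window_bin, step = config$window_step
    )
    contrast <- lad_contrast(change, inputs$lads, qc$assignment)
    list(change = change, track = track, contrast = contrast)
  })
  write_bedgraph(windows$track, file.path(config$out_dir, "backbone_change.bedgraph"))
  readr::write_tsv(windows$contrast, file.path(config$out_dir, "lad_contrast.tsv"),
    progress = FALSE
  )

  assoc <- run_stage("associations", {
    tumors <- summary[!is.na(summary$tissue) & summary$tissue == "tumor", ]
    clin <- assoc_clinical(tumors, inputs$clinical,
      variables = intersect(c("stage", "grade", "msi"), names(inputs$clinical))
    )
    mut_df <- tibble::as_tibble(inputs$mutations, rownames = "sample_id")
    mol <- assoc_molecular(tumors, mut_df,
      variables = colnames(inputs$mutations), scale = "binary"
    )
    scans <- bind_rows(purrr::map(
      setdiff(unique(tumors$tumor_type), NA),
      function(tt) {
        sub <- tumors[tumors$tumor_type == tt, ]
        sc <- scna_scan(sub, inputs$copy_number, inputs$cn_genes)
        sc$tumor_type <- tt
        sc
      }
    ))
    pct <- if (length(unique(scans$tumor_type)) >= 2) {
      cross_tumor_percentiles(scans)
    } else {
      NULL
    }
    list(clinical = clin, molecular = mol, scans = scans, percentiles = pct)
  })
  readr::write_tsv(assoc$clinical, file.path(config$out_dir, "assoc_clinical.tsv"),
    progress = FALSE
  )
  readr::write_tsv(assoc$molecular, file.path(config$out_dir, "assoc_molecular.tsv"),
    progress = FALSE
  )
  readr::write_tsv(assoc$scans, file.path(config$out_dir, "scna_scan.tsv"),
    progress = FALSE
  )
  if (!is.null(assoc$percentiles)) {
    readr::write_tsv(assoc$percentiles, file.path(config$out_dir, "scna_percentiles.tsv"),
      progress = FALSE
    )
  }

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config[setdiff(names(config), c("out_dir", "input_dir"))]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("backbonemeth")),
    n_probes_retained = nrow(qc$manifest),
    n_samples = nrow(summary),
    region_probe_counts = stats::setNames(
      as.list(region_probe_counts(qc$assignment)$n_probes),
      region_probe_counts(qc$assignment)$region
    ),
    n_differential_calls = if (!is.null(calls)) nrow(calls) else 0L,
    n_windows = nrow(windows$track),
    n_association_tests = nrow(assoc$clinical) + nrow(assoc$molecular) + nrow(assoc$scans),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
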