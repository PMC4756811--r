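#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join inner_join distinct rename across n
#' @importFrom tibble tibble as_tibble
NULL

# Regions are tibbles with columns chrom, start, end (0-based, half-open),
# optionally strand and name; a genome is a tibble with chrom, length.

#' Construct a region tibble
#'
#' Builds and validates a table of genomic intervals in BED convention
#' (0-based, half-open). This is the unit of the region algebra: CpG islands,
#' shores, promoters, exons, TF-binding sites, repeats, LADs and the backbone
#' are all represented this way.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like interval bounds, `0 <= start < end`.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."`.
#' @param name Optional feature name.
#' @return A tibble with columns `chrom`, `start`, `end` and any of
#'   `strand`, `name` that were supplied.
#' @examples
#' region_tbl("chr1", c(100, 150), c(200, 300))
#' @export
region_tbl <- function(chrom, start, end, strand = NULL, name = NULL) {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end)
  )
  if (!is.null(strand)) out$strand <- as.character(strand)
  if (!is.null(name)) out$name <- as.character(name)
  validate_regions(out)
  out
}

validate_regions <- function(regions, arg = "regions") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(regions))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` must have columns chrom/start/end (missing: %s)",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(regions) == 0) return(invisible(regions))
  if (anyNA(regions$start) || anyNA(regions$end)) {
    abort(sprintf("`%s` has NA interval bounds", arg))
  }
  if (any(regions$start < 0)) {
    abort(sprintf("`%s` has intervals with start < 0", arg))
  }
  if (any(regions$end <= regions$start)) {
    bad <- which(regions$end <= regions$start)[1]
    abort(sprintf(
      "`%s` has malformed intervals with end <= start (e.g. row %d: %s:%g-%g)",
      arg, bad, regions$chrom[bad], regions$start[bad], regions$end[bad]
    ))
  }
  invisible(regions)
}

validate_genome <- function(genome) {
  if (!all(c("chrom", "length") %in% names(genome))) {
    abort("`genome` must have columns chrom and length")
  }
  if (any(genome$length <= 0) || anyNA(genome$length)) {
    abort("`genome` chromosome lengths must be positive")
  }
  if (anyDuplicated(genome$chrom)) abort("duplicated chromosome in `genome`")
  invisible(genome)
}

# 0-based half-open tibble -> 1-based closed GRanges (and back)
regions_to_gr <- function(regions, genome = NULL) {
  seqlengths <- NULL
  seqnames_levels <- NULL
  if (!is.null(genome)) {
    seqlengths <- stats::setNames(as.integer(genome$length), genome$chrom)
    seqnames_levels <- genome$chrom
  }
  if (nrow(regions) == 0) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(seqlengths)) {
      gr <- GenomicRanges::GRanges(seqlengths = seqlengths)
    }
    return(gr)
  }
  strand <- if ("strand" %in% names(regions)) {
    ifelse(regions$strand %in% c("+", "-"), regions$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = seqnames_levels %||% unique(regions$chrom)),
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    strand = strand,
    seqlengths = seqlengths
  )
}

gr_to_regions <- function(gr) {
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
  # canonical order regardless of the seqlevel order the input implied
  arrange(out, .data$chrom, .data$start)
}

#' Normalize a region set
#'
#' Sorts intervals and merges overlapping or bookended ones so that the
#' result is a minimal sorted set of disjoint intervals covering exactly the
#' same bases. `region_normalize()` is idempotent and order-independent.
#'
#' @param regions A region tibble (`chrom`, `start`, `end`).
#' @return A normalized region tibble (`chrom`, `start`, `end`), sorted by
#'   chromosome then start.
#' @examples
#' region_normalize(region_tbl("chr1", c(100, 150), c(200, 300)))
#' @export
region_normalize <- function(regions) {
  validate_regions(regions)
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  gr <- GenomicRanges::reduce(regions_to_gr(regions[c("chrom", "start", "end")]))
  gr_to_regions(GenomicRanges::sort(gr))
}

#' Total bases covered by a region set
#'
#' @param regions A region tibble; normalized first so overlapping input
#'   intervals are not double-counted.
#' @return A single number of covered bases.
#' @export
region_width <- function(regions) {
  norm <- region_normalize(regions)
  sum(norm$end - norm$start)
}

#' Union of several region sets
#'
#' @param ... Region tibbles (or a single list of them).
#' @return The normalized union as a region tibble.
#' @export
region_union <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.data.frame(sets[[1]]) == FALSE) sets <- sets[[1]]
  sets <- purrr::keep(sets, ~ !is.null(.x))
  if (length(sets) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  region_normalize(bind_rows(lapply(sets, function(s) s[c("chrom", "start", "end")])))
}

#' CpG-island shores
#'
#' Computes the 2 kb (by default) flanking regions on each side of every CpG
#' island, clipped to chromosome bounds, with the island bases themselves
#' excluded, so that shores and islands are disjoint region classes.
#'
#' @param cgi Region tibble of CpG islands.
#' @param genome Genome tibble (`chrom`, `length`).
#' @param flank Shore width in bp on each side (default 2000).
#' @return Normalized region tibble of shores.
#' @examples
#' genome <- tibble::tibble(chrom = "chr1", length = 1e6)
#' region_shores(region_tbl("chr1", 10000, 10500), genome)
#' @export
region_shores <- function(cgi, genome, flank = 2000) {
  validate_regions(cgi, "cgi")
  validate_genome(genome)
  cgi <- region_normalize(cgi)
  if (nrow(cgi) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (!all(cgi$chrom %in% genome$chrom)) {
    abort("`cgi` uses chromosomes absent from `genome`")
  }
  lengths <- stats::setNames(genome$length, genome$chrom)
  flanks <- bind_rows(
    tibble(chrom = cgi$chrom, start = pmax(0, cgi$start - flank), end = cgi$start),
    tibble(
      chrom = cgi$chrom, start = cgi$end,
      end = pmin(unname(lengths[cgi$chrom]), cgi$end + flank)
    )
  )
  flanks <- filter(flanks, .data$end > .data$start)
  region_subtract(region_normalize(flanks), cgi)
}

#' Subtract one region set from another
#'
#' @param regions,exclude Region tibbles; bases of `exclude` are removed from
#'   `regions`.
#' @return Normalized region tibble of `regions` bases not in `exclude`.
#' @export
region_subtract <- function(regions, exclude) {
  validate_regions(regions)
  validate_regions(exclude, "exclude")
  a <- regions_to_gr(region_normalize(regions))
  b <- regions_to_gr(region_normalize(exclude))
  if (length(a) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (length(b) == 0) return(region_normalize(regions))
  common <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- common
  GenomeInfoDb::seqlevels(b) <- common
  gr_to_regions(GenomicRanges::sort(GenomicRanges::setdiff(a, b)))
}

validate_genes <- function(genes, require_strand = TRUE) {
  validate_regions(genes, "genes")
  if (require_strand) {
    if (!"strand" %in% names(genes)) abort("`genes` must have a strand column")
    bad <- !genes$strand %in% c("+", "-")
    if (any(bad)) {
      abort(sprintf(
        "%d gene(s) have strand other than +/- ; promoters and 5'-bodies are undefined without orientation",
        sum(bad)
      ))
    }
  }
  invisible(genes)
}

#' Promoter regions of genes
#'
#' The promoter is the fixed-width window (1.5 kb by default) immediately
#' upstream of the strand-appropriate transcription start site, clipped to
#' chromosome bounds.
#'
#' @param genes Region tibble of transcripts with a `strand` column
#'   (`"+"`/`"-"`); one promoter is emitted per input row, so multi-transcript
#'   genes may contribute several (later deduplicated by
#'   [region_normalize()]).
#' @param genome Genome tibble.
#' @param upstream Promoter length in bp (default 1500).
#' @return Region tibble with one row per input gene (un-merged; pass through
#'   [region_normalize()] for the promoter class track). Carries over a
#'   `name` column when present.
#' @examples
#' genome <- tibble::tibble(chrom = "chr1", length = 1e6)
#' genes <- region_tbl("chr1", 5000, 8000, strand = c("+"))
#' region_promoters(genes, genome)
#' @export
region_promoters <- function(genes, genome, upstream = 1500) {
  validate_genes(genes)
  validate_genome(genome)
  if (!all(genes$chrom %in% genome$chrom)) {
    abort("`genes` uses chromosomes absent from `genome`")
  }
  lengths <- stats::setNames(genome$length, genome$chrom)
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0, genes$start - upstream), genes$end)
  end <- ifelse(plus, genes$start,
    pmin(unname(lengths[genes$chrom]), genes$end + upstream)
  )
  out <- tibble(chrom = genes$chrom, start = start, end = end, strand = genes$strand)
  if ("name" %in% names(genes)) out$name <- genes$name
  filter(out, .data$end > .data$start)
}

#' 5'-body regions of genes
#'
#' The 5'-body is the first fraction (10% by default) of the gene body
#' measured from the strand-appropriate 5' end. Fractional lengths are
#' floored (rounded toward the 5' end), with a minimum of 1 bp.
#'
#' @inheritParams region_promoters
#' @param fraction Fraction of the gene body taken from the 5' end
#'   (default 0.1).
#' @return Region tibble, one row per input gene.
#' @examples
#' genes <- region_tbl("chr1", 5000, 8000, strand = "+")
#' region_five_prime_body(genes) # chr1:5000-5300
#' @export
region_five_prime_body <- function(genes, fraction = 0.1) {
  validate_genes(genes)
  len <- genes$end - genes$start
  if (any(len < 1)) abort("gene of zero length")
  frac_len <- pmax(1, floor(fraction * len))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start, genes$end - frac_len)
  end <- ifelse(plus, genes$start + frac_len, genes$end)
  out <- tibble(chrom = genes$chrom, start = start, end = end, strand = genes$strand)
  if ("name" %in% names(genes)) out$name <- genes$name
  out
}

#' Build the full region taxonomy
#'
#' Assembles the named list of normalized region class tracks used
#' throughout the pipeline: the supplied CpG islands, DNase hypersensitive
#' sites, TF-binding sites, enhancers and repeats; shores, promoters and
#' 5'-bodies derived from the islands and gene models; exons; and the
#' backbone as the genome complement of all of the above.
#'
#' @param genome Genome tibble (`chrom`, `length`).
#' @param cgi Region tibble of CpG islands.
#' @param genes Region tibble of transcripts with `strand` (one row per
#'   transcript; multi-transcript genes contribute one promoter/5'-body per
#'   row).
#' @param exons Region tibble of exons (optional).
#' @param dnase,tf,enhancer,repeats Optional region tibbles for DNase
#'   hypersensitive sites, TF-binding sites, enhancers and repeat elements.
#' @param shore_flank Shore width in bp (default 2000).
#' @param promoter_length Promoter length in bp (default 1500).
#' @param body_fraction 5'-body fraction of the gene body (default 0.1).
#' @return A named list of normalized region tibbles with elements `cgi`,
#'   `shore`, `promoter`, `five_prime_body`, `exon`, `dnase`, `tf`,
#'   `enhancer`, `repeat`, `backbone` (absent optional inputs yield empty
#'   tracks).
#' @export
build_region_taxonomy <- function(genome, cgi, genes, exons = NULL,
                                  dnase = NULL, tf = NULL, enhancer = NULL,
                                  repeats = NULL, shore_flank = 2000,
                                  promoter_length = 1500, body_fraction = 0.1) {
  validate_genome(genome)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric())
  cgi_norm <- region_normalize(cgi)
  taxonomy <- list(
    cgi = cgi_norm,
    shore = region_shores(cgi_norm, genome, flank = shore_flank),
    promoter = region_normalize(region_promoters(genes, genome, upstream = promoter_length)),
    five_prime_body = region_normalize(region_five_prime_body(genes, fraction = body_fraction)),
    exon = if (is.null(exons)) empty else region_normalize(exons),
    dnase = if (is.null(dnase)) empty else region_normalize(dnase),
    tf = if (is.null(tf)) empty else region_normalize(tf),
    enhancer = if (is.null(enhancer)) empty else region_normalize(enhancer),
    `repeat` = if (is.null(repeats)) empty else region_normalize(repeats)
  )
  taxonomy$backbone <- region_backbone(
    genome,
    functional = taxonomy[c(
      "cgi", "shore", "promoter", "five_prime_body",
      "exon", "dnase", "tf", "enhancer"
    )],
    repeats = taxonomy$`repeat`
  )
  taxonomy
}

#' Build the backbone region set
#'
#' The backbone is the genome complement of the union of all annotated
#' functional region classes (CpG islands, shores, promoters, 5'-bodies,
#' exons, DNase hypersensitive sites, TF-binding sites, enhancers) and
#' repeats. It serves as a proxy for non-functional intergenic sequence whose
#' average methylation is the second summary axis of the analysis.
#'
#' @param genome Genome tibble (`chrom`, `length`).
#' @param functional A list of region tibbles (the functional classes).
#' @param repeats Region tibble of repeat elements (optional).
#' @return Normalized region tibble of backbone intervals. Together with the
#'   normalized union of the excluded sets it exactly tiles the genome.
#' @examples
#' genome <- tibble::tibble(chrom = "chr1", length = 1000)
#' region_backbone(genome, list(region_tbl("chr1", 100, 300)))
#' @export
region_backbone <- function(genome, functional, repeats = NULL) {
  validate_genome(genome)
  if (is.data.frame(functional)) functional <- list(functional)
  excluded <- region_union(c(functional, list(repeats)))
  genome_regions <- tibble(chrom = genome$chrom, start = 0, end = genome$length)
  region_subtract(genome_regions, excluded)
}
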