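#' Read a BED track
#'
#' Reads a >= 3 column tab-separated BED file into a merged interval tibble
#' (0-based half-open, as BED is natively). A 4th column, when present, is
#' kept as `name` (merging is skipped in that case so names survive).
#'
#' @param path File path.
#' @param merge Merge overlapping intervals on load (default TRUE; forced
#'   off when a name column is present).
#' @return Interval tibble (`chrom`, `start`, `end`\[, `name`\]).
#' @export
read_bed <- function(path, merge = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: fewer than 3 tab-separated fields", bad[1]))
  }
  starts <- suppressWarnings(as.integer(map_chr(fields, 2)))
  ends <- suppressWarnings(as.integer(map_chr(fields, 3)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))[1]
    abort(sprintf("malformed BED line %d: non-integer coordinates", bad))
  }
  track <- tibble(
    chrom = map_chr(fields, 1),
    start = starts,
    end = ends
  )
  has_name <- all(lengths(fields) >= 4)
  if (has_name) track$name <- map_chr(fields, 4)
  if (merge && !has_name) track <- merge_intervals(track)
  track
}

#' Write a track as BED
#'
#' @param track Interval tibble (`chrom`, `start`, `end`, optional further
#'   columns written in order).
#' @param path Output path.
#' @export
write_bed <- function(track, path) {
  readr::write_tsv(as_tibble(track), path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from a BED12-like file
#'
#' Columns: chrom, start, end, name, score, strand, thickStart, thickEnd,
#' itemRgb, blockCount, blockSizes, blockStarts (sizes/starts comma
#' separated, starts relative to the gene start). TSS/TES are derived
#' strand-aware (TSS = start for `+`, = end for `-`), and exons are numbered
#' in transcription order.
#'
#' @param path File path.
#' @return List of tibbles `genes` (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes`) and `exons` (`gene_id`, `exon`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "thickStart", "thickEnd", "itemRgb", "blockCount",
                  "blockSizes", "blockStarts"),
    col_types = "ciicdciicicc", progress = FALSE
  )
  if (!all(raw$strand %in% c("+", "-"))) {
    abort('gene strand must be "+" or "-"')
  }
  genes <- .derive_tss_tes(tibble(
    gene_id = raw$name, chrom = raw$chrom, strand = raw$strand,
    start = raw$start, end = raw$end
  ))
  exons <- pmap(
    list(raw$name, raw$start, raw$strand, raw$blockSizes, raw$blockStarts),
    function(gene_id, gstart, strand, sizes, offsets) {
      sizes <- as.integer(strsplit(sizes, ",")[[1]])
      offsets <- as.integer(strsplit(offsets, ",")[[1]])
      ex <- tibble(
        gene_id = gene_id,
        start = gstart + offsets,
        end = gstart + offsets + sizes
      )
      ex$exon <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
      arrange(select(ex, "gene_id", "exon", "start", "end"), .data$exon)
    }
  ) %>% list_rbind()
  list(genes = genes, exons = exons)
}

#' Write gene models as BED12
#'
#' @param genes,exons Gene and exon tibbles as produced by
#'   [generate_genome()] or [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, exons, path) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  rows <- pmap(genes, function(gene_id, chrom, strand, start, end, ...) {
    ex <- arrange(filter(exons, .data$gene_id == !!gene_id), .data$start)
    tibble(
      chrom = chrom, start = start, end = end, name = gene_id, score = 0,
      strand = strand, thickStart = start, thickEnd = end, itemRgb = "0",
      blockCount = nrow(ex),
      blockSizes = paste(ex$end - ex$start, collapse = ","),
      blockStarts = paste(ex$start - start, collapse = ",")
    )
  }) %>% list_rbind()
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' Write a toy genome to disk
#'
#' Gene models as BED12 (`genes.bed`), CpGs as TSV (`cpgs.tsv`:
#' `cpg_id`, `chrom`, `pos`) and chromosome lengths (`chromosomes.tsv`).
#'
#' @param genome A `toy_genome`.
#' @param dir Output directory (created if needed).
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(genome$genes, genome$exons, file.path(dir, "genes.bed"))
  readr::write_tsv(genome$cpgs, file.path(dir, "cpgs.tsv"))
  readr::write_tsv(genome$chromosomes, file.path(dir, "chromosomes.tsv"))
  invisible(dir)
}

#' Write a simulated cohort to disk
#'
#' Methylation, expression and covariates as TSV keyed by sample id, plus
#' the ground-truth ledger of planted effects.
#'
#' @param cohort An `ecpg_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth <- as_tibble(cohort$methylation, rownames = "sample_id")
  expr <- as_tibble(t(cohort$expression), rownames = "sample_id")
  readr::write_tsv(meth, file.path(dir, "methylation.tsv"))
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write classified eCpGs as a genome-browser BED track
#'
#' One line per eCpG-transcript pair: name = associated gene, score =
#' `min(1000, -10 log10 p)`, strand = direction of correlation.
#'
#' @param classified Classified records with `cpg_id`, `chrom`, `pos`,
#'   `gene_id`, `p`, `effect`.
#' @param path Output path.
#' @export
write_ucsc_track <- function(classified, path) {
  classified <- as_tibble(classified)
  track <- transmute(classified,
    chrom = .data$chrom,
    start = .data$pos,
    end = .data$pos + 1L,
    name = .data$gene_id,
    score = round(pmin(1000, -10 * log10(pmax(.data$p, 1e-300)))),
    strand = ifelse(.data$effect >= 0, "+", "-")
  )
  readr::write_tsv(track, path, col_names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' All thresholds of the analysis live here, with the scan's defaults:
#' suggestive 1e-5 and significant 1e-11 p-value tiers, GIF cap 2, 50 kb cis
#' window, 2500 bp promoter window, 1500 bp shore/shelf width, neighbor
#' windows 100-2000 bp. Can be loaded from a YAML file; explicit arguments
#' override file values.
#'
#' @param path Optional YAML file with any of the fields.
#' @param ... Named overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    out_dir = NULL,
    seed = NULL,
    n_chrom = 2, genes_per_chrom = 10, cpg_density = 0.5,
    n_samples = 100, n_confounders = 0, bimodal_fraction = 0.8,
    planted = NULL,
    alpha_suggestive = .default_alpha_suggestive,
    alpha_significant = .default_alpha_significant,
    gif_max = 2,
    cis_window = 50000, promoter_window = 2500,
    shore_width = 1500,
    neighbor_windows = c(100, 500, 1000, 1500, 2000),
    n_perm = 1000
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (is.null(cfg$seed)) abort("config must set a seed")
  if (is.null(cfg$out_dir)) abort("config must set out_dir")
  bad <- c("alpha_suggestive", "alpha_significant", "cis_window",
           "promoter_window", "shore_width")
  if (any(unlist(cfg[bad]) <= 0)) abort("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulate a genome and cohort, scan all pairs, apply the GIF filter,
#' classify significant pairs, compute neighbor congruence and the
#' intermediate-methylation enrichment, and write every artifact (TSVs, BED
#' track, run log) into `config$out_dir`. Re-running with an identical
#' config and seed reproduces the outputs byte for byte.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory results (`genome`, `cohort`,
#'   `records`, `gif`, `classified`, `congruence`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(stage, fmt, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  cat(sprintf(
    "ecpgscan %s | seed %d | thresholds: suggestive %g significant %g gif_max %g\n",
    as.character(utils::packageVersion("ecpgscan")), config$seed,
    config$alpha_suggestive, config$alpha_significant, config$gif_max
  ), file = log_path)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  genome <- run_stage("simulate", generate_genome(
    config$n_chrom, config$genes_per_chrom, config$cpg_density, seed = config$seed
  ))
  cohort <- run_stage("simulate", generate_cohort(
    genome, config$n_samples, config$n_confounders,
    planted = config$planted, bimodal_fraction = config$bimodal_fraction,
    seed = config$seed + 1L
  ))
  write_genome(genome, file.path(config$out_dir, "genome"))
  write_cohort(cohort, file.path(config$out_dir, "cohort"))
  logf("simulate", "%d CpGs x %d transcripts x %d samples",
       ncol(cohort$methylation), nrow(cohort$expression), nrow(cohort$methylation))

  records <- run_stage("scan", scan_cohort(
    cohort,
    alpha_suggestive = config$alpha_suggestive,
    alpha_significant = config$alpha_significant
  ))
  readr::write_tsv(tidy(records), file.path(config$out_dir, "associations.tsv"))
  gif <- compute_gif(records, gif_max = config$gif_max)
  readr::write_tsv(gif, file.path(config$out_dir, "gif.tsv"))
  kept <- run_stage("gif_filter", filter_gif(records, gif_max = config$gif_max))
  logf("scan", "%d pairs tested; %d transcripts removed by GIF > %g",
       nrow(records), length(attr(kept, "removed_transcripts")), config$gif_max)

  sig <- filter(kept, .data$tier == "significant")
  if (nrow(sig) == 0) {
    logf("classify", "no significant pairs; writing empty outputs")
    classified <- sig %>% mutate(
      gene_id = character(0), pos = integer(0),
      broad = factor(character(0), levels = c("cis", "distal", "trans")),
      detailed = factor(character(0), levels = .detailed_levels),
      canonical = logical(0), signed_distance = integer(0)
    )
    congruence <- NULL
    enrichment <- NULL
  } else {
    classified <- run_stage("classify", classify_associations(
      sig, genome,
      cis_window = config$cis_window, promoter_window = config$promoter_window
    ))
    cls_out <- left_join(
      classified,
      select(genome$cpgs, "cpg_id", chrom = "chrom"),
      by = "cpg_id"
    )
    write_ucsc_track(cls_out, file.path(config$out_dir, "ecpgs.bed"))
    congruence <- run_stage("corroborate", neighbor_congruence(
      cls_out %>% mutate(sign = ifelse(.data$effect >= 0, "+", "-")) %>%
        select("cpg_id", "chrom", "pos", "gene_id", "sign"),
      windows = config$neighbor_windows
    ))
    readr::write_tsv(congruence, file.path(config$out_dir, "congruence.tsv"))
    enrichment <- run_stage("enrich", intermediate_methylation_enrichment(
      colMeans(cohort$methylation),
      colnames(cohort$methylation) %in% classified$cpg_id
    ))
    readr::write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
    logf("classify", "%d significant pairs classified", nrow(classified))
  }
  readr::write_tsv(as_tibble(classified), file.path(config$out_dir, "classified.tsv"))

  invisible(list(
    genome = genome, cohort = cohort, records = records, gif = gif,
    classified = classified, congruence = congruence, enrichment = enrichment
  ))
}
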