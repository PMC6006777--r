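#' @noRd
.detailed_levels <- c(
  "near_promoter", "in_gene_body", "closest_upstream_gene",
  "closest_downstream_gene", "closer_5prime", "closer_3prime",
  "gene_between", "in_different_gene", "multiple_closer_between",
  "distal", "trans"
)
.canonical_levels <- c(
  "near_promoter", "in_gene_body", "closest_upstream_gene",
  "closest_downstream_gene"
)

# base-position view of a gene row: classification distances are measured
# between base positions, which keeps every rule exactly mirror-symmetric
# (boundary TSS/TES coordinates are off by one under reflection)
.gene_geometry <- function(gene) {
  fwd <- gene$strand == "+"
  list(
    chrom = gene$chrom,
    lo = gene$start, hi = gene$end,
    tss = ifelse(fwd, gene$start, gene$end - 1L),
    tes = ifelse(fwd, gene$end - 1L, gene$start),
    fwd = fwd
  )
}

# unsigned bp distance from a point to a half-open span (0 inside)
.span_distance <- function(pos, lo, hi) {
  ifelse(pos < lo, lo - pos, ifelse(pos >= hi, pos - (hi - 1L), 0L))
}

#' Classify one CpG-gene pair into the positional eCpG taxonomy
#'
#' Assigns the broad (`cis` < 50 kb from the gene span / `distal` same
#' chromosome beyond 50 kb / `trans` different chromosome) and detailed
#' category of a CpG relative to its associated gene and all other genes.
#' Within cis, the categories are, in precedence order: `near_promoter`
#' (within 2500 bp of the TSS on either side), `in_gene_body` (inside the
#' span, more than 2500 bp downstream of the TSS), `closest_downstream_gene`
#' (CpG upstream of the gene and the gene's TSS nearer than any other gene),
#' `closest_upstream_gene` (CpG past the TES, the gene's TES nearer than any
#' other gene), then the non-canonical configurations `closer_5prime`
#' (another TSS on the opposite side of the CpG is nearer than the
#' associated TSS), `closer_3prime` (another gene's TES is nearer than
#' either end of the associated gene), `gene_between` (another TSS lies
#' between the CpG and the associated TSS) and `in_different_gene` (the CpG
#' sits inside another gene's span); `multiple_closer_between` when more
#' than one of those four holds. All upstream/downstream logic is
#' strand-aware. The first four detailed categories are the canonical
#' methylation-expression roles.
#'
#' @param cpg One-row data frame (or list) with `chrom` and `pos`.
#' @param gene One-row data frame for the associated gene with `gene_id`,
#'   `chrom`, `strand`, `start`, `end`.
#' @param all_genes Gene table containing `gene` and its neighbors.
#' @param cis_window Cis distance threshold in bp (default 50000; cis is
#'   strictly less than this).
#' @param promoter_window Promoter half-width in bp (default 2500,
#'   inclusive).
#' @return One-row tibble: `broad`, `detailed`, `canonical`,
#'   `signed_distance` (bp from CpG to gene span; negative upstream of the
#'   TSS, 0 inside the span).
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1", strand = "+",
#'   start = 10000L, end = 20000L
#' )
#' classify_pair(list(chrom = "chr1", pos = 9000L), genes[1, ], genes)
#' @export
classify_pair <- function(cpg, gene, all_genes,
                          cis_window = 50000, promoter_window = 2500) {
  gene <- as.list(gene)
  if (gene$start >= gene$end) abort("malformed gene annotation: empty span")
  pos <- cpg$pos
  geom <- .gene_geometry(gene)

  if (cpg$chrom != gene$chrom) {
    return(.classification("trans", "trans", NA_integer_))
  }
  span_dist <- .span_distance(pos, geom$lo, geom$hi)
  upstream_side <- if (geom$fwd) pos < geom$lo else pos >= geom$hi
  signed <- if (span_dist == 0L) 0L else if (upstream_side) -span_dist else span_dist
  if (span_dist >= cis_window) {
    return(.classification("distal", "distal", signed))
  }

  d_tss <- abs(pos - geom$tss)
  d_tes <- abs(pos - geom$tes)
  inside <- span_dist == 0L
  if (d_tss <= promoter_window) {
    return(.classification("cis", "near_promoter", signed))
  }
  if (inside) {
    return(.classification("cis", "in_gene_body", signed))
  }

  others <- filter(as_tibble(all_genes),
                   .data$gene_id != gene$gene_id, .data$chrom == gene$chrom)
  if (nrow(others) > 0) {
    og <- .gene_geometry(others)
    other_span_d <- .span_distance(pos, og$lo, og$hi)
    d_other_min <- min(other_span_d)
  } else {
    d_other_min <- Inf
  }

  # CpG outside the span and beyond the promoter window: which end faces it?
  if (upstream_side) {
    # ties go to the associated gene in the closest-downstream role
    if (d_tss <= d_other_min) {
      return(.classification("cis", "closest_downstream_gene", signed))
    }
  } else {
    if (d_tes < d_other_min) {
      return(.classification("cis", "closest_upstream_gene", signed))
    }
  }

  og <- .gene_geometry(others)
  side_assoc <- sign(geom$tss - pos)
  side_other <- sign(og$tss - pos)
  between <- side_other == side_assoc & side_other != 0 &
    abs(og$tss - pos) < abs(geom$tss - pos)
  opposite <- side_other == -side_assoc & side_other != 0 & side_assoc != 0
  hits <- c(
    closer_5prime = any(opposite & abs(og$tss - pos) < d_tss),
    closer_3prime = any(abs(og$tes - pos) < min(d_tss, d_tes)),
    gene_between = any(between),
    in_different_gene = any(pos >= og$lo & pos < og$hi)
  )
  if (sum(hits) == 0) {
    abort("internal classification gap: no detailed category applies")
  }
  detailed <- if (sum(hits) > 1) "multiple_closer_between" else names(hits)[hits]
  .classification("cis", detailed, signed)
}

.classification <- function(broad, detailed, signed) {
  tibble(
    broad = factor(broad, levels = c("cis", "distal", "trans")),
    detailed = factor(detailed, levels = .detailed_levels),
    canonical = detailed %in% .canonical_levels,
    signed_distance = as.integer(signed)
  )
}

#' Classify every (CpG, gene) pair of a result set
#'
#' Vectorized driver around [classify_pair()]: joins CpG positions and gene
#' models onto scan records and appends `broad`, `detailed`, `canonical` and
#' `signed_distance` columns. Transcripts map to genes by
#' `transcript_id = "tx_<gene_id>"` unless an explicit `transcript_map`
#' (columns `transcript_id`, `gene_id`) is given.
#'
#' @param records Tibble with `cpg_id` and `transcript_id` columns (e.g.
#'   significant scan records).
#' @param genome A `toy_genome`, or a list with `genes` and `cpgs` tibbles.
#' @param transcript_map Optional transcript-to-gene map.
#' @inheritParams classify_pair
#' @return `records` with classification columns added.
#' @export
classify_associations <- function(records, genome, transcript_map = NULL,
                                  cis_window = 50000, promoter_window = 2500) {
  records <- as_tibble(records)
  genes <- as_tibble(genome$genes)
  cpgs <- as_tibble(genome$cpgs)
  if (is.null(transcript_map)) {
    transcript_map <- tibble(
      transcript_id = paste0("tx_", genes$gene_id),
      gene_id = genes$gene_id
    )
  }
  recs <- records %>%
    left_join(transcript_map, by = "transcript_id") %>%
    left_join(select(cpgs, "cpg_id", cpg_chrom = "chrom", pos = "pos"), by = "cpg_id")
  if (anyNA(recs$gene_id) || anyNA(recs$pos)) {
    abort("records contain transcripts or CpGs absent from the genome")
  }
  pairs <- distinct(recs, .data$cpg_chrom, .data$pos, .data$gene_id)
  cls <- pmap(
    list(pairs$cpg_chrom, pairs$pos, pairs$gene_id),
    function(chrom, pos, gene_id) {
      classify_pair(
        list(chrom = chrom, pos = pos),
        genes[genes$gene_id == gene_id, ],
        genes,
        cis_window = cis_window, promoter_window = promoter_window
      )
    }
  ) %>% list_rbind()
  pairs <- bind_cols(pairs, cls)
  recs %>%
    left_join(pairs, by = c("cpg_chrom", "pos", "gene_id")) %>%
    select(-"cpg_chrom")
}

#' Sub-localize a gene-body CpG
#'
#' For a CpG classified `in_gene_body`, reports whether it falls in an exon
#' (half-open interval overlap), and if so whether that exon is the first or
#' last in transcription order (strand-aware); otherwise it is intronic.
#'
#' @param cpg List or one-row data frame with `chrom`, `pos`.
#' @param gene One-row gene table entry.
#' @param exons Exon tibble (`gene_id`, `exon`, `start`, `end`), `exon`
#'   numbered in transcription order.
#' @return One-row tibble of logicals: `exonic`, `intronic`, `first_exon`,
#'   `last_exon`.
#' @export
genebody_subcategory <- function(cpg, gene, exons) {
  gene <- as.list(gene)
  cls <- classify_pair(cpg, gene, as_tibble(gene))
  if (cls$detailed != "in_gene_body") {
    abort("genebody_subcategory requires a CpG inside the gene body")
  }
  ex <- filter(as_tibble(exons), .data$gene_id == gene$gene_id)
  if (nrow(ex) == 0) abort("gene has no exons")
  hit <- cpg$pos >= ex$start & cpg$pos < ex$end
  tibble(
    exonic = any(hit),
    intronic = !any(hit),
    first_exon = any(hit & ex$exon == min(ex$exon)),
    last_exon = any(hit & ex$exon == max(ex$exon))
  )
}

#' Relative proportion of eCpGs by distance bin
#'
#' For each distance bin, the share of eCpGs falling in the bin divided by
#' the share of all array CpGs falling in it: values above 1 mean eCpGs
#' concentrate at that distance relative to the array background. Bins with
#' no array CpGs are undefined (NA), not zero.
#'
#' @param ecpg_distances Signed or unsigned distances of eCpGs to their
#'   associated gene.
#' @param all_cpg_distances Distances of all array CpGs to their nearest
#'   gene.
#' @param bins Vector of bin edges covering all observations.
#' @return Tibble with `bin_lo`, `bin_hi`, `n_ecpg`, `n_cpg`, `ratio`.
#' @export
relative_proportion_by_distance <- function(ecpg_distances, all_cpg_distances, bins) {
  if (length(ecpg_distances) == 0 || length(all_cpg_distances) == 0) {
    abort("empty input")
  }
  if (min(c(ecpg_distances, all_cpg_distances)) < min(bins) ||
      max(c(ecpg_distances, all_cpg_distances)) >= max(bins)) {
    abort("bins must cover all observations")
  }
  cut_e <- cut(ecpg_distances, bins, right = FALSE)
  cut_a <- cut(all_cpg_distances, bins, right = FALSE)
  n_e <- as.integer(table(cut_e))
  n_a <- as.integer(table(cut_a))
  tibble(
    bin_lo = bins[-length(bins)],
    bin_hi = bins[-1],
    n_ecpg = n_e,
    n_cpg = n_a,
    ratio = ifelse(n_a == 0, NA_real_,
                   (n_e / sum(n_e)) / (n_a / sum(n_a)))
  )
}

#' Find eCpGs regulating overlapping gene pairs
#'
#' Returns every CpG that is significantly associated with two genes at once,
#' sitting in the promoter of one and the gene body of the other -- the
#' configuration where a single methylation change can show opposite-signed
#' correlations with two overlapping transcripts.
#'
#' @param classified Classified significant records: columns `cpg_id`,
#'   `gene_id`, `detailed`, and `sign` (correlation direction, `"+"`/`"-"`).
#' @return Tibble with one row per qualifying CpG and gene pair: `cpg_id`,
#'   `gene_promoter`, `gene_body`, `sign_promoter`, `sign_body`.
#' @export
find_overlapping_gene_pairs <- function(classified) {
  classified <- as_tibble(classified)
  stopifnot(all(c("cpg_id", "gene_id", "detailed", "sign") %in% names(classified)))
  prom <- filter(classified, .data$detailed == "near_promoter")
  body <- filter(classified, .data$detailed == "in_gene_body")
  out <- dplyr::inner_join(
    select(prom, "cpg_id", gene_promoter = "gene_id", sign_promoter = "sign"),
    select(body, "cpg_id", gene_body = "gene_id", sign_body = "sign"),
    by = "cpg_id", relationship = "many-to-many"
  )
  filter(out, .data$gene_promoter != .data$gene_body)
}

#' Choose the genomic location of a multi-mapping expression probe
#'
#' Expression probes can anneal to several genomic locations. For a given
#' eCpG, the probe location is chosen by: keeping candidates annotatable to a
#' gene whenever any exist, then taking the same-chromosome candidate closest
#' to the CpG (different-chromosome candidates rank last), breaking ties by
#' match rank (`primary` < `secondary` < `other`), then by lowest start.
#'
#' @param candidates Tibble of candidate locations: `chrom`, `start`, `end`,
#'   `match_rank` (one of `"primary"`, `"secondary"`, `"other"`), `gene_id`
#'   (NA when the location cannot be annotated to a gene).
#' @param cpg List or one-row data frame with `chrom`, `pos`.
#' @return The chosen candidate row (one-row tibble).
#' @export
resolve_probe_location <- function(candidates, cpg) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) abort("probe has no candidate locations")
  stopifnot(all(candidates$match_rank %in% c("primary", "secondary", "other")))
  annot <- filter(candidates, !is.na(.data$gene_id))
  pool <- if (nrow(annot) > 0) annot else candidates
  pool %>%
    mutate(
      .dist = ifelse(.data$chrom == cpg$chrom,
                     .span_distance(cpg$pos, .data$start, .data$end), Inf),
      .rank = match(.data$match_rank, c("primary", "secondary", "other"))
    ) %>%
    arrange(.data$.dist, .data$.rank, .data$start) %>%
    slice(1) %>%
    select(-".dist", -".rank")
}

#' Map CpGs to genes for term enrichment
#'
#' Intragenic CpGs take the host gene; intergenic CpGs are assigned the gene
#' with the closest downstream TSS (the nearest TSS the CpG lies 5' of,
#' strand-aware), falling back to the nearest TSS outright when no gene lies
#' downstream on the chromosome.
#'
#' @param cpgs CpG tibble (`cpg_id`, `chrom`, `pos`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `start`, `end`).
#' @return `cpgs` with a `gene_id` column (NA when the chromosome has no
#'   genes).
#' @export
assign_cpg_genes <- function(cpgs, genes) {
  cpgs <- as_tibble(cpgs)
  genes <- as_tibble(genes)
  geom <- .gene_geometry(genes)
  out <- pmap(list(cpgs$chrom, cpgs$pos), function(chrom, pos) {
    same <- genes$chrom == chrom
    if (!any(same)) return(NA_character_)
    inside <- same & pos >= genes$start & pos < genes$end
    if (any(inside)) {
      d0 <- .span_distance(pos, genes$start, genes$end)
      return(genes$gene_id[which(inside)[which.min(d0[inside])]])
    }
    d_tss <- abs(geom$tss - pos)
    downstream <- same & ifelse(geom$fwd, pos <= geom$tss, pos >= geom$tss)
    pool <- if (any(downstream)) downstream else same
    genes$gene_id[which(pool)[which.min(d_tss[pool])]]
  })
  mutate(cpgs, gene_id = unlist(out))
}
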