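#' Generate a toy genome for end-to-end testing
#'
#' Builds a small multi-chromosome genome whose gene layout deliberately
#' instantiates every positional eCpG-transcript configuration the classifier
#' distinguishes. The first three genes of each chromosome follow a fixed
#' template (two nearby same-strand genes, one long far minus-strand gene on
#' chromosome 1; a nested gene pair plus one isolated gene on chromosome 2);
#' further genes are appended with alternating strands. A deterministic set
#' of "targeted" CpGs is placed in the promoter, first exon, intron, last
#' exon, near flank and far flank of the template genes, and `cpg_density`
#' background CpGs per kb are scattered uniformly.
#'
#' All coordinates are 0-based, half-open; a CpG is the point coordinate of
#' its C. TSS/TES are reported as BED-style boundary coordinates
#' (TSS = start for + strand genes, = end for - strand genes).
#'
#' @param n_chrom Number of chromosomes (>= 2, so trans pairs exist).
#' @param genes_per_chrom Genes per chromosome (>= 1; the full category
#'   coverage guarantee needs >= 3).
#' @param cpg_density Background CpG density in sites per kb.
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   genome.
#' @param chrom_length Optional chromosome length in bp; the default sizes
#'   each chromosome to fit the requested genes. An explicit length too short
#'   for the layout is an error.
#' @return A `toy_genome` object: list of tibbles `chromosomes` (`chrom`,
#'   `length`), `genes` (`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `tes`), `exons` (`gene_id`, `exon`, `start`, `end`; `exon` numbers in
#'   transcription order) and `cpgs` (`cpg_id`, `chrom`, `pos`).
#' @examples
#' genome <- generate_genome(2, 3, 1, seed = 1)
#' genome$genes
#' @export
generate_genome <- function(n_chrom, genes_per_chrom, cpg_density, seed,
                            chrom_length = NULL) {
  if (n_chrom < 2) {
    abort("n_chrom must be >= 2: trans pairs are impossible on a single chromosome")
  }
  stopifnot(genes_per_chrom >= 1, cpg_density > 0)
  withr::local_seed(seed)

  needed <- 300000 + max(0, genes_per_chrom - 3) * 30000
  L <- chrom_length %||% needed
  if (L < needed) {
    abort(sprintf(
      "chromosome length %d too short to host %d genes (need >= %d bp)",
      L, genes_per_chrom, needed
    ))
  }

  chroms <- paste0("chr", seq_len(n_chrom))
  genome <- list(
    chromosomes = tibble(chrom = chroms, length = as.integer(L)),
    genes = NULL, exons = NULL, cpgs = NULL
  )

  genes <- list()
  exons <- list()
  for (ci in seq_len(n_chrom)) {
    layout <- .template_layout(chroms[ci], ci, genes_per_chrom, L)
    genes[[ci]] <- layout$genes
    exons[[ci]] <- layout$exons
  }
  genes <- list_rbind(genes)
  exons <- list_rbind(exons)

  cpgs <- list()
  for (ci in seq_len(n_chrom)) {
    targeted <- .targeted_cpgs(filter(genes, .data$chrom == chroms[ci]), ci)
    n_bg <- round(L / 1000 * cpg_density)
    bg <- sample.int(L, size = min(n_bg, L), replace = FALSE) - 1L
    pos <- sort(unique(c(targeted, bg)))
    cpgs[[ci]] <- tibble(chrom = chroms[ci], pos = as.integer(pos))
  }
  cpgs <- list_rbind(cpgs)
  cpgs$cpg_id <- sprintf("cg%06d", seq_len(nrow(cpgs)))
  cpgs <- select(cpgs, "cpg_id", "chrom", "pos")

  genome$genes <- .derive_tss_tes(genes)
  genome$exons <- exons
  genome$cpgs <- cpgs
  validate_toy_genome(structure(genome, class = "toy_genome"))
}

# fixed per-chromosome gene templates; chromosome index alternates the two
# layouts so both appear whenever n_chrom >= 2
.template_layout <- function(chrom, ci, n_genes, L) {
  if (ci %% 2 == 1) {
    template <- tibble(
      start = c(50000L, 67000L, 140000L),
      end = c(62000L, 75000L, 290000L),
      strand = c("+", "+", "-")
    )
  } else {
    template <- tibble(
      start = c(100000L, 140000L, 260000L),
      end = c(200000L, 160000L, 272000L),
      strand = c("+", "+", "-")
    )
  }
  template <- head(template, n_genes)
  extra <- n_genes - nrow(template)
  if (extra > 0) {
    starts <- 300000L + (seq_len(extra) - 1L) * 30000L
    template <- bind_rows(template, tibble(
      start = starts,
      end = starts + 8000L,
      strand = rep(c("+", "-"), length.out = extra)
    ))
  }
  template$chrom <- chrom
  template$gene_id <- sprintf("gene_%s_%d", chrom, seq_len(nrow(template)))
  ex <- pmap(template, function(start, end, strand, chrom, gene_id) {
    .make_exons(gene_id, start, end, strand)
  })
  list(
    genes = select(template, "gene_id", "chrom", "strand", "start", "end"),
    exons = list_rbind(ex)
  )
}

# three exons at fixed fractions of the span, numbered in transcription order
.make_exons <- function(gene_id, start, end, strand) {
  len <- end - start
  if (len < 600) {
    ex <- tibble(start = start, end = end)
  } else {
    # first exon covers 30% of the span so gene-body CpGs can fall in it
    # beyond the 2.5 kb promoter window of template-sized genes
    ex_start <- as.integer(c(start, start + floor(0.45 * len), start + floor(0.8 * len)))
    ex_end <- as.integer(c(start + floor(0.3 * len), start + floor(0.6 * len), end))
    ex <- tibble(start = ex_start, end = ex_end)
  }
  ex$gene_id <- gene_id
  ex$exon <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  arrange(select(ex, "gene_id", "exon", "start", "end"), .data$exon)
}

.derive_tss_tes <- function(genes) {
  mutate(genes,
    tss = ifelse(.data$strand == "+", .data$start, .data$end),
    tes = ifelse(.data$strand == "+", .data$end, .data$start)
  )
}

# deterministic CpGs guaranteeing promoter / body / exon / intron / flank
# coverage for the first template gene, plus the engineered single-category
# configurations between template genes
.targeted_cpgs <- function(genes, ci) {
  g1 <- genes[1, ]
  out <- integer(0)
  pr <- if (g1$strand == "+") g1$start - 1000L else g1$end + 1000L
  out <- c(out, pr)                       # promoter, 1 kb upstream
  ex <- .make_exons(g1$gene_id, g1$start, g1$end, g1$strand)
  ex <- arrange(ex, .data$start)
  out <- c(out, g1$start + 3000L)         # first exon, past the promoter window
  out <- c(out, ex$end[nrow(ex)] - 500L)  # last exon
  if (nrow(ex) > 1) out <- c(out, ex$end[1] + 500L) # intron
  out <- c(out, g1$start - 30000L)        # near flank (< 50 kb)
  out <- c(out, max(g1$end + 60000L, 0L)) # far flank on same chromosome
  if (ci %% 2 == 1) {
    # chr1-style layout: closest-upstream, closer-5', closer-3', multiple
    out <- c(out, 64000L, 65000L, 124000L, 70000L, 20000L)
  } else {
    # chr2-style layout: gene-between (single), in-different-gene (single)
    out <- c(out, 95000L, 121000L, 150500L)
  }
  sort(unique(out[out >= 0]))
}

validate_toy_genome <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  g <- genome$genes
  if (any(g$start < 0 | g$end > lens[g$chrom] | g$start >= g$end)) {
    abort("gene spans must lie within chromosome bounds")
  }
  ex <- left_join(genome$exons, g, by = "gene_id", suffix = c("", ".gene"))
  if (any(ex$start < ex$start.gene | ex$end > ex$end.gene)) {
    abort("exons must be nested within their gene span")
  }
  if (any(duplicated(genome$cpgs[c("chrom", "pos")]))) {
    abort("CpG positions must be unique per chromosome")
  }
  if (any(genome$cpgs$pos < 0 | genome$cpgs$pos >= lens[genome$cpgs$chrom])) {
    abort("CpG positions must lie within chromosome bounds")
  }
  genome
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf(
    "<toy_genome> %d chromosome(s), %d genes, %d CpGs\n",
    nrow(x$chromosomes), nrow(x$genes), nrow(x$cpgs)
  ))
  invisible(x)
}

#' Mirror a toy genome
#'
#' Reflects every coordinate (`pos -> length - 1 - pos`, intervals
#' `[s, e) -> [L - e, L - s)`) and flips all strands. Classification is
#' coordinate-system agnostic, so every eCpG-transcript category must be
#' invariant under this transformation; the mirrored genome is used to assert
#' that property.
#'
#' @param genome A `toy_genome`.
#' @return The mirrored `toy_genome`.
#' @export
mirror_genome <- function(genome) {
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  g <- genome$genes
  genes <- mutate(g,
    start = as.integer(lens[.data$chrom] - g$end),
    end = as.integer(lens[.data$chrom] - g$start),
    strand = ifelse(.data$strand == "+", "-", "+")
  )
  genes <- .derive_tss_tes(select(genes, "gene_id", "chrom", "strand", "start", "end"))
  ex <- left_join(genome$exons, select(g, "gene_id", "chrom"), by = "gene_id")
  exons <- ex %>%
    mutate(
      new_start = as.integer(lens[.data$chrom] - .data$end),
      new_end = as.integer(lens[.data$chrom] - .data$start)
    ) %>%
    group_by(.data$gene_id) %>%
    mutate(exon = rank(-.data$exon)) %>%
    ungroup() %>%
    transmute(
      gene_id = .data$gene_id, exon = as.integer(.data$exon),
      start = .data$new_start, end = .data$new_end
    ) %>%
    arrange(.data$gene_id, .data$exon)
  cpgs <- mutate(genome$cpgs, pos = as.integer(lens[.data$chrom] - 1L - .data$pos))
  validate_toy_genome(structure(
    list(
      chromosomes = genome$chromosomes,
      genes = genes, exons = exons, cpgs = cpgs
    ),
    class = "toy_genome"
  ))
}
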