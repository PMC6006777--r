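test_that("pair classification matches the hand-labelled fixtures", {
  g <- fixture_genome()
  for (i in seq_len(nrow(hand_labels()))) {
    row <- hand_labels()[i, ]
    cls <- classify_pair(
      list(chrom = row$chrom, pos = row$pos),
      fixture_gene(g, row$gene), g$genes
    )
    expect_equal(as.character(cls$detailed), row$detailed, info = paste(row$chrom, row$pos, row$gene))
    expect_equal(cls$canonical, row$canonical)
  }
})

test_that("broad categories follow the chromosome and 50 kb rules", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          start = 10000L, end = 20000L)
  cls <- function(chrom, pos) classify_pair(list(chrom = chrom, pos = pos), genes[1, ], genes)
  p <- cls("chr1", 9000L)
  expect_equal(as.character(p$detailed), "near_promoter")
  expect_equal(p$signed_distance, -1000L)
  body <- cls("chr1", 15000L)
  expect_equal(as.character(body$detailed), "in_gene_body")
  expect_equal(body$signed_distance, 0L)
  expect_equal(as.character(cls("chr2", 15000L)$broad), "trans")
  far <- cls("chr1", 75000L)
  expect_equal(as.character(far$broad), "distal")
  expect_gt(far$signed_distance, 50000)
  near <- cls("chr1", 69000L)
  expect_equal(as.character(near$broad), "cis")
  expect_error(classify_pair(list(chrom = "chr1", pos = 1L),
                             tibble::tibble(gene_id = "bad", chrom = "chr1",
                                            strand = "+", start = 5L, end = 5L),
                             genes), "malformed")
})

test_that("classification is strand-aware at the promoter boundary", {
  genes <- tibble::tibble(gene_id = "m1", chrom = "chr1", strand = "-",
                          start = 10000L, end = 20000L)
  # TSS of a minus-strand gene sits at the high-coordinate end
  up <- classify_pair(list(chrom = "chr1", pos = 21000L), genes[1, ], genes)
  expect_equal(as.character(up$detailed), "near_promoter")
  expect_equal(up$signed_distance, -1001L)
  down <- classify_pair(list(chrom = "chr1", pos = 9000L), genes[1, ], genes)
  expect_equal(as.character(down$detailed), "closest_upstream_gene")
  body <- classify_pair(list(chrom = "chr1", pos = 12000L), genes[1, ], genes)
  expect_equal(as.character(body$detailed), "in_gene_body")
})

test_that("cis categories are exhaustive, exclusive and mirror-invariant", {
  g <- fixture_genome(seed = 2)
  pairs <- tidyr::crossing(cpg_id = g$cpgs$cpg_id, gene_id = g$genes$gene_id)
  recs <- tibble::tibble(cpg_id = pairs$cpg_id,
                         transcript_id = paste0("tx_", pairs$gene_id))
  cls <- classify_associations(recs, g)
  expect_false(anyNA(cls$detailed))
  expect_true(all(cls$canonical == (cls$detailed %in% c(
    "near_promoter", "in_gene_body", "closest_upstream_gene", "closest_downstream_gene"
  ))))
  expect_true(all(cls$broad[cls$canonical] == "cis"))
  expect_true(all((cls$detailed == "trans") == (cls$broad == "trans")))
  expect_true(all((cls$detailed == "distal") == (cls$broad == "distal")))
  # signed distance is zero exactly for CpGs inside the gene span
  inside <- cls$detailed %in% c("in_gene_body", "near_promoter")
  expect_true(all(cls$signed_distance[cls$detailed == "in_gene_body"] == 0))
  expect_true(all(cls$signed_distance[!inside & cls$broad != "trans"] != 0))

  mirrored <- classify_associations(recs, mirror_genome(g))
  expect_identical(as.character(cls$detailed), as.character(mirrored$detailed))
  expect_identical(cls$signed_distance, mirrored$signed_distance)
})

test_that("gene-body subcategories respect exon structure and strand", {
  exons <- tibble::tibble(
    gene_id = "g1", exon = 1:3,
    start = c(10000L, 14000L, 18000L), end = c(11000L, 15000L, 20000L)
  )
  gene <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                         start = 10000L, end = 20000L)
  in_first <- genebody_subcategory(list(chrom = "chr1", pos = 13000L), gene, exons)
  expect_false(in_first$exonic) # 13000 is between exons
  expect_true(in_first$intronic)
  ex1 <- genebody_subcategory(list(chrom = "chr1", pos = 14500L), gene, exons)
  expect_true(ex1$exonic)
  expect_false(ex1$first_exon)
  last <- genebody_subcategory(list(chrom = "chr1", pos = 19000L), gene, exons)
  expect_true(last$last_exon)

  # minus strand: the highest-coordinate exon is the first exon (using a
  # longer gene so its first exon clears the promoter window)
  gene_m <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "-",
                           start = 10000L, end = 30000L)
  exons_m <- tibble::tibble(
    gene_id = "g1", exon = c(3L, 2L, 1L),
    start = c(10000L, 14000L, 25000L), end = c(11000L, 15000L, 30000L)
  )
  first_m <- genebody_subcategory(list(chrom = "chr1", pos = 26000L), gene_m, exons_m)
  expect_true(first_m$first_exon)
  expect_false(first_m$last_exon)
  last_m <- genebody_subcategory(list(chrom = "chr1", pos = 10500L), gene_m, exons_m)
  expect_true(last_m$last_exon)

  expect_error(
    genebody_subcategory(list(chrom = "chr1", pos = 9000L), gene, exons),
    "gene body"
  )
})

test_that("relative proportions compare eCpG and array distance profiles", {
  rp <- relative_proportion_by_distance(
    c(100, 100, 5000, 9000), c(rep(100, 10), rep(5000, 90)), c(0, 1000, 10000)
  )
  expect_equal(rp$ratio[1], (2 / 4) / (10 / 100))
  same <- relative_proportion_by_distance(c(1, 500, 2000), c(1, 500, 2000),
                                          c(0, 1000, 5000))
  expect_equal(same$ratio, c(1, 1))
  holes <- relative_proportion_by_distance(c(100), c(100), c(0, 1000, 2000))
  expect_true(is.na(holes$ratio[2]))
  expect_error(relative_proportion_by_distance(numeric(0), 1, c(0, 10)), "empty")
})

test_that("overlapping gene pairs are found only when both roles are significant", {
  g <- fixture_genome()
  # chr2 CpG at 150500: inside nested f2 (body) while also inside f1 (body);
  # use a CpG in f2's promoter that is inside f1's body instead
  classified <- tibble::tibble(
    cpg_id = c("x", "x", "y"),
    gene_id = c("gene_chr2_1", "gene_chr2_2", "gene_chr2_1"),
    detailed = c("in_gene_body", "near_promoter", "in_gene_body"),
    sign = c("+", "-", "-")
  )
  hits <- find_overlapping_gene_pairs(classified)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$gene_promoter, "gene_chr2_2")
  expect_equal(hits$gene_body, "gene_chr2_1")
  # drop the promoter record: no hit
  expect_equal(nrow(find_overlapping_gene_pairs(classified[-2, ])), 0)
})

test_that("a promoter CpG of a nested gene classifies as body of the host", {
  g <- fixture_genome()
  # 139000 is within 2500 bp of f2's TSS (140000) and deep inside f1
  host <- classify_pair(list(chrom = "chr2", pos = 139000L),
                        fixture_gene(g, "gene_chr2_1"), g$genes)
  nested <- classify_pair(list(chrom = "chr2", pos = 139000L),
                          fixture_gene(g, "gene_chr2_2"), g$genes)
  expect_equal(as.character(host$detailed), "in_gene_body")
  expect_equal(as.character(nested$detailed), "near_promoter")
})

test_that("probe locations resolve by annotation, proximity then match rank", {
  cpg <- list(chrom = "chr1", pos = 50000L)
  single <- tibble::tibble(chrom = "chr9", start = 1L, end = 100L,
                           match_rank = "other", gene_id = NA_character_)
  expect_equal(resolve_probe_location(single, cpg)$chrom, "chr9")

  two <- tibble::tibble(
    chrom = "chr1", start = c(51000L, 150000L), end = c(51050L, 150050L),
    match_rank = c("secondary", "primary"), gene_id = c("gA", "gB")
  )
  expect_equal(resolve_probe_location(two, cpg)$start, 51000L)

  tied <- tibble::tibble(
    chrom = "chr1", start = c(51000L, 49000L), end = c(51050L, 49050L),
    match_rank = c("secondary", "primary"), gene_id = c("gA", "gB")
  )
  # equal distances (999 bp each side): primary wins
  expect_equal(resolve_probe_location(tied, cpg)$match_rank, "primary")

  mixed <- tibble::tibble(
    chrom = c("chr1", "chr1"), start = c(51000L, 200L), end = c(51050L, 250L),
    match_rank = c("other", "primary"), gene_id = c("gA", NA)
  )
  # annotatable candidates beat unannotatable ones regardless of rank
  expect_equal(resolve_probe_location(mixed, cpg)$gene_id, "gA")
})

test_that("intergenic CpGs map to the closest downstream TSS", {
  genes <- tibble::tibble(
    gene_id = c("left", "right"), chrom = "chr1", strand = c("-", "+"),
    start = c(1000L, 30000L), end = c(5000L, 40000L)
  )
  got <- assign_cpg_genes(
    tibble::tibble(cpg_id = c("a", "b", "c"), chrom = "chr1",
                   pos = c(10000L, 2000L, 29000L)),
    genes
  )
  # a sits between the two genes and is 5' of both (the left gene points
  # away from it): the left TSS at 4999 is the nearer downstream TSS
  expect_equal(got$gene_id, c("left", "left", "right"))
})
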