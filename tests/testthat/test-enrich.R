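test_that("shores and shelves follow the 1.5 kb band definition", {
  cgi <- tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L)
  bands <- build_shores_shelves(cgi)
  expect_equal(bands$shore$start, c(8500L, 11000L))
  expect_equal(bands$shore$end, c(10000L, 12500L))
  expect_equal(bands$shelf$start, c(7000L, 12500L))
  expect_equal(bands$shelf$end, c(8500L, 14000L))
})

test_that("nearby islands share a shore and lose their shelf gap", {
  cgi <- tibble::tibble(chrom = "chr1", start = c(10000L, 13000L),
                        end = c(11000L, 14000L))
  bands <- build_shores_shelves(cgi)
  # the 2 kb inter-island gap is entirely shore
  gap_shore <- bands$shore[bands$shore$start >= 11000 & bands$shore$end <= 13000, ]
  expect_equal(sum(gap_shore$end - gap_shore$start), 2000L)
  expect_false(any(bands$shelf$start >= 11000 & bands$shelf$end <= 13000))
})

test_that("bands clip at chromosome bounds", {
  cgi <- tibble::tibble(chrom = "chr1", start = 500L, end = 1200L)
  bands <- build_shores_shelves(cgi, chrom_lengths = tibble::tibble(chrom = "chr1", length = 2500L))
  expect_true(all(bands$shore$start >= 0))
  expect_true(all(bands$shelf$start >= 0))
  expect_true(all(bands$shelf$end <= 2500))
})

test_that("shore and shelf construction matches a per-bp set oracle", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n_isl <- sample(2:6, 1)
      starts <- sort(sample.int(40000, n_isl))
      cgi <- tibble::tibble(chrom = "c", start = starts,
                            end = starts + sample(200:3000, n_isl, replace = TRUE))
      cgi_m <- merge_intervals(cgi)
      bands <- build_shores_shelves(cgi, chrom_lengths = tibble::tibble(chrom = "c", length = 50000L))
      len <- 50000L
      in_cgi <- track_mask(cgi_m, "c", len)
      grown1 <- track_mask(dplyr::mutate(cgi_m, start = pmax(start - 1500L, 0L), end = end + 1500L), "c", len)
      grown2 <- track_mask(dplyr::mutate(cgi_m, start = pmax(start - 3000L, 0L), end = end + 3000L), "c", len)
      expect_identical(track_mask(bands$shore, "c", len), grown1 & !in_cgi)
      expect_identical(track_mask(bands$shelf, "c", len), grown2 & !grown1)
      # pairwise disjoint layers
      expect_false(any(track_mask(bands$shore, "c", len) & in_cgi))
      expect_false(any(track_mask(bands$shelf, "c", len) & track_mask(bands$shore, "c", len)))
    }
  })
})

test_that("CpG annotation is half-open: start in, end out", {
  tracks <- list(
    cgi = tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L),
    shore = tibble::tibble(chrom = "chr1", start = 8500L, end = 10000L)
  )
  cpgs <- tibble::tibble(cpg_id = c("a", "b", "c"), chrom = "chr1",
                         pos = c(8600L, 10000L, 11000L))
  ann <- annotate_cpgs(cpgs, tracks)
  expect_equal(ann$shore, c(TRUE, FALSE, FALSE))
  expect_equal(ann$cgi, c(FALSE, TRUE, FALSE))
  expect_warning(
    annotate_cpgs(dplyr::mutate(cpgs, chrom = c("chr1", "chrX", "chr1")), tracks,
                  chrom_lengths = tibble::tibble(chrom = "chr1", length = 1e6)),
    "unknown"
  )
})

test_that("Fisher enrichment reproduces enumeration and cross-product arithmetic", {
  res <- fisher_enrichment(2, 0, 0, 2)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(res$zero_cell)

  or <- fisher_enrichment(10, 90, 10, 890)
  expect_equal(or$odds_ratio, 9.888889, tolerance = 1e-6)
  expect_true(or$ci_low <= or$odds_ratio & or$odds_ratio <= or$ci_high)

  flat <- fisher_enrichment(5, 5, 5, 5)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  expect_error(fisher_enrichment(0, 0, 0, 0), "all-zero")
})

test_that("row swap inverts the odds ratio and preserves the p-value", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      tab <- sample.int(15, 4, replace = TRUE)
      f1 <- fisher_enrichment(tab[1], tab[2], tab[3], tab[4])
      f2 <- fisher_enrichment(tab[3], tab[4], tab[1], tab[2])
      expect_equal(f1$odds_ratio, 1 / f2$odds_ratio, tolerance = 1e-12)
      expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
    }
  })
})

test_that("intermediate methylation uses an inclusive 0.2-0.8 band", {
  mean_beta <- c(0.2, 0.8, 0.19, 0.81, 0.5, 0.05)
  is_ecpg <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  res <- intermediate_methylation_enrichment(mean_beta, is_ecpg)
  expect_equal(res$a, 3) # all three eCpGs are intermediate (boundaries in)
  expect_equal(res$c, 0)
  expect_true(res$zero_cell)
  expect_gt(res$odds_ratio, 1)
})

test_that("planted mid-range eCpGs show intermediate-methylation enrichment", {
  genome <- generate_genome(2, 10, 1, seed = 41)
  cohort <- generate_cohort(genome, n_samples = 100, n_confounders = 0,
                            bimodal_fraction = 0.8, seed = 42)
  mb <- colMeans(cohort$methylation)
  # treat the mid-beta CpGs as the "significant" set plus noise
  withr::with_seed(43, {
    is_ecpg <- (mb > 0.25 & mb < 0.75 & runif(length(mb)) < 0.5) |
      runif(length(mb)) < 0.02
  })
  res <- intermediate_methylation_enrichment(mb, is_ecpg)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.05)
})

test_that("gene-body sign enrichment reports per-region fractions and ORs", {
  recs <- tibble::tibble(
    cpg_id = sprintf("cg%02d", 1:10),
    chrom = "chr1",
    pos = c(1:7 * 100L, 7500L, 8500L, 9500L),
    sign = c(rep("-", 7), rep("+", 3)),
    exonic = c(rep(TRUE, 7), rep(TRUE, 3)),
    intronic = FALSE,
    first_exon = c(rep(TRUE, 7), rep(TRUE, 3)),
    last_exon = FALSE
  )
  tracks <- list(enhancer = tibble::tibble(chrom = "chr1", start = 0L, end = 750L))
  out <- genebody_sign_enrichment(recs, tracks)
  expect_equal(out$sign_fractions$frac_negative[out$sign_fractions$region == "first_exon"], 0.7)
  enh <- out$enrichment[out$enrichment$track == "enhancer", ]
  expect_gt(enh$odds_ratio, 1) # negatives all in the enhancer, positives out
  expect_error(genebody_sign_enrichment(recs[0, ], tracks), "no gene-body")
})

test_that("sign-track independence yields uniform Fisher p-values", {
  withr::with_seed(51, {
    pvals <- vapply(1:300, function(i) {
      n <- 60
      sign <- sample(c("+", "-"), n, replace = TRUE)
      inside <- sample(c(TRUE, FALSE), n, replace = TRUE)
      fisher_enrichment(
        sum(sign == "-" & inside), sum(sign == "-" & !inside),
        sum(sign == "+" & inside), sum(sign == "+" & !inside)
      )$p_value
    }, numeric(1))
    expect_gt(mean(pvals < 0.05), 0.01)
    expect_lt(mean(pvals < 0.05), 0.08)
    expect_gt(mean(pvals), 0.4)
  })
})

test_that("term enrichment matches combinatorial enumeration and BH", {
  res <- term_enrichment(
    selected = paste0("g", 1:4),
    universe = paste0("g", 1:10),
    term_map = tibble::tibble(term_id = "t1", gene_id = paste0("g", 1:5))
  )
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  all_term <- term_enrichment(
    selected = paste0("g", 1:3),
    universe = paste0("g", 1:10),
    term_map = tibble::tibble(term_id = "t1", gene_id = paste0("g", 1:10))
  )
  expect_equal(all_term$p_value, 1)

  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  multi <- term_enrichment(
    selected = paste0("g", 1:4),
    universe = paste0("g", 1:20),
    term_map = tibble::tibble(
      term_id = rep(c("t1", "t2", "t3"), times = c(5, 8, 3)),
      gene_id = c(paste0("g", 1:5), paste0("g", 6:13), paste0("g", c(1, 2, 14)))
    )
  )
  expect_true(all(multi$fdr >= multi$p_value))
  expect_true(all(diff(multi$fdr) >= -1e-12)) # sorted by p: FDR monotone
  expect_error(term_enrichment(character(0), "g1",
                               tibble::tibble(term_id = "t", gene_id = "g1")),
               "empty")
})

test_that("ChromHMM state groups parse from track names", {
  bed <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L, 300L), end = c(50L, 150L, 250L, 350L),
    name = c("1_Active_Promoter", "4_Strong_Enhancer", "7_Weak_Enhancer", "8_Insulator")
  )
  prom <- chromhmm_state_track(bed, 1:3)
  expect_equal(nrow(prom), 1)
  enh <- chromhmm_state_track(bed, 4:7)
  expect_equal(nrow(enh), 2)
  expect_error(chromhmm_state_track(dplyr::mutate(bed, name = "oops"), 1:3),
               "state number")
})
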