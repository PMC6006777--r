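test_that("pair matching counts exact key agreement per category", {
  st <- make_pair_studies(n_pairs = 40, shared_frac = 1, seed = 1)
  full <- match_pairs(st$a, st$b)
  expect_true(all(full$overlap == 1))

  disjoint <- make_pair_studies(n_pairs = 40, shared_frac = 0, seed = 2)
  none <- match_pairs(disjoint$a, disjoint$b)
  expect_true(all(none$overlap == 0))

  a <- tibble::tibble(
    cpg_id = paste0("cg", 1:4), probe_id = paste0("p", 1:4),
    chrom = "chr1", start = 1:4 * 100L, end = 1:4 * 100L + 50L,
    sign = "+", category = "cis"
  )
  b <- a
  b$sign[4] <- "-"
  got <- match_pairs(a, b)
  expect_equal(got$overlap, 0.75)
})

test_that("the permutation null is seeded and reproducible", {
  st <- make_pair_studies(n_pairs = 60, shared_frac = 0.5, seed = 3)
  n1 <- permutation_null(st$a, st$b, n_perm = 20, seed = 42)
  n2 <- permutation_null(st$a, st$b, n_perm = 20, seed = 42)
  expect_identical(tibble::as_tibble(n1), tibble::as_tibble(n2))
  n3 <- permutation_null(st$a, st$b, n_perm = 20, seed = 43)
  expect_false(identical(tibble::as_tibble(n1), tibble::as_tibble(n3)))
})

test_that("degenerate permutation cases behave as enumeration predicts", {
  a <- tibble::tibble(
    cpg_id = c("cg1", "cg2"), probe_id = "p1", chrom = "chr1",
    start = 100L, end = 150L, sign = "+", category = "cis"
  )
  empty <- a[0, ]
  null_empty <- permutation_null(a, empty, n_perm = 5, seed = 1)
  expect_true(all(null_empty$overlap == 0))
  # a single shared probe id: shuffling is the identity, overlap is invariant
  null_single <- permutation_null(a, a, n_perm = 5, seed = 1)
  expect_true(all(null_single$overlap == 1))
})

test_that("true sharing exceeds the permutation null's tail", {
  st <- make_pair_studies(n_pairs = 200, shared_frac = 0.5, seed = 5)
  null <- permutation_null(st$a, st$b, n_perm = 200, seed = 6)
  obs <- attr(null, "observed")
  for (cat in obs$category) {
    q99 <- stats::quantile(null$overlap[null$category == cat], 0.99)
    expect_gt(obs$overlap[obs$category == cat], q99)
  }
})

test_that("neighbor congruence follows the window arithmetic of small fixtures", {
  two <- tibble::tibble(
    cpg_id = c("a", "b"), chrom = "chr1", pos = c(1000L, 1300L),
    gene_id = "g1", sign = "+"
  )
  got <- neighbor_congruence(two, windows = c(100, 500))
  expect_equal(got$n_with_neighbor, c(0L, 2L))
  expect_equal(got$frac_share_gene[2], 1)
  expect_equal(got$frac_share_gene_and_sign[2], 1)
  expect_equal(got$frac_all_congruent[2], 1)

  flipped <- dplyr::mutate(two, sign = c("+", "-"))
  got2 <- neighbor_congruence(flipped, windows = 500)
  expect_equal(got2$frac_share_gene, 1)
  expect_equal(got2$frac_share_gene_and_sign, 0)

  # boundary distance is inclusive
  expect_equal(neighbor_congruence(two, windows = 300)$n_with_neighbor, 2L)

  three <- tibble::tibble(
    cpg_id = c("a", "b", "c"), chrom = "chr1", pos = c(1000L, 1200L, 1400L),
    gene_id = c("g1", "g1", "g2"), sign = "+"
  )
  got3 <- neighbor_congruence(three, windows = 500, detail = TRUE)
  pq <- attr(got3, "per_query")
  a_row <- pq[pq$cpg_id == "a", ]
  expect_true(a_row$shares_gene_sign)
  expect_false(a_row$all_congruent)
  expect_equal(got3$frac_share_gene, 2 / 3)
})

test_that("congruence fractions nest for arbitrary random data", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      ec <- tibble::tibble(
        cpg_id = paste0("cg", 1:40),
        chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
        pos = sample.int(5000, 40),
        gene_id = sample(paste0("g", 1:5), 40, replace = TRUE),
        sign = sample(c("+", "-"), 40, replace = TRUE)
      )
      got <- neighbor_congruence(ec, windows = c(100, 500, 1000, 2000))
      with_nb <- got$n_with_neighbor > 0
      expect_true(all(
        got$frac_all_congruent[with_nb] <= got$frac_share_gene_and_sign[with_nb] + 1e-12
      ))
      expect_true(all(
        got$frac_share_gene_and_sign[with_nb] <= got$frac_share_gene[with_nb] + 1e-12
      ))
    }
  })
})

test_that("full congruence cannot recover as windows widen", {
  withr::with_seed(10, {
    for (rep in 1:5) {
      ec <- tibble::tibble(
        cpg_id = paste0("cg", 1:30),
        chrom = "chr1",
        pos = sample.int(3000, 30),
        gene_id = sample(paste0("g", 1:4), 30, replace = TRUE),
        sign = sample(c("+", "-"), 30, replace = TRUE)
      )
      windows <- c(200, 500, 1000, 2000)
      got <- neighbor_congruence(ec, windows = windows, detail = TRUE)
      pq <- attr(got, "per_query")
      seed_set <- pq$cpg_id[pq$window == windows[1] & pq$has_neighbor]
      if (length(seed_set) == 0) next
      fractions <- vapply(windows, function(w) {
        sub <- pq[pq$window == w & pq$cpg_id %in% seed_set, ]
        mean(sub$all_congruent)
      }, numeric(1))
      expect_true(all(diff(fractions) <= 1e-12))
    }
  })
})
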