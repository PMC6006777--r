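# shared fixtures: the template toy genome doubles as the hand-labelled
# classification fixture (its first three genes per chromosome are laid out
# deterministically)

fixture_genome <- function(seed = 2) {
  generate_genome(2, 3, 1, seed = seed)
}

fixture_gene <- function(genome, gene_id) {
  genome$genes[genome$genes$gene_id == gene_id, ]
}

# the fixture genome's engineered coordinates, hand-labelled:
#   chr1: g1 + [50000,62000), g2 + [67000,75000), g3 - [140000,290000)
#   chr2: f1 + [100000,200000), f2 + [140000,160000) nested, f3 - [260000,272000)
hand_labels <- function() {
  tibble::tribble(
    ~chrom, ~pos,    ~gene,          ~detailed,                 ~canonical,
    "chr1", 49000L,  "gene_chr1_1", "near_promoter",            TRUE,
    "chr1", 55000L,  "gene_chr1_1", "in_gene_body",             TRUE,
    "chr1", 20000L,  "gene_chr1_1", "closest_downstream_gene",  TRUE,
    "chr1", 64000L,  "gene_chr1_1", "closest_upstream_gene",    TRUE,
    "chr1", 65000L,  "gene_chr1_1", "closer_5prime",            FALSE,
    "chr1", 124000L, "gene_chr1_2", "closer_3prime",            FALSE,
    "chr1", 70000L,  "gene_chr1_1", "multiple_closer_between",  FALSE,
    "chr2", 95000L,  "gene_chr2_2", "gene_between",             FALSE,
    "chr2", 121000L, "gene_chr2_2", "in_different_gene",        FALSE,
    "chr1", 20000L,  "gene_chr1_3", "distal",                   FALSE,
    "chr2", 95000L,  "gene_chr1_1", "trans",                    FALSE
  )
}

# independent OLS oracle via lm(): returns effect, T and p for the
# methylation term of y ~ covariates + M
ols_oracle <- function(y, M, X_noint) {
  fit <- stats::lm(y ~ . + M, data = as.data.frame(cbind(X_noint, M = M)))
  s <- summary(fit)$coefficients["M", ]
  list(effect = unname(s[1]), T = unname(s[3]), p = unname(s[4]))
}

# small pure-null cohort with more transcripts than samples
null_cohort <- function(n_samples = 60, genes_per_chrom = 20, seed = 1,
                        cpg_density = 0.25) {
  genome <- generate_genome(2, genes_per_chrom, cpg_density, seed = seed)
  cohort <- generate_cohort(genome, n_samples = n_samples, n_confounders = 0,
                            seed = seed + 1000L)
  list(genome = genome, cohort = cohort)
}

# two eCpG pair-key studies sharing a controlled fraction of pairs
make_pair_studies <- function(n_pairs = 200, shared_frac = 0.5, seed = 7) {
  withr::with_seed(seed, {
    pool_probe <- sprintf("pr%03d", 1:50)
    pool_cpg <- sprintf("cg%04d", 1:400)
    mk <- function(n, cpgs) {
      tibble::tibble(
        cpg_id = sample(cpgs, n),
        probe_id = sample(pool_probe, n, replace = TRUE),
        sign = sample(c("+", "-"), n, replace = TRUE),
        category = sample(c("cis", "distal", "trans"), n, replace = TRUE)
      ) |>
        dplyr::mutate(
          chrom = "chr1",
          start = match(probe_id, pool_probe) * 1000L,
          end = start + 50L
        )
    }
    a <- mk(n_pairs, pool_cpg[1:200])
    b <- mk(n_pairs, pool_cpg[201:400])
    n_shared <- round(shared_frac * n_pairs)
    b[seq_len(n_shared), ] <- a[seq_len(n_shared), ]
    list(a = a, b = b)
  })
}

# brute-force per-bp membership oracle for interval tracks on one chromosome
track_mask <- function(track, chrom, len) {
  mask <- logical(len)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    lo <- max(tr$start[i], 0L)
    hi <- min(tr$end[i], len)
    if (hi > lo) mask[(lo + 1):hi] <- TRUE
  }
  mask
}

# two-sided Fisher p by direct combinatorial enumeration (independent of
# both the package and fisher.test): sum of hypergeometric outcome
# probabilities not exceeding the observed one
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  x <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p_obs <- logp[x == a]
  sum(exp(logp)[exp(logp) <= exp(p_obs) * (1 + 1e-7)])
}
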