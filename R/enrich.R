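#' Fisher's exact enrichment for a 2x2 table
#'
#' Two-sided Fisher exact p-value (hypergeometric enumeration on the raw
#' counts) together with the cross-product odds ratio `ad/bc` and its Wald
#' 95% confidence interval on the log scale. Zero cells get the
#' Haldane-Anscombe +0.5 correction for the odds ratio and CI only; the
#' p-value always uses the raw counts.
#'
#' The table is laid out feature x status:
#' \preformatted{            status+  status-
#'   feature+     a        b
#'   feature-     c        d}
#'
#' @param a,b,c,d Non-negative counts; vectors test one table per element.
#'   `a` may also be a single 2x2 matrix.
#' @param test_design Optional label (`"all_cpgs"` or `"within_significant"`)
#'   recording which of the two enrichment designs produced the table.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return A tibble, one row per table: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `a`, `b`, `c`, `d`, `test_design`, `zero_cell`.
#' @examples
#' fisher_enrichment(10, 90, 10, 890)
#' @export
fisher_enrichment <- function(a, b = NULL, c = NULL, d = NULL,
                              test_design = NA_character_, conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  stopifnot(
    length(b) == length(a), length(c) == length(a), length(d) == length(a),
    all(is.finite(c(a, b, c, d))), all(c(a, b, c, d) >= 0)
  )
  if (any(a + b + c + d == 0)) abort("all-zero contingency table")
  p <- vapply(seq_along(a), function(i) .fisher2x2_p(a[i], b[i], c[i], d[i]),
              numeric(1))
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  ha <- a + 0.5 * zero; hb <- b + 0.5 * zero
  hc <- c + 0.5 * zero; hd <- d + 0.5 * zero
  or <- (ha * hd) / (hb * hc)
  se_log <- sqrt(1 / ha + 1 / hb + 1 / hc + 1 / hd)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se_log),
    ci_high = exp(log(or) + z * se_log),
    p_value = p,
    a = a, b = b, c = c, d = d,
    test_design = test_design,
    zero_cell = zero
  )
}

# two-sided Fisher exact p for one 2x2 table: total probability of outcomes
# no more likely than the observed one, at fixed margins (same tie rule as
# stats::fisher.test, relative slack 1e-7)
.fisher2x2_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  x <- max(0, c1 - (n - r1)):min(r1, c1)
  dens <- dhyper(x, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Intermediate-methylation enrichment among eCpGs
#'
#' eCpGs tend to be intermediately methylated (average beta between 0.2 and
#' 0.8, inclusive): intermediate CpGs are the variable ones, where an
#' association is detectable at all. Tests eCpG status against intermediate
#' status with [fisher_enrichment()] in the all-CpGs design.
#'
#' @param mean_beta Per-CpG average beta values, in \[0, 1\].
#' @param is_ecpg Logical vector: does the CpG reach genome-wide
#'   significance for any transcript?
#' @param lower,upper Intermediate band bounds (inclusive).
#' @return One-row enrichment tibble (see [fisher_enrichment()]) with an
#'   `intermediate` orientation: `odds_ratio > 1` means eCpGs are enriched
#'   for intermediate methylation.
#' @export
intermediate_methylation_enrichment <- function(mean_beta, is_ecpg,
                                                lower = 0.2, upper = 0.8) {
  stopifnot(length(mean_beta) == length(is_ecpg),
            all(mean_beta >= 0 & mean_beta <= 1))
  mid <- mean_beta >= lower & mean_beta <= upper
  fisher_enrichment(
    sum(mid & is_ecpg), sum(!mid & is_ecpg),
    sum(mid & !is_ecpg), sum(!mid & !is_ecpg),
    test_design = "all_cpgs"
  )
}

#' Direction-of-correlation enrichment for gene-body eCpGs
#'
#' Among CpGs inside the body of their associated gene, tests whether
#' negatively correlated eCpGs concentrate in annotated promoter or enhancer
#' intervals (sign x membership Fisher tests, one per track), and reports
#' the fraction of negative correlations per gene-body subregion
#' (whole body, intronic, exonic, first exon, last exon).
#'
#' @param records Gene-body records: `cpg_id`, `chrom`, `pos`, `sign`
#'   (`"+"`/`"-"`), plus logical subregion columns `exonic`, `intronic`,
#'   `first_exon`, `last_exon` (e.g. from [genebody_subcategory()]).
#' @param tracks Named list of annotation tracks (typically `promoter` =
#'   ChromHMM states 1-3 and `enhancer` = states 4-8).
#' @return List with `enrichment` (one row per track; `odds_ratio > 1` means
#'   negative eCpGs are enriched in the track) and `sign_fractions`
#'   (`region`, `n`, `frac_negative`).
#' @export
genebody_sign_enrichment <- function(records, tracks) {
  records <- as_tibble(records)
  need <- c("cpg_id", "chrom", "pos", "sign", "exonic", "intronic", "first_exon", "last_exon")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) == 0) abort("no gene-body records")
  neg <- records$sign == "-"
  ann <- annotate_cpgs(select(records, "cpg_id", "chrom", "pos"), tracks)
  enr <- imap(tracks, function(tr, nm) {
    inside <- ann[[nm]]
    mutate(
      fisher_enrichment(
        sum(neg & inside), sum(neg & !inside),
        sum(!neg & inside), sum(!neg & !inside),
        test_design = "within_significant"
      ),
      track = nm, .before = 1
    )
  }) %>% list_rbind()
  regions <- list(
    gene_body = rep(TRUE, nrow(records)),
    intronic = records$intronic,
    exonic = records$exonic,
    first_exon = records$first_exon,
    last_exon = records$last_exon
  )
  fractions <- imap(regions, function(sel, nm) {
    tibble(region = nm, n = sum(sel), frac_negative = mean(neg[sel]))
  }) %>% list_rbind()
  list(enrichment = enr, sign_fractions = fractions)
}

#' Hypergeometric term enrichment with BH FDR
#'
#' One-sided (upper tail) hypergeometric test of each term's genes among the
#' selected genes, with a cross-product odds ratio and Benjamini-Hochberg
#' false-discovery-rate adjustment across terms. Terms are restricted to the
#' universe before testing.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all eligible gene ids.
#' @param term_map Tibble with columns `term_id`, `gene_id`.
#' @return Tibble per term: `term_id`, `n_term`, `n_overlap`, `odds_ratio`,
#'   `p_value`, `fdr`, sorted by p-value.
#' @examples
#' term_enrichment(
#'   selected = c("g1", "g2"),
#'   universe = paste0("g", 1:10),
#'   term_map = tibble::tibble(term_id = "t1", gene_id = c("g1", "g2", "g3"))
#' )
#' @export
term_enrichment <- function(selected, universe, term_map) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (length(selected) == 0) abort("empty gene selection")
  if (!all(selected %in% universe)) abort("selected genes must be a subset of the universe")
  term_map <- as_tibble(term_map)
  stopifnot(all(c("term_id", "gene_id") %in% names(term_map)))
  term_map <- filter(distinct(term_map), .data$gene_id %in% universe)
  if (nrow(term_map) == 0) abort("no term overlaps the universe")
  N <- length(universe)
  n_sel <- length(selected)
  out <- term_map %>%
    group_by(.data$term_id) %>%
    summarise(
      n_term = dplyr::n(),
      n_overlap = sum(.data$gene_id %in% selected),
      .groups = "drop"
    ) %>%
    mutate(
      p_value = phyper(.data$n_overlap - 1, .data$n_term, N - .data$n_term,
                       n_sel, lower.tail = FALSE),
      odds_ratio = {
        a <- .data$n_overlap
        b <- n_sel - a
        cc <- .data$n_term - a
        dd <- N - .data$n_term - b
        zero <- a == 0 | b == 0 | cc == 0 | dd == 0
        ((a + 0.5 * zero) * (dd + 0.5 * zero)) /
          ((b + 0.5 * zero) * (cc + 0.5 * zero))
      },
      fdr = p.adjust(.data$p_value, method = "BH")
    ) %>%
    arrange(.data$p_value) %>%
    select("term_id", "n_term", "n_overlap", "odds_ratio", "p_value", "fdr")
  out
}
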