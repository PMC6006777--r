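.pair_key_cols <- c("cpg_id", "probe_id", "chrom", "start", "end", "sign")

#' Between-study overlap of eCpG-transcript pairs
#'
#' Fraction of one study's significant pairs found, per broad category, in a
#' second study's significant pairs. A pair matches only when CpG id,
#' expression probe id, resolved probe location (chrom, start, end) and
#' direction of correlation all agree exactly.
#'
#' @param study_a,study_b Pair-key tibbles: columns `cpg_id`, `probe_id`,
#'   `chrom`, `start`, `end`, `sign` (`"+"`/`"-"`), `category` (`cis`,
#'   `distal`, `trans`).
#' @return Tibble per category: `category`, `n`, `n_matched`, `overlap`.
#' @export
match_pairs <- function(study_a, study_b) {
  study_a <- .check_pair_keys(study_a)
  study_b <- .check_pair_keys(study_b)
  key_b <- .pair_key(study_b)
  study_a %>%
    mutate(matched = .pair_key(study_a) %in% key_b) %>%
    group_by(.data$category) %>%
    summarise(
      n = dplyr::n(),
      n_matched = sum(.data$matched),
      overlap = mean(.data$matched),
      .groups = "drop"
    )
}

.check_pair_keys <- function(x) {
  x <- as_tibble(x)
  need <- c(.pair_key_cols, "category")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste("pair keys need columns:", paste(missing, collapse = ", ")))
  }
  if (!all(x$sign %in% c("+", "-"))) abort('sign must be "+" or "-"')
  x
}

.pair_key <- function(x) {
  do.call(paste, c(as.list(x[.pair_key_cols]), sep = "\r"))
}

#' Permutation null for the between-study overlap
#'
#' Recomputes the per-category overlap after randomly permuting the
#' expression probe ids within each (study, category) stratum, `n_perm`
#' times. Sampling is a permutation (without replacement): only the pairing
#' of probes with CpGs is broken, the marginal probe frequencies are kept.
#'
#' @inheritParams match_pairs
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed making the null reproducible.
#' @return Tibble with one row per (permutation, category): `perm`,
#'   `category`, `overlap`. The observed overlap is attached as the
#'   `"observed"` attribute; per-category null maxima as `"max_null"`.
#' @export
permutation_null <- function(study_a, study_b, n_perm, seed) {
  stopifnot(n_perm >= 1)
  study_a <- .check_pair_keys(study_a)
  study_b <- .check_pair_keys(study_b)
  withr::local_seed(seed)
  shuffle <- function(x) {
    x %>%
      group_by(.data$category) %>%
      mutate(probe_id = sample(.data$probe_id)) %>%
      ungroup()
  }
  null <- map(seq_len(n_perm), function(i) {
    ov <- match_pairs(shuffle(study_a), shuffle(study_b))
    mutate(ov, perm = i)
  }) %>% list_rbind()
  null <- select(null, "perm", "category", "overlap")
  observed <- match_pairs(study_a, study_b)
  structure(
    null,
    observed = observed,
    max_null = null %>% group_by(.data$category) %>%
      summarise(max_overlap = max(.data$overlap), .groups = "drop")
  )
}

#' Neighbor congruence of eCpGs within a study
#'
#' For each window size, considers every eCpG having at least one neighboring
#' eCpG within the window (the query itself excluded; the boundary distance
#' is included) and reports three nested fractions: eCpGs sharing at least
#' one associated gene with at least one neighbor; sharing at least one
#' (gene, direction) with at least one neighbor; and eCpGs all of whose
#' neighbors share at least one (gene, direction) with it.
#'
#' @param ecpgs Tibble with one row per significant (CpG, gene) association:
#'   `cpg_id`, `chrom`, `pos`, `gene_id`, `sign`.
#' @param windows Window half-widths in bp, positive and sorted.
#' @param detail If `TRUE`, also return the per-query flags (attribute
#'   `"per_query"`).
#' @return A tibble per window: `window`, `n_with_neighbor`,
#'   `frac_share_gene`, `frac_share_gene_and_sign`, `frac_all_congruent`.
#' @export
neighbor_congruence <- function(ecpgs, windows = c(100, 500, 1000, 1500, 2000),
                                detail = FALSE) {
  ecpgs <- as_tibble(ecpgs)
  stopifnot(all(c("cpg_id", "chrom", "pos", "gene_id", "sign") %in% names(ecpgs)))
  if (any(windows <= 0) || is.unsorted(windows)) abort("windows must be positive and sorted")

  sites <- distinct(ecpgs, .data$cpg_id, .data$chrom, .data$pos)
  gene_sets <- split(ecpgs$gene_id, ecpgs$cpg_id)
  gs_sets <- split(paste(ecpgs$gene_id, ecpgs$sign), ecpgs$cpg_id)

  per_query <- map(windows, function(w) {
    rows <- map(seq_len(nrow(sites)), function(i) {
      here <- sites[i, ]
      nb <- sites$cpg_id[sites$chrom == here$chrom &
                           abs(sites$pos - here$pos) <= w &
                           sites$cpg_id != here$cpg_id]
      if (length(nb) == 0) {
        return(tibble(
          cpg_id = here$cpg_id, has_neighbor = FALSE,
          shares_gene = NA, shares_gene_sign = NA, all_congruent = NA
        ))
      }
      qg <- gene_sets[[here$cpg_id]]
      qgs <- gs_sets[[here$cpg_id]]
      nb_gene <- map_lgl(nb, ~ length(intersect(gene_sets[[.x]], qg)) > 0)
      nb_gs <- map_lgl(nb, ~ length(intersect(gs_sets[[.x]], qgs)) > 0)
      tibble(
        cpg_id = here$cpg_id, has_neighbor = TRUE,
        shares_gene = any(nb_gene),
        shares_gene_sign = any(nb_gs),
        all_congruent = all(nb_gs)
      )
    }) %>% list_rbind()
    mutate(rows, window = w)
  }) %>% list_rbind()

  out <- per_query %>%
    group_by(.data$window) %>%
    summarise(
      n_with_neighbor = sum(.data$has_neighbor),
      frac_share_gene = mean(.data$shares_gene[.data$has_neighbor]),
      frac_share_gene_and_sign = mean(.data$shares_gene_sign[.data$has_neighbor]),
      frac_all_congruent = mean(.data$all_congruent[.data$has_neighbor]),
      .groups = "drop"
    )
  if (detail) attr(out, "per_query") <- per_query
  out
}
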