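#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the standard probability-ordering two-sided
#' rule: the p-value sums the probabilities of all tables with the observed
#' margins whose probability does not exceed the observed table's (with a
#' relative tie tolerance of 1e-7). The reported odds ratio is the sample
#' odds ratio ad/bc (not the conditional MLE); it is `Inf` when bc = 0 and
#' ad > 0, and `NaN` for 0/0.
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   integer counts `[[a, c], [b, d]]` with `a` the overlap cell.
#' @param alternative `"two.sided"` (probability ordering) or `"greater"`
#'   (upper hypergeometric tail on the `a` cell).
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.vector(tab)
  if (length(tab) != 4L) abort("Need a 2x2 table.")
  if (any(tab < 0) || any(tab != floor(tab))) {
    abort("Table entries must be non-negative integers.")
  }
  a <- tab[1L]; b <- tab[2L]; c <- tab[3L]; d <- tab[4L]
  m <- a + b  # row-1 margin of the first column grouping
  n <- c + d
  k <- a + c
  p <- if (m + n == 0L || k == 0L || k == m + n || m == 0L || n == 0L) {
    1
  } else if (alternative == "greater") {
    phyper(a - 1L, m, n, k, lower.tail = FALSE)
  } else {
    support <- max(0L, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  list(odds_ratio = (a * d) / (b * c), p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH with monotonicity enforcement, returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

# shared best-hit ordering: lowest e-value, then highest bitscore, then
# lexicographic target id
best_hit_per_query <- function(hits) {
  hits |>
    arrange(.data$query_id, .data$evalue, desc(.data$bitscore), .data$target_id) |>
    distinct(.data$query_id, .keep_all = TRUE)
}

#' Call one-to-one orthologs as reciprocal best hits
#'
#' From a combined-database hit table, each gene's best cross-species hit is
#' the one with the lowest e-value (ties broken by higher bitscore, then
#' lexicographic target id) among hits below `max_evalue`; self-hits are
#' discarded. A pair (a, b) is a one-to-one ortholog call iff each is the
#' other's best cross-species hit. With
#' `reject_if_within_species_hit_better = TRUE` (default), a gene whose best
#' within-species hit (excluding itself) outranks its best cross-species hit
#' is dropped, which suppresses one-to-one calls in the presence of recent
#' inparalogs, mirroring a combined-database best-hit search.
#'
#' @param hits hit tibble (see [read_hit_table()]).
#' @param taxon_a,taxon_b the two taxa to pair.
#' @param max_evalue qualifying e-value cutoff (strict `<`).
#' @param reject_if_within_species_hit_better drop genes dominated by a
#'   within-species hit.
#' @return tibble (`gene_a`, `gene_b`, `evalue_ab`, `evalue_ba`), `gene_a`
#'   from `taxon_a`, sorted by `gene_a`; each gene appears at most once.
#' @export
call_rbh_orthologs <- function(hits, taxon_a, taxon_b, max_evalue = 1e-3,
                               reject_if_within_species_hit_better = TRUE) {
  qual <- hits |>
    filter(.data$query_id != .data$target_id, .data$evalue < max_evalue,
           .data$query_taxon %in% c(taxon_a, taxon_b),
           .data$target_taxon %in% c(taxon_a, taxon_b))
  cross <- qual |> filter(.data$query_taxon != .data$target_taxon)
  best_ab <- best_hit_per_query(cross |> filter(.data$query_taxon == taxon_a))
  best_ba <- best_hit_per_query(cross |> filter(.data$query_taxon == taxon_b))
  if (reject_if_within_species_hit_better) {
    within_best <- best_hit_per_query(
      qual |> filter(.data$query_taxon == .data$target_taxon)
    )
    dominated <- function(bests) {
      j <- inner_join(bests, within_best, by = "query_id",
                      suffix = c("", ".within"))
      j$query_id[j$evalue.within < j$evalue |
                   (j$evalue.within == j$evalue & j$bitscore.within > j$bitscore)]
    }
    best_ab <- best_ab |> filter(!.data$query_id %in% dominated(best_ab))
    best_ba <- best_ba |> filter(!.data$query_id %in% dominated(best_ba))
  }
  pairs <- inner_join(
    best_ab |> select(gene_a = "query_id", gene_b = "target_id", evalue_ab = "evalue"),
    best_ba |> select(gene_b = "query_id", gene_a = "target_id", evalue_ba = "evalue"),
    by = c("gene_a", "gene_b")
  )
  pairs |> arrange(.data$gene_a)
}

#' Write an ortholog map
#'
#' @param orthologs tibble from [call_rbh_orthologs()].
#' @param path output TSV path.
#' @export
write_ortholog_map <- function(orthologs, path) {
  readr::write_tsv(orthologs, path)
  invisible(path)
}

enrichment_row <- function(k, K, n, N, alternative = "two.sided") {
  if (K == 0L || n == 0L) {
    return(tibble(k = k, K = K, n = n, N = N, odds_ratio = 0, p = 1))
  }
  ft <- fisher_exact_2x2(c(k, K - k, n - k, N - K - n + k),
                         alternative = alternative)
  or <- ft$odds_ratio
  tibble(k = k, K = K, n = n, N = N,
         odds_ratio = if (is.nan(or)) 0 else or, p = ft$p)
}

#' Region-by-region sharing of regional genes
#'
#' Quantifies how many regional genes two regions share and how surprising
#' the overlap is. Cross-species mode (both profiles plus an ortholog map):
#' the universe is the set of one-to-one ortholog pairs expressed (in at
#' least one region) in both species; for a region pair, `K` and `n` are the
#' pairs regional in the two regions and `k` the pairs regional in both.
#' Within-species mode (`rp_b = NULL`): the profile is compared against
#' itself over all unordered region pairs (including each region with
#' itself), with the universe being that species' expressed genes.
#' Fisher's exact test per pair, BH adjustment across all pairs tested.
#'
#' @param rp_a,rp_b `region_profile`s (`rp_b = NULL` for within-species).
#' @param orthologs one-to-one ortholog tibble (`gene_a`, `gene_b`);
#'   required in cross-species mode.
#' @param alternative passed to [fisher_exact_2x2()].
#' @return tibble (`region_a`, `region_b`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p`, `q`).
#' @export
region_overlap_tests <- function(rp_a, rp_b = NULL, orthologs = NULL,
                                 alternative = "two.sided") {
  if (is.null(rp_b)) {
    expressed_any <- rowSums(rp_a$expressed) > 0
    universe <- rp_a$gene_ids[expressed_any]
    sets <- purrr::map(rp_a$regions, function(r) {
      intersect(rp_a$gene_ids[rp_a$regional[, r]], universe)
    })
    names(sets) <- rp_a$regions
    grid <- expand_grid(region_a = rp_a$regions, region_b = rp_a$regions) |>
      filter(match(.data$region_a, rp_a$regions) <=
               match(.data$region_b, rp_a$regions))
    N <- length(universe)
    res <- purrr::pmap(grid, function(region_a, region_b) {
      A <- sets[[region_a]]; B <- sets[[region_b]]
      enrichment_row(length(intersect(A, B)), length(A), length(B), N,
                     alternative)
    })
  } else {
    if (is.null(orthologs)) abort("Cross-species mode needs `orthologs`.")
    pairs <- orthologs |>
      filter(.data$gene_a %in% rp_a$gene_ids, .data$gene_b %in% rp_b$gene_ids)
    pairs <- pairs[rowSums(rp_a$expressed[pairs$gene_a, , drop = FALSE]) > 0 &
                     rowSums(rp_b$expressed[pairs$gene_b, , drop = FALSE]) > 0, ]
    N <- nrow(pairs)
    grid <- expand_grid(region_a = rp_a$regions, region_b = rp_b$regions)
    res <- purrr::pmap(grid, function(region_a, region_b) {
      in_a <- rp_a$regional[pairs$gene_a, region_a]
      in_b <- rp_b$regional[pairs$gene_b, region_b]
      enrichment_row(sum(in_a & in_b), sum(in_a), sum(in_b), N, alternative)
    })
  }
  out <- bind_rows(res)
  out <- bind_cols(grid, out)
  out$q <- bh_fdr(out$p)
  out
}

#' Protein-domain overrepresentation per region
#'
#' For every (region, domain) pair, tests whether the region's regional genes
#' are enriched for members of the domain family, against a background of all
#' expressed genes (expressed in at least one region). Reports the member
#' count `k`, Fisher's exact p, BH q across all pairs, and the cumulative
#' expression of the overlapping regional genes (sum of their median
#' normalized counts in the region).
#'
#' @param rp a `region_profile`.
#' @param domains tibble (`gene_id`, `domain_id`); domains with no member in
#'   the expressed universe are skipped with a warning.
#' @param alternative passed to [fisher_exact_2x2()].
#' @return tibble (`region`, `domain`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p`, `q`, `cumulative_expression`).
#' @export
domain_enrichment <- function(rp, domains, alternative = "two.sided") {
  universe <- rp$gene_ids[rowSums(rp$expressed) > 0]
  N <- length(universe)
  dom_in <- domains |> filter(.data$gene_id %in% universe)
  skipped <- setdiff(unique(domains$domain_id), unique(dom_in$domain_id))
  if (length(skipped)) {
    warn(paste0("Domains with no expressed member, skipped: ",
                paste(head(skipped, 10L), collapse = ", ")))
  }
  if (nrow(dom_in) == 0L) abort("No domain has members in the expressed universe.")
  dom_sets <- split(dom_in$gene_id, dom_in$domain_id)
  reg_sets <- purrr::map(rp$regions, function(r) {
    intersect(rp$gene_ids[rp$regional[, r]], universe)
  })
  names(reg_sets) <- rp$regions
  grid <- expand_grid(region = rp$regions, domain = names(dom_sets))
  res <- purrr::pmap(grid, function(region, domain) {
    members <- intersect(reg_sets[[region]], dom_sets[[domain]])
    row <- enrichment_row(length(members), length(reg_sets[[region]]),
                          length(dom_sets[[domain]]), N, alternative)
    row$cumulative_expression <-
      if (length(members)) sum(rp$median_norm[members, region]) else 0
    row
  })
  out <- bind_cols(grid, bind_rows(res))
  out$q <- bh_fdr(out$p)
  out |> select("region", "domain", "k", "K", "n", "N", "odds_ratio",
                "p", "q", "cumulative_expression")
}

#' Heatmap-ready matrices from an overlap test
#'
#' @param overlaps tibble from [region_overlap_tests()].
#' @return list of two matrices (`k` counts, `neglog10_q`) with region_a rows
#'   and region_b columns.
#' @export
overlap_matrices <- function(overlaps) {
  ra <- unique(overlaps$region_a); rb <- unique(overlaps$region_b)
  mk <- matrix(NA_real_, length(ra), length(rb), dimnames = list(ra, rb))
  mq <- mk
  for (i in seq_len(nrow(overlaps))) {
    mk[overlaps$region_a[i], overlaps$region_b[i]] <- overlaps$k[i]
    mq[overlaps$region_a[i], overlaps$region_b[i]] <-
      -log10(pmax(overlaps$q[i], .Machine$double.xmin))
  }
  list(k = mk, neglog10_q = mq)
}
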