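#' Select one-to-one ortholog pairs by minimum dS
#'
#' Ortholog-cluster rate tables can list several candidate partners per focal
#' gene; for selection analysis, the partner with the lowest estimated dS is
#' taken as the one-to-one ortholog (ties broken by lower omega, then
#' lexicographic partner id). Rows with undefined omega (e.g. dS = 0) are
#' excluded first and their count reported via a message.
#'
#' @param rates tibble (`gene_a`, `gene_b`, `dN`, `dS`, `omega`).
#' @param focal_side `"a"` or `"b"`: which column holds the focal species'
#'   genes.
#' @return tibble (`gene_id`, `partner`, `dN`, `dS`, `omega`), one row per
#'   focal gene.
#' @export
select_min_ds_orthologs <- function(rates, focal_side = c("a", "b")) {
  focal_side <- match.arg(focal_side)
  focal <- if (focal_side == "a") "gene_a" else "gene_b"
  partner <- if (focal_side == "a") "gene_b" else "gene_a"
  n_undef <- sum(is.na(rates$omega))
  if (n_undef) inform(sprintf("Excluding %d pair(s) with undefined omega.", n_undef))
  rates |>
    filter(!is.na(.data$omega)) |>
    select(gene_id = all_of(focal), partner = all_of(partner),
           "dN", "dS", "omega") |>
    arrange(.data$gene_id, .data$dS, .data$omega, .data$partner) |>
    distinct(.data$gene_id, .keep_all = TRUE)
}

#' Summarize dN/dS by group
#'
#' Median and interquartile range of omega per group (phylostratum, region,
#' ...), using linear-interpolation (type-7) quantiles. Genes in the grouping
#' without a selected pair are skipped (count reported via a message); groups
#' without any pair are reported with `n = 0` and `NA` statistics.
#'
#' @param selected tibble from [select_min_ds_orthologs()].
#' @param grouping tibble (`gene_id`, `group`); a gene may appear in several
#'   groups (e.g. regional in two regions).
#' @return tibble (`group`, `n`, `median_omega`, `q1`, `q3`).
#' @export
summarize_rates <- function(selected, grouping) {
  joined <- inner_join(grouping, selected, by = "gene_id")
  n_skipped <- nrow(anti_join(grouping, selected, by = "gene_id"))
  if (n_skipped) {
    inform(sprintf("%d grouped gene(s) without a selected ortholog pair, skipped.",
                   n_skipped))
  }
  all_groups <- unique(grouping$group)
  joined |>
    group_by(.data$group) |>
    summarise(n = n(),
              median_omega = median(.data$omega),
              q1 = quantile(.data$omega, 0.25, type = 7, names = FALSE),
              q3 = quantile(.data$omega, 0.75, type = 7, names = FALSE),
              .groups = "drop") |>
    complete(group = all_groups,
             fill = list(n = 0L, median_omega = NA_real_,
                         q1 = NA_real_, q3 = NA_real_)) |>
    arrange(match(.data$group, all_groups))
}

#' Match a species pair by median dS divergence
#'
#' Given candidate species-pair rate tables, picks the pair whose median dS
#' is closest to a reference divergence (e.g. match a congeneric pair to the
#' C. elegans / C. briggsae distance); ties go to the larger median dS (the
#' more conservative, i.e. more diverged, choice).
#'
#' @param candidates named list of rates tibbles.
#' @param reference_median_ds reference median dS to match.
#' @return list with `choice` (candidate name), `median_ds` (its median dS)
#'   and `candidates` (tibble of all medians and distances).
#' @export
match_species_pair_by_ds <- function(candidates, reference_median_ds) {
  if (!length(candidates)) abort("Need at least one candidate pair.")
  tab <- purrr::imap(candidates, function(rt, nm) {
    ds <- rt$dS[!is.na(rt$dS)]
    if (!length(ds)) abort(sprintf("Candidate '%s' has no defined dS.", nm))
    tibble(candidate = nm, median_ds = median(ds))
  }) |>
    bind_rows() |>
    mutate(abs_diff = abs(.data$median_ds - reference_median_ds)) |>
    arrange(.data$abs_diff, desc(.data$median_ds))
  list(choice = tab$candidate[1L], median_ds = tab$median_ds[1L],
       candidates = tab)
}

#' Boxplot-ready long table of selected rates
#'
#' @param selected tibble from [select_min_ds_orthologs()].
#' @param grouping tibble (`gene_id`, `group`).
#' @return long tibble (`group`, `gene_id`, `omega`).
#' @export
rates_long <- function(selected, grouping) {
  inner_join(grouping, selected, by = "gene_id") |>
    select("group", "gene_id", "omega")
}
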