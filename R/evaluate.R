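precision_recall_f1 <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  precision <- if (length(pred)) tp / length(pred) else NA_real_
  recall <- if (length(truth)) tp / length(truth) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(n_pred = length(pred), n_truth = length(truth), tp = tp,
         precision = precision, recall = recall, f1 = f1)
}

#' Compare pipeline outputs against synthetic ground truth
#'
#' Computes recovery metrics for whichever outputs are supplied: region
#' boundary errors (in sections) per specimen, regional-gene precision /
#' recall / F1 at the (gene, region) and gene level, one-to-one ortholog
#' call accuracy, phylostratum assignment accuracy, the young-fraction ranks
#' attained by the planted sperm regions, and whether per-stratum omega
#' medians decrease strictly with age.
#'
#' @param truth the `truth` element of a [generate_experiment()] result.
#' @param assignments named list (species -> list of `region_assignment`s).
#' @param profiles named list (species -> `region_profile`).
#' @param orthologs tibble from [call_rbh_orthologs()].
#' @param ages tibble from [assign_phylostrata()].
#' @param young_test tibble from [young_fraction_test()].
#' @param rate_summary tibble from [summarize_rates()] grouped by
#'   `stratum_name` in ladder order.
#' @return list of metric tibbles/values (components for inputs not supplied
#'   are omitted).
#' @export
evaluate_recovery <- function(truth, assignments = NULL, profiles = NULL,
                              orthologs = NULL, ages = NULL,
                              young_test = NULL, rate_summary = NULL) {
  out <- list()
  if (!is.null(assignments)) {
    rows <- purrr::imap(assignments, function(ras, sp) {
      purrr::map(ras, function(ra) {
        inferred <- region_boundaries(ra)
        tb <- truth$boundaries |> filter(.data$specimen == ra$specimen_id[1L])
        j <- inner_join(inferred, tb, by = "region",
                        suffix = c("_inferred", "_true"))
        tibble(species = sp, specimen = ra$specimen_id[1L],
               region = j$region[-1L],
               error = abs(j$start_inferred[-1L] - j$start_true[-1L]))
      }) |> bind_rows()
    }) |> bind_rows()
    out$boundary_errors <- rows
    out$boundary_summary <- rows |>
      summarise(mean_abs_error = mean(.data$error),
                max_error = max(.data$error),
                frac_within_1 = mean(.data$error <= 1))
  }
  if (!is.null(profiles)) {
    out$regional_recovery <- purrr::imap(profiles, function(rp, sp) {
      tr <- truth$regional[[sp]] |> filter(.data$gene_id %in% rp$gene_ids)
      pred_pairs <- tidy.region_profile(rp) |> filter(.data$regional)
      pairs <- precision_recall_f1(
        paste(pred_pairs$gene_id, pred_pairs$region),
        paste(tr$gene_id, tr$region)
      ) |> mutate(species = sp, level = "gene_region", .before = 1L)
      genes <- precision_recall_f1(unique(pred_pairs$gene_id),
                                   unique(tr$gene_id)) |>
        mutate(species = sp, level = "gene", .before = 1L)
      bind_rows(pairs, genes)
    }) |> bind_rows()
  }
  if (!is.null(orthologs)) {
    out$ortholog_recovery <- precision_recall_f1(
      paste(orthologs$gene_a, orthologs$gene_b),
      paste(truth$orthologs$gene_a, truth$orthologs$gene_b)
    )
  }
  if (!is.null(ages)) {
    if (!all(ages$gene_id %in% truth$strata$gene_id)) {
      abort("Aged genes are not a subset of the truth universe.")
    }
    j <- inner_join(ages, truth$strata, by = "gene_id",
                    suffix = c("_called", "_true"))
    out$stratum_accuracy <- mean(j$stratum_called == j$stratum_true)
  }
  if (!is.null(young_test)) {
    ranks <- young_test |>
      filter(.data$region %in% truth$sperm_region_labels)
    out$young_region_ranks <- ranks |> select("region", "rank", "q")
    out$sperm_regions_top2 <- all(ranks$rank <= 2L)
    out$sperm_regions_significant <- all(ranks$q < 0.05)
  }
  if (!is.null(rate_summary)) {
    med <- rate_summary$median_omega[rate_summary$n > 0]
    out$omega_medians <- rate_summary
    out$omega_strictly_decreasing <- all(diff(med) < 0)
  }
  out
}
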