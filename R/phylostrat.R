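#' Assign phylostrata over a ladder phylogeny
#'
#' A taxon carries homology evidence for a gene if any protein hit targets it
#' with `evalue < protein_threshold`, or any nucleotide hit with
#' `evalue < nucleotide_threshold` (the nucleotide search rescues genes whose
#' open reading frames are mis-annotated, so evidence is the union of the two
#' assays). A gene's phylostratum is the highest stratum index among taxa
#' with evidence; genes with no qualifying hit anywhere are stratum 1,
#' i.e. specific to the focal species.
#'
#' @param protein_hits hit tibble (see [read_hit_table()]); `target_taxon`
#'   must resolve to ladder taxa.
#' @param nucleotide_hits optional hit tibble for the nucleotide rescue
#'   search (`NULL` for none).
#' @param ladder a [ladder_config()].
#' @param universe character vector of focal genes to age; every universe
#'   gene receives exactly one stratum.
#' @return tibble (`gene_id`, `stratum`, `stratum_name`) with
#'   `stratum_name` the roman numeral of the index.
#' @export
assign_phylostrata <- function(protein_hits, nucleotide_hits = NULL, ladder,
                               universe) {
  stopifnot(inherits(ladder, "ladder_config"), length(universe) > 0L)
  tax2str <- ladder_taxon_strata(ladder)
  check_taxa <- function(hits, what) {
    if (is.null(hits) || nrow(hits) == 0L) return(invisible())
    unknown <- setdiff(unique(hits$target_taxon), names(tax2str))
    if (length(unknown)) {
      abort(paste0(what, " hits target taxa absent from the ladder: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  check_taxa(protein_hits, "Protein")
  check_taxa(nucleotide_hits, "Nucleotide")
  qual <- bind_rows(
    if (!is.null(protein_hits) && nrow(protein_hits)) {
      protein_hits |> filter(.data$evalue < ladder$protein_threshold)
    },
    if (!is.null(nucleotide_hits) && nrow(nucleotide_hits)) {
      nucleotide_hits |> filter(.data$evalue < ladder$nucleotide_threshold)
    }
  )
  strata <- rep(1L, length(universe))
  names(strata) <- universe
  if (!is.null(qual) && nrow(qual)) {
    hit_strata <- qual |>
      filter(.data$query_id %in% universe) |>
      mutate(stratum = tax2str[.data$target_taxon]) |>
      group_by(.data$query_id) |>
      summarise(stratum = max(.data$stratum), .groups = "drop")
    strata[hit_strata$query_id] <- pmax(1L, hit_strata$stratum)
  }
  tibble(gene_id = universe, stratum = unname(strata[universe]),
         stratum_name = as.character(utils::as.roman(unname(strata[universe]))))
}

#' Phylostratum composition of gene sets
#'
#' Counts and fractions of each age class within each regional gene set,
#' plus the genome-wide reference composition over the whole universe
#' (reported as set `"Ref"`).
#'
#' @param ages tibble from [assign_phylostrata()].
#' @param regional_sets named list: region -> character vector of genes
#'   (must be a subset of the universe).
#' @param n_strata total number of strata (defaults to the maximum observed).
#' @return tibble (`set`, `stratum`, `count`, `fraction`); fractions of a
#'   nonempty set sum to 1, empty sets report all-zero fractions.
#' @export
age_composition <- function(ages, regional_sets, n_strata = max(ages$stratum)) {
  lookup <- setNames(ages$stratum, ages$gene_id)
  bad <- purrr::map_lgl(regional_sets, function(g) !all(g %in% ages$gene_id))
  if (any(bad)) {
    abort(paste0("Regional sets outside the aged universe: ",
                 paste(names(regional_sets)[bad], collapse = ", ")))
  }
  sets <- c(list(Ref = ages$gene_id), regional_sets)
  purrr::imap(sets, function(genes, nm) {
    counts <- tabulate(lookup[genes], nbins = n_strata)
    tibble(set = nm, stratum = seq_len(n_strata), count = counts,
           fraction = if (length(genes)) counts / length(genes) else
             rep(0, n_strata))
  }) |> bind_rows()
}

#' Test regional gene sets for excess young genes
#'
#' For each region, a one-sided (greater) Fisher's exact test asks whether
#' its regional genes are enriched for young phylostrata relative to the
#' rest of the universe, with BH adjustment across regions. Also reports the
#' observed young fraction and each region's rank by young fraction
#' (rank 1 = youngest), the quantity behind the out-of-testis comparison of
#' sperm regions against the rest of the body.
#'
#' @param ages tibble from [assign_phylostrata()].
#' @param regional_sets named list region -> gene vector.
#' @param young_strata integer vector of stratum indices counted as young.
#' @return tibble (`region`, `n_regional`, `n_young`, `young_fraction`,
#'   `odds_ratio`, `p`, `q`, `rank`).
#' @export
young_fraction_test <- function(ages, regional_sets, young_strata = 1:3) {
  if (!length(young_strata)) abort("`young_strata` must be nonempty.")
  young_genes <- ages$gene_id[ages$stratum %in% young_strata]
  universe <- ages$gene_id
  rows <- purrr::imap(regional_sets, function(genes, nm) {
    a <- length(intersect(genes, young_genes))
    b <- length(genes) - a
    c_ <- length(young_genes) - a
    d <- length(universe) - length(genes) - c_
    ft <- fisher_exact_2x2(c(a, b, c_, d), alternative = "greater")
    tibble(region = nm, n_regional = length(genes), n_young = a,
           young_fraction = if (length(genes)) a / length(genes) else NA_real_,
           odds_ratio = if (is.nan(ft$odds_ratio)) 0 else ft$odds_ratio,
           p = ft$p)
  })
  out <- bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out$rank <- rank(-out$young_fraction, ties.method = "min", na.last = "keep")
  out
}

#' Write age tables and compositions
#'
#' @param ages tibble from [assign_phylostrata()].
#' @param path output TSV path.
#' @export
write_age_table <- function(ages, path) {
  readr::write_tsv(ages, path)
  invisible(path)
}

#' @rdname write_age_table
#' @param composition tibble from [age_composition()].
#' @export
write_age_composition <- function(composition, path) {
  readr::write_tsv(composition, path)
  invisible(path)
}
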