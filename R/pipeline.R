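#' Pipeline run configuration
#'
#' Bundles all input paths and thresholds of an end-to-end run. Counts,
#' marker configs, hit tables, the domain table and the rates table are
#' expected in the layout [write_experiment()] produces (and that real
#' inputs can be arranged into).
#'
#' @param input_dir directory holding the input tables.
#' @param output_dir directory for stage outputs (created on run).
#' @param species character vector of the two species names (first = focal);
#'   used as gene-id prefixes `<species>_`.
#' @param min_z marker-peak threshold.
#' @param smooth_window running-median width for the marker signal.
#' @param regional_z regional-gene z-score threshold (strict `>`).
#' @param min_specimens detection requirement for the gene universe
#'   (`NULL` = all specimens).
#' @param max_evalue RBH qualifying e-value.
#' @param young_strata stratum indices counted as young.
#' @param fdr_alpha significance level applied to FDR-adjusted q-values in
#'   the summary report.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       species = c("Ppa", "Cel"),
                       min_z = 1, smooth_window = 3L, regional_z = 1,
                       min_specimens = NULL, max_evalue = 1e-3,
                       young_strata = 1:3, fdr_alpha = 0.05) {
  structure(as.list(environment()), class = "run_config")
}

config_paths <- function(cfg) {
  fp <- function(...) file.path(cfg$input_dir, ...)
  counts <- purrr::map(cfg$species, function(sp) {
    sort(Sys.glob(fp(sprintf("counts_%s_*.tsv", sp))))
  })
  names(counts) <- cfg$species
  list(
    counts = counts,
    markers = setNames(fp(sprintf("markers_%s.yaml", cfg$species)), cfg$species),
    ladder = fp("ladder.yaml"),
    protein_hits = fp("protein_hits.tsv"),
    nucleotide_hits = fp("nucleotide_hits.tsv"),
    rbh_hits = fp("rbh_hits.tsv"),
    domains = fp("domains.tsv"),
    rates = fp("rates.tsv")
  )
}

#' Validate a run configuration
#'
#' Checks thresholds and the existence and mutual consistency of the inputs
#' (marker genes present in the count matrices, ladder taxa covering the hit
#' tables). Problems are returned, not raised; an empty return means the
#' configuration is runnable.
#'
#' @param cfg a [run_config()].
#' @return character vector of problems (empty if valid).
#' @export
validate_config <- function(cfg) {
  problems <- character()
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) {
    problems <- c(problems, "fdr_alpha must be in (0, 1)")
  }
  if (cfg$min_z <= 0) problems <- c(problems, "min_z must be positive")
  if (cfg$regional_z <= 0) problems <- c(problems, "regional_z must be positive")
  if (cfg$max_evalue <= 0) problems <- c(problems, "max_evalue must be positive")
  if (cfg$smooth_window %% 2L != 1L) {
    problems <- c(problems, "smooth_window must be odd")
  }
  paths <- config_paths(cfg)
  flat <- c(unlist(paths$counts), paths$markers, paths$ladder,
            paths$protein_hits, paths$nucleotide_hits, paths$rbh_hits,
            paths$domains, paths$rates)
  missing <- flat[!file.exists(flat)]
  if (length(missing)) {
    return(c(problems, paste0("missing input file: ", missing)))
  }
  if (any(lengths(paths$counts) == 0L)) {
    return(c(problems, "no count matrices found for at least one species"))
  }
  for (sp in cfg$species) {
    mc <- tryCatch(read_marker_config(paths$markers[[sp]]),
                   error = function(e) conditionMessage(e))
    if (is.character(mc)) {
      problems <- c(problems, paste0("marker config (", sp, "): ", mc))
      next
    }
    sc <- tryCatch(read_section_counts(paths$counts[[sp]][1L]),
                   error = function(e) NULL)
    if (!is.null(sc)) {
      markers <- unique(unlist(mc$markers))
      absent <- setdiff(markers, rownames(sc$counts))
      if (length(absent)) {
        problems <- c(problems, paste0(
          "marker gene(s) absent from ", sp, " counts: ",
          paste(head(absent, 5L), collapse = ", ")))
      }
    }
  }
  problems
}

log_stage <- function(log, stage, t0, note = "") {
  bind_rows(log, tibble(stage = stage, seconds = round(as.numeric(
    difftime(Sys.time(), t0, units = "secs")), 3L), note = note))
}

#' Run the full comparative tomo-seq pipeline
#'
#' Executes every stage in dependency order: normalization and z-scoring per
#' specimen, marker-peak segmentation, pooling into region profiles with
#' expressed/regional calls, section clustering, reciprocal-best-hit
#' orthology, region-overlap tests (cross-species and within each species),
#' domain overrepresentation, phylostratigraphy with age composition and
#' young-fraction tests, and dN/dS selection and summaries by stratum and
#' region. Writes every stage's TSV plus a run log and plain-text summary
#' into `cfg$output_dir`. All stages are deterministic: rerunning an
#' identical configuration on identical inputs reproduces the outputs
#' byte-for-byte.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a named list of all in-memory stage results.
#' @export
run_all <- function(cfg) {
  problems <- validate_config(cfg)
  if (length(problems)) {
    abort(paste0("Invalid configuration:\n", paste("-", problems, collapse = "\n")))
  }
  paths <- config_paths(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(...) file.path(cfg$output_dir, ...)
  taxon_map <- setNames(cfg$species, paste0(cfg$species, "_"))
  log <- tibble(stage = character(), seconds = double(), note = character())
  res <- list()

  for (sp in cfg$species) {
    t0 <- Sys.time()
    scs <- purrr::map(paths$counts[[sp]], function(path) {
      read_section_counts(
        path,
        specimen_id = sub("^counts_", "", sub("\\.[^.]*$", "", basename(path)))
      )
    })
    zps <- purrr::map(scs, normalize_and_zscore)
    mc <- read_marker_config(paths$markers[[sp]])
    ras <- purrr::map(zps, segment_regions, cfg = mc, min_z = cfg$min_z,
                      smooth_window = cfg$smooth_window)
    min_spec <- cfg$min_specimens %||% length(zps)
    rp <- pool_regions(zps, ras, min_specimens = min_spec,
                       regional_z = cfg$regional_z)
    write_region_assignments(ras, op(sprintf("region_assignment_%s.tsv", sp)))
    write_region_profile(rp, op(sprintf("region_profile_%s.tsv", sp)))
    write_dendrogram_newick(cluster_sections(zps),
                            op(sprintf("section_dendrogram_%s.nwk", sp)))
    res$zps[[sp]] <- zps
    res$assignments[[sp]] <- ras
    res$profiles[[sp]] <- rp
    log <- log_stage(log, paste0("spatial_", sp), t0,
                     sprintf("%d specimens, %d universe genes",
                             length(zps), length(rp$gene_ids)))
  }

  t0 <- Sys.time()
  rbh_hits <- read_hit_table(paths$rbh_hits, taxon_map, format = "reduced6")
  orthologs <- call_rbh_orthologs(rbh_hits, cfg$species[1L], cfg$species[2L],
                                  max_evalue = cfg$max_evalue)
  write_ortholog_map(orthologs, op("orthologs.tsv"))
  res$orthologs <- orthologs
  log <- log_stage(log, "orthologs", t0, sprintf("%d pairs", nrow(orthologs)))

  t0 <- Sys.time()
  rp_a <- res$profiles[[cfg$species[1L]]]
  rp_b <- res$profiles[[cfg$species[2L]]]
  cross <- region_overlap_tests(rp_a, rp_b, orthologs)
  readr::write_tsv(cross, op("overlap_cross_species.tsv"))
  for (sp in cfg$species) {
    within <- region_overlap_tests(res$profiles[[sp]])
    readr::write_tsv(within, op(sprintf("overlap_within_%s.tsv", sp)))
    res$overlap_within[[sp]] <- within
  }
  res$overlap_cross <- cross
  write_dendrogram_newick(
    cluster_regions_by_orthologs(rp_a, rp_b, orthologs,
                                 species_a = cfg$species[1L],
                                 species_b = cfg$species[2L]),
    op("region_dendrogram.nwk")
  )
  log <- log_stage(log, "overlap", t0)

  t0 <- Sys.time()
  domains <- read_domain_table(paths$domains)
  enr <- domain_enrichment(rp_a, domains)
  readr::write_tsv(enr, op("domain_enrichment.tsv"))
  res$domain_enrichment <- enr
  log <- log_stage(log, "domains", t0,
                   sprintf("%d significant at q<%g", sum(enr$q < cfg$fdr_alpha),
                           cfg$fdr_alpha))

  t0 <- Sys.time()
  ladder <- read_ladder_config(paths$ladder)
  prot <- read_hit_table(paths$protein_hits, taxon_map, format = "reduced6",
                         target_is_taxon = TRUE)
  nuc <- read_hit_table(paths$nucleotide_hits, taxon_map, format = "reduced6",
                        target_is_taxon = TRUE)
  ages <- assign_phylostrata(prot, nuc, ladder, universe = rp_a$gene_ids)
  reg_sets <- regional_gene_sets(rp_a)
  composition <- age_composition(ages, reg_sets,
                                 n_strata = length(ladder$strata))
  young <- young_fraction_test(ages, reg_sets,
                               young_strata = cfg$young_strata)
  write_age_table(ages, op("phylostrata.tsv"))
  write_age_composition(composition, op("age_composition.tsv"))
  readr::write_tsv(young, op("young_fraction_tests.tsv"))
  res$ages <- ages
  res$age_composition <- composition
  res$young_test <- young
  log <- log_stage(log, "phylostrat", t0,
                   sprintf("%d strata", length(ladder$strata)))

  t0 <- Sys.time()
  rates <- read_rates_table(paths$rates)
  selected <- suppressMessages(select_min_ds_orthologs(rates, "a"))
  by_stratum <- suppressMessages(summarize_rates(
    selected,
    ages |> arrange(.data$stratum) |>
      select(gene_id = "gene_id", group = "stratum_name")
  ))
  region_grouping <- purrr::imap(reg_sets, function(g, r) {
    tibble(gene_id = g, group = r)
  }) |> bind_rows()
  by_region <- suppressMessages(summarize_rates(selected, region_grouping))
  readr::write_tsv(selected, op("selected_orthologs.tsv"))
  readr::write_tsv(by_stratum, op("rates_by_stratum.tsv"))
  readr::write_tsv(by_region, op("rates_by_region.tsv"))
  res$selected_rates <- selected
  res$rates_by_stratum <- by_stratum
  res$rates_by_region <- by_region
  log <- log_stage(log, "rates", t0, sprintf("%d pairs", nrow(selected)))

  readr::write_tsv(log |> select("stage", "note"), op("run_log.tsv"))
  writeLines(run_summary_text(cfg, res), op("summary.txt"))
  invisible(res)
}

run_summary_text <- function(cfg, res) {
  rp_a <- res$profiles[[cfg$species[1L]]]
  young <- res$young_test |> arrange(.data$rank)
  c(
    sprintf("species: %s vs %s", cfg$species[1L], cfg$species[2L]),
    sprintf("universe (focal): %d genes; expressed: %d; regional: %d",
            length(rp_a$gene_ids), sum(rowSums(rp_a$expressed) > 0),
            sum(rowSums(rp_a$regional) > 0)),
    sprintf("one-to-one orthologs: %d", nrow(res$orthologs)),
    sprintf("domain enrichments at q<%g: %d", cfg$fdr_alpha,
            sum(res$domain_enrichment$q < cfg$fdr_alpha)),
    "young-fraction ranks (youngest first):",
    sprintf("  %s  rank %d  young_fraction %.3f  q %.3g",
            young$region, young$rank, young$young_fraction, young$q)
  )
}
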