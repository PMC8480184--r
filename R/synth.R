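#' Parameters of the synthetic tomo-seq experiment
#'
#' Defaults describe the study conditions the analysis is designed for: two
#' nematode species, four specimens each, about forty 20-um cryosections per
#' animal, eight anatomical regions of which two are sperm-related and share
#' a two-peak MSP-like marker (defining them as its first and second A-P
#' peak) and one is defined indirectly between its neighbours. Counts are
#' negative-binomial with per-section log-normal library-size factors, the
#' minimal noise model under which normalizing by section totals is
#' necessary.
#'
#' @param n_specimens specimens per species.
#' @param n_sections cryosections per specimen.
#' @param n_genes genes per species (markers are added on top).
#' @param n_regions anatomical regions per species.
#' @param sperm_regions indices of the two sperm-related regions (share the
#'   two-peak marker and receive the young-gene boost).
#' @param indirect_region index of the region defined between its anchors.
#' @param sperm_region_width sections per sperm region (narrow,
#'   spermatheca-like); the remaining sections are shared near-equally by
#'   the other regions.
#' @param regional_fraction probability a gene is regional somewhere.
#' @param fold expression fold of a regional gene in its home region.
#' @param marker_fold expression fold of a marker gene in its region(s).
#' @param n_markers_per_region marker genes per single-region marker set.
#' @param n_sperm_markers genes in the shared sperm (MSP-like) marker family.
#'   The two-peak marker's z-score plateau saturates near 1.7 however strong
#'   its fold (it is high in a quarter of the sections), so its signal is
#'   only usable averaged over a family; MSP is a large family in real
#'   nematodes, with regions expressing dozens of members.
#' @param dispersion negative-binomial dispersion; 0 means noise-free
#'   counts (rounded expected values), the deterministic limit.
#' @param equalize_totals if `TRUE`, expected section totals are equalized
#'   across sections before drawing counts, removing both library-size and
#'   compositional variation. With total-count normalization, strongly
#'   expressed regional genes inflate their home sections' totals and
#'   thereby depress every other gene's normalized value there; equalizing
#'   isolates the planted signal from that coupling (used for noiseless
#'   validation).
#' @param libsize_sdlog sdlog of the per-section library-size factor.
#' @param base_meanlog,base_sdlog log-normal baseline expression per gene.
#' @param ortholog_fraction fraction of genes with a one-to-one ortholog.
#' @param conservation probability an ortholog pair shares its regional
#'   status and home region across species.
#' @param stratum_distribution genome-wide phylostratum reference
#'   distribution (stratum 1 = focal-species-specific, oldest last).
#' @param young_strata stratum indices counted as young.
#' @param young_boost multiplier on young-stratum weights for genes regional
#'   in a sperm region (1 = null).
#' @param omega_means mean dN/dS per stratum (must be positive; strictly
#'   decreasing encodes stronger purifying selection on older genes).
#' @param omega_shape Gamma shape of the omega draws.
#' @param ds_meanlog,ds_sdlog log-normal dS divergence of true pairs.
#' @param max_paralog_partners extra (higher-dS) cluster partners per pair.
#' @param decoy_hit_prob probability of a non-qualifying decoy hit to an
#'   older taxon.
#' @param nucleotide_rescue_prob probability a gene's defining evidence is
#'   nucleotide-only (exercises the BlastN rescue).
#' @param species names (and id prefixes) of the two species.
#' @return named list of parameters.
#' @export
synth_params <- function(n_specimens = 4L, n_sections = 40L, n_genes = 3000L,
                         n_regions = 8L, sperm_regions = c(3L, 7L),
                         indirect_region = 6L, sperm_region_width = 3L,
                         regional_fraction = 0.3, fold = 4,
                         marker_fold = 10, n_markers_per_region = 3L,
                         n_sperm_markers = 12L,
                         dispersion = 0.3, libsize_sdlog = 0.2,
                         equalize_totals = FALSE,
                         base_meanlog = log(5), base_sdlog = 0.8,
                         ortholog_fraction = 0.3, conservation = 0.8,
                         stratum_distribution = c(0.25, 0.15, 0.15, 0.20, 0.25),
                         young_strata = 1:3, young_boost = 3,
                         omega_means = c(0.5, 0.35, 0.25, 0.18, 0.12),
                         omega_shape = 3,
                         ds_meanlog = log(1.5), ds_sdlog = 0.4,
                         max_paralog_partners = 2L,
                         decoy_hit_prob = 0.3,
                         nucleotide_rescue_prob = 0.2,
                         species = c("Ppa", "Cel")) {
  p <- as.list(environment())
  if (p$n_regions > p$n_sections) abort("More regions than sections is infeasible.")
  if (p$n_sections / p$n_regions < 2) abort("Regions need at least 2 sections each on average.")
  if (length(p$sperm_regions) != 2L) abort("Exactly two sperm regions are planted.")
  if (p$indirect_region %in% c(1L, p$n_regions, p$sperm_regions)) {
    abort("The indirect region must be interior and not a sperm region.")
  }
  if (!all(abs(sum(p$stratum_distribution) - 1) < 1e-9)) {
    abort("stratum_distribution must sum to 1.")
  }
  if (length(p$omega_means) != length(p$stratum_distribution)) {
    abort("omega_means must have one entry per stratum.")
  }
  if (length(p$species) != 2L) abort("Exactly two species.")
  p
}

# deterministic per-component sub-seeds from one user seed (kept < 2^31)
component_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + offset
}

# region index of every section for one specimen. Sperm regions are narrow
# (spermatheca-like, `sperm_region_width` sections), the rest share the
# remaining sections near-equally; internal boundaries jittered by +-1
# (minimum block width 2).
synth_boundaries <- function(p) {
  n_regions <- p$n_regions
  widths <- rep(0L, n_regions)
  widths[p$sperm_regions] <- p$sperm_region_width
  other <- setdiff(seq_len(n_regions), p$sperm_regions)
  rest <- p$n_sections - sum(widths)
  widths[other] <- diff(round(seq(0, rest, length.out = length(other) + 1L)))
  cuts <- cumsum(c(0L, widths))
  shift <- sample(-1:1, n_regions - 1L, replace = TRUE)
  # a narrow sperm region shifts rigidly (both cuts together) so specimen
  # jitter moves it along the axis without shrinking it
  for (j in p$sperm_regions) {
    s <- sample(-1:1, 1L)
    shift[j - 1L] <- s
    if (j < n_regions) shift[j] <- s
  }
  inner <- cuts[2:n_regions] + shift
  cuts2 <- c(0L, inner, p$n_sections)
  if (any(diff(cuts2) < 2L)) cuts2 <- cuts  # jitter would starve a region
  rep(seq_len(n_regions), diff(cuts2))
}

synth_marker_table <- function(p, sp) {
  marker_regions <- setdiff(seq_len(p$n_regions), p$indirect_region)
  rows <- purrr::map(marker_regions, function(j) {
    if (j %in% p$sperm_regions) {
      tibble(region = j,
             gene_id = sprintf("%s_msp_%d", sp, seq_len(p$n_sperm_markers)),
             set = "msp")
    } else {
      tibble(region = j,
             gene_id = sprintf("%s_mk%d_%d", sp, j, seq_len(p$n_markers_per_region)),
             set = sprintf("mk%d", j))
    }
  })
  bind_rows(rows)
}

synth_marker_config <- function(p, sp, markers) {
  letter <- substr(sp, 1L, 1L)
  labels <- paste0(letter, seq_len(p$n_regions))
  regions <- purrr::map(seq_len(p$n_regions), function(j) {
    if (j == p$indirect_region) {
      list(label = labels[j], between = list(labels[j - 1L], labels[j + 1L]))
    } else {
      mk <- unique(markers$gene_id[markers$region == j])
      ordinal <- if (j %in% p$sperm_regions) match(j, sort(p$sperm_regions)) else 1L
      list(label = labels[j], markers = as.list(mk), peak = ordinal)
    }
  })
  marker_config(regions)
}

# per-species design: regional status, home regions, baselines, markers
synth_species_design <- function(p, sp, seed, copy_from = NULL) {
  withr::with_seed(seed, {
    genes <- sprintf("%s_g%04d", sp, seq_len(p$n_genes))
    regional <- runif(p$n_genes) < p$regional_fraction
    home <- ifelse(regional, sample.int(p$n_regions, p$n_genes, replace = TRUE),
                   NA_integer_)
    if (!is.null(copy_from)) {
      n_orth <- length(copy_from$ortholog_idx)
      keep <- runif(n_orth) < p$conservation
      idx <- copy_from$ortholog_idx[keep]
      regional[seq_len(n_orth)[keep]] <- copy_from$regional[idx]
      home[seq_len(n_orth)[keep]] <- copy_from$home[idx]
    }
    markers <- synth_marker_table(p, sp)
    all_ids <- c(genes, unique(markers$gene_id))
    base <- rlnorm(length(all_ids), p$base_meanlog, p$base_sdlog)
    names(base) <- all_ids
    list(species = sp, gene_ids = genes, regional = regional, home = home,
         markers = markers, base = base,
         labels = paste0(substr(sp, 1L, 1L), seq_len(p$n_regions)))
  })
}

synth_counts_one <- function(p, design, specimen, seed) {
  withr::with_seed(seed, {
    region_of <- synth_boundaries(p)
    lib <- rlnorm(p$n_sections, 0, p$libsize_sdlog)
    ids <- names(design$base)
    G <- length(ids)
    foldm <- matrix(1, G, p$n_sections, dimnames = list(ids, NULL))
    reg_idx <- which(design$regional)
    for (g in reg_idx) {
      foldm[g, region_of == design$home[g]] <- p$fold
    }
    for (i in seq_len(nrow(design$markers))) {
      foldm[design$markers$gene_id[i],
            region_of == design$markers$region[i]] <- p$marker_fold
    }
    mu <- design$base * foldm * rep(lib, each = G)
    if (p$equalize_totals) {
      mu <- sweep(mu, 2L, colSums(mu), "/") * (G * exp(p$base_meanlog))
    }
    counts <- if (p$dispersion > 0) {
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / p$dispersion)
    } else {
      round(as.vector(mu))
    }
    m <- matrix(as.integer(counts), G, p$n_sections,
                dimnames = list(ids, sprintf("S%02d", seq_len(p$n_sections))))
    list(counts = section_counts(m, specimen_id = specimen),
         region_of = region_of)
  })
}

# ladder taxa: one taxon per stratum above the focal species
synth_ladder <- function(p) {
  n <- length(p$stratum_distribution)
  taxa <- c(p$species[1L], sprintf("Rel%02d", seq_len(n - 1L)))
  ladder_config(p$species[1L], as.list(taxa))
}

#' Generate synthetic phylostrata and homology hit tables
#'
#' Draws a phylostratum per focal gene (reference distribution, with young
#' strata boosted by `young_boost` for genes regional in a sperm region) and
#' emits protein and nucleotide hit tables that encode it: every taxon at or
#' below the gene's stratum may carry a qualifying hit, the defining
#' stratum always does (as a nucleotide-only rescue hit with probability
#' `nucleotide_rescue_prob`), and decoy hits to older taxa sit above the
#' qualifying thresholds.
#'
#' @param p parameter list from [synth_params()].
#' @param design species design (internal; from [generate_experiment()]).
#' @param seed RNG seed for this component.
#' @param decoys emit decoy hits.
#' @return list with `strata` (integer per gene incl. markers), `ladder`,
#'   `protein_hits`, `nucleotide_hits`.
#' @keywords internal
synth_ages_and_hits <- function(p, design, seed, decoys = TRUE) {
  ladder <- synth_ladder(p)
  n_strata <- length(ladder$strata)
  taxa <- purrr::map_chr(ladder$strata, 1L)
  withr::with_seed(seed, {
    ids <- names(design$base)
    boosted_genes <- design$gene_ids[design$regional &
                                       design$home %in% p$sperm_regions]
    boosted_markers <- unique(design$markers$gene_id[
      design$markers$region %in% p$sperm_regions])
    boosted <- ids %in% c(boosted_genes, boosted_markers)
    w_ref <- p$stratum_distribution
    w_boost <- w_ref * ifelse(seq_len(n_strata) %in% p$young_strata,
                              p$young_boost, 1)
    w_boost <- w_boost / sum(w_boost)
    strata <- integer(length(ids))
    strata[!boosted] <- sample.int(n_strata, sum(!boosted), replace = TRUE,
                                   prob = w_ref)
    strata[boosted] <- sample.int(n_strata, sum(boosted), replace = TRUE,
                                  prob = w_boost)
    names(strata) <- ids

    qtax <- p$species[1L]
    hit_row <- function(gene, taxon, evalue) {
      tibble(query_id = gene, target_id = taxon, query_taxon = qtax,
             target_taxon = taxon, evalue = evalue,
             bitscore = pmax(30, -10 * log10(pmax(evalue, 1e-180))))
    }
    old <- which(strata >= 2L)
    rescue <- runif(length(old)) < p$nucleotide_rescue_prob
    # defining evidence at the gene's own stratum
    def_taxon <- taxa[strata[old]]
    prot_def <- hit_row(ids[old][!rescue], def_taxon[!rescue],
                        10^-runif(sum(!rescue), 4, 50))
    nuc_def <- hit_row(ids[old][rescue], def_taxon[rescue],
                       10^-runif(sum(rescue), 6, 30))
    prot_decoy_def <- hit_row(ids[old][rescue], def_taxon[rescue],
                              runif(sum(rescue), 2e-3, 0.5))
    # extra qualifying hits at intermediate strata (do not change the max)
    n_extra <- pmax(0L, strata[old] - 2L)
    eg <- rep(ids[old], n_extra)
    et <- taxa[sequence(n_extra) + 1L]
    keep <- runif(length(eg)) < 0.8
    prot_extra <- hit_row(eg[keep], et[keep], 10^-runif(sum(keep), 4, 50))
    # decoy non-qualifying hits to strictly older taxa
    prot_decoy <- NULL
    if (decoys) {
      cand <- which(strata < n_strata)
      pick <- cand[runif(length(cand)) < p$decoy_hit_prob]
      dtax <- taxa[strata[pick] +
                     vapply(n_strata - strata[pick], function(r)
                       sample.int(r, 1L), integer(1L))]
      prot_decoy <- hit_row(ids[pick], dtax, runif(length(pick), 2e-3, 0.9))
    }
    list(strata = strata, ladder = ladder,
         protein_hits = bind_rows(prot_def, prot_decoy_def, prot_extra,
                                  prot_decoy),
         nucleotide_hits = nuc_def)
  })
}

# cross- and within-species homology hits encoding the true one-to-one pairs
synth_rbh_hits <- function(p, design_a, design_b, n_orth, seed) {
  withr::with_seed(seed, {
    ta <- p$species[1L]; tb <- p$species[2L]
    a <- design_a$gene_ids[seq_len(n_orth)]
    b <- design_b$gene_ids[seq_len(n_orth)]
    ev <- 10^-runif(n_orth, 20, 80)
    bs <- -10 * log10(ev) + runif(n_orth, 0, 20)
    mk <- function(q, t, qt, tt, ev, bs) {
      tibble(query_id = q, target_id = t, query_taxon = qt, target_taxon = tt,
             evalue = ev, bitscore = bs)
    }
    true_hits <- bind_rows(mk(a, b, ta, tb, ev, bs), mk(b, a, tb, ta, ev, bs))
    # weaker, one-directional decoy cross hits
    decoy_of <- function(genes, partner_pool, qt, tt) {
      pick <- which(runif(length(genes)) < p$decoy_hit_prob)
      if (!length(pick)) return(NULL)
      tgt <- sample(partner_pool, length(pick), replace = TRUE)
      dev <- 10^-runif(length(pick), 4, 15)
      mk(genes[pick], tgt, qt, tt, dev, -10 * log10(dev))
    }
    rest_a <- setdiff(design_a$gene_ids, a)
    rest_b <- setdiff(design_b$gene_ids, b)
    decoys <- bind_rows(
      decoy_of(design_a$gene_ids, b, ta, tb),
      decoy_of(rest_b, a, tb, ta)
    )
    # within-species paralog hits, always weaker than the true cross hits
    para <- bind_rows(
      mk(sample(design_a$gene_ids, n_orth %/% 2L),
         sample(design_a$gene_ids, n_orth %/% 2L), ta, ta,
         10^-runif(n_orth %/% 2L, 5, 12), runif(n_orth %/% 2L, 40, 80)),
      mk(sample(design_b$gene_ids, n_orth %/% 2L),
         sample(design_b$gene_ids, n_orth %/% 2L), tb, tb,
         10^-runif(n_orth %/% 2L, 5, 12), runif(n_orth %/% 2L, 40, 80))
    )
    para <- para |> filter(.data$query_id != .data$target_id)
    bind_rows(true_hits, decoys, para)
  })
}

#' Generate a synthetic ortholog-pair rates table
#'
#' One cluster per true ortholog pair: the true partner carries the minimal
#' dS; extra paralog partners get strictly larger dS. Omega is
#' Gamma-distributed with a mean decreasing in the gene's stratum index
#' (older genes under stronger purifying selection); dN = omega * dS. A few
#' dS = 0 rows with undefined omega are included to exercise their
#' exclusion.
#'
#' @param p parameter list.
#' @param pairs tibble (`gene_a`, `gene_b`).
#' @param strata named integer vector (stratum per `gene_a`).
#' @param seed RNG seed.
#' @return list with `rates` tibble and `truth` tibble
#'   (`gene_a`, `true_partner`, `true_omega`, `stratum`).
#' @keywords internal
synth_rates <- function(p, pairs, strata, seed) {
  withr::with_seed(seed, {
    n <- nrow(pairs)
    st <- unname(strata[pairs$gene_a])
    ds <- rlnorm(n, p$ds_meanlog, p$ds_sdlog)
    omega <- rgamma(n, shape = p$omega_shape,
                    rate = p$omega_shape / p$omega_means[st])
    true_rows <- tibble(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                        dN = omega * ds, dS = ds, omega = omega)
    n_extra <- sample.int(p$max_paralog_partners + 1L, n, replace = TRUE) - 1L
    ei <- rep(seq_len(n), n_extra)
    if (length(ei)) {
      ds2 <- ds[ei] * runif(length(ei), 1.05, 2.5)
      om2 <- rgamma(length(ei), shape = p$omega_shape,
                    rate = p$omega_shape / p$omega_means[st[ei]])
      extra <- tibble(gene_a = pairs$gene_a[ei],
                      gene_b = sprintf("%s_par%05d", p$species[2L], seq_along(ei)),
                      dN = om2 * ds2, dS = ds2, omega = om2)
    } else extra <- NULL
    zero_i <- which(runif(n) < 0.02)
    zero <- if (length(zero_i)) {
      tibble(gene_a = pairs$gene_a[zero_i],
             gene_b = sprintf("%s_zds%04d", p$species[2L], seq_along(zero_i)),
             dN = runif(length(zero_i), 0, 0.1), dS = 0, omega = NA_real_)
    } else NULL
    list(rates = bind_rows(true_rows, extra, zero) |> arrange(.data$gene_a),
         truth = tibble(gene_a = pairs$gene_a, true_partner = pairs$gene_b,
                        true_omega = omega, stratum = st))
  })
}

synth_domains <- function(p, design, seed) {
  withr::with_seed(seed, {
    reg_sets <- purrr::map(seq_len(p$n_regions), function(j) {
      design$gene_ids[design$regional & design$home == j & !is.na(design$home)]
    })
    planted <- purrr::map(seq_len(p$n_regions), function(j) {
      pool <- reg_sets[[j]]
      if (length(pool) < 5L) return(NULL)
      tibble(gene_id = sample(pool, min(8L, length(pool))),
             domain_id = sprintf("DUFP%03d", j), region = j)
    }) |> bind_rows()
    random <- purrr::map(seq_len(20L), function(d) {
      tibble(gene_id = sample(design$gene_ids, stats::rpois(1L, 6L) + 2L),
             domain_id = sprintf("DOM%03d", d), region = NA_integer_)
    }) |> bind_rows()
    all <- bind_rows(planted, random)
    list(domains = distinct(all |> select("gene_id", "domain_id")),
         planted = distinct(planted |> select("domain_id", "region")))
  })
}

#' Generate a complete synthetic two-species tomo-seq experiment
#'
#' Produces every input the pipeline consumes — per-specimen count matrices
#' for both species, marker and ladder configurations, homology hit tables
#' for orthology and phylostratigraphy, a protein-domain table and an
#' ortholog-cluster rates table — together with the full ground truth
#' (region boundaries, regional genes, ortholog pairs, strata, true omega
#' draws). The same seed reproduces the experiment bit-identically; each
#' component draws from its own sub-seed derived from `seed`, so components
#' can be regenerated independently.
#'
#' @param params list from [synth_params()].
#' @param seed integer seed governing all randomness.
#' @return a `synth_experiment` list: `species` (per species: `counts`,
#'   `marker_cfg`, `design`), `ladder`, `protein_hits`, `nucleotide_hits`,
#'   `rbh_hits`, `domains`, `rates`, `taxon_map`, and `truth`.
#' @export
generate_experiment <- function(params = synth_params(), seed = 1L) {
  p <- params
  design_a <- synth_species_design(p, p$species[1L], component_seed(seed, 1L))
  n_orth <- round(p$ortholog_fraction * p$n_genes)
  design_b <- synth_species_design(
    p, p$species[2L], component_seed(seed, 2L),
    copy_from = list(ortholog_idx = seq_len(n_orth),
                     regional = design_a$regional, home = design_a$home)
  )
  species <- list()
  truth_boundaries <- list()
  for (si in 1:2) {
    design <- if (si == 1L) design_a else design_b
    runs <- purrr::map(seq_len(p$n_specimens), function(k) {
      synth_counts_one(p, design, sprintf("%s_w%d", design$species, k),
                       component_seed(seed, 10L * si + k))
    })
    species[[design$species]] <- list(
      counts = purrr::map(runs, "counts"),
      marker_cfg = synth_marker_config(p, design$species, design$markers),
      design = design
    )
    truth_boundaries[[design$species]] <- purrr::imap(
      purrr::map(runs, "region_of"),
      function(region_of, k) {
        r <- rle(region_of)
        ends <- cumsum(r$lengths)
        tibble(specimen = sprintf("%s_w%d", design$species, k),
               region = design$labels[r$values],
               start = ends - r$lengths + 1L, end = ends)
      }
    ) |> bind_rows()
  }
  ages <- synth_ages_and_hits(p, design_a, component_seed(seed, 30L))
  pairs <- tibble(gene_a = design_a$gene_ids[seq_len(n_orth)],
                  gene_b = design_b$gene_ids[seq_len(n_orth)])
  rbh_hits <- synth_rbh_hits(p, design_a, design_b, n_orth,
                             component_seed(seed, 31L))
  doms <- synth_domains(p, design_a, component_seed(seed, 32L))
  rates <- synth_rates(p, pairs, ages$strata, component_seed(seed, 33L))

  regional_pairs <- function(design) {
    genes <- tibble(
      gene_id = design$gene_ids[design$regional],
      region = design$labels[design$home[design$regional]]
    )
    mk <- tibble(gene_id = design$markers$gene_id,
                 region = design$labels[design$markers$region])
    bind_rows(genes, mk) |> distinct()
  }
  truth <- list(
    seed = seed, params = p,
    boundaries = bind_rows(truth_boundaries),
    regional = setNames(
      purrr::map(species, function(s) regional_pairs(s$design)),
      names(species)
    ),
    orthologs = pairs,
    strata = tibble(gene_id = names(ages$strata),
                    stratum = unname(ages$strata)),
    sperm_region_labels = design_a$labels[p$sperm_regions],
    planted_domains = doms$planted |>
      mutate(region = design_a$labels[.data$region]),
    rates = rates$truth
  )
  structure(
    list(species = species, ladder = ages$ladder,
         protein_hits = ages$protein_hits,
         nucleotide_hits = ages$nucleotide_hits,
         rbh_hits = rbh_hits, domains = doms$domains, rates = rates$rates,
         taxon_map = setNames(p$species, paste0(p$species, "_")),
         truth = truth),
    class = "synth_experiment"
  )
}

#' @export
print.synth_experiment <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "<synth_experiment> seed %d: %s/%s, %d specimens x %d sections, %d genes, %d regions\n",
    x$truth$seed, p$species[1L], p$species[2L], p$n_specimens, p$n_sections,
    p$n_genes, p$n_regions))
  invisible(x)
}

#' Write a synthetic experiment to an input directory
#'
#' Writes every table in the plain-text formats the readers consume:
#' per-specimen count TSVs, marker/ladder YAML configs, hit tables
#' (reduced 6-column), domain and rates TSVs, and the ground truth as JSON.
#'
#' @param exp a `synth_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  for (sp in names(exp$species)) {
    s <- exp$species[[sp]]
    for (sc in s$counts) {
      write_section_counts(sc, fp(sprintf("counts_%s.tsv", sc$specimen_id)))
    }
    write_marker_config(s$marker_cfg, fp(sprintf("markers_%s.yaml", sp)))
  }
  write_ladder_config(exp$ladder, fp("ladder.yaml"))
  write_hit_table(exp$protein_hits, fp("protein_hits.tsv"))
  write_hit_table(exp$nucleotide_hits, fp("nucleotide_hits.tsv"))
  write_hit_table(exp$rbh_hits, fp("rbh_hits.tsv"))
  write_domain_table(exp$domains, fp("domains.tsv"))
  write_rates_table(exp$rates, fp("rates.tsv"))
  truth <- exp$truth
  truth$params$species <- as.list(truth$params$species)
  jsonlite::write_json(truth, fp("truth.json"), digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
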