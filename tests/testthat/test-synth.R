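small_params <- function(...) {
  synth_params(n_specimens = 2L, n_sections = 24L, n_genes = 300L,
               n_sperm_markers = 6L, ...)
}

test_that("the same seed reproduces the experiment bit-identically", {
  e1 <- generate_experiment(small_params(), seed = 5L)
  e2 <- generate_experiment(small_params(), seed = 5L)
  expect_identical(e1, e2)
  e3 <- generate_experiment(small_params(), seed = 6L)
  expect_false(identical(e1$species$Ppa$counts[[1L]]$counts,
                         e3$species$Ppa$counts[[1L]]$counts))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_experiment(e1, d1)
  write_experiment(e2, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("every generated table passes the io validators on reload", {
  exp <- generate_experiment(small_params(), seed = 3L)
  dir <- withr::local_tempdir()
  write_experiment(exp, dir)
  tm <- exp$taxon_map
  sc <- read_section_counts(file.path(dir, "counts_Ppa_w1.tsv"))
  expect_s3_class(sc, "section_counts")
  expect_equal(dim(sc$counts), dim(exp$species$Ppa$counts[[1L]]$counts))
  hits <- read_hit_table(file.path(dir, "rbh_hits.tsv"), tm, "reduced6")
  expect_equal(nrow(hits), nrow(exp$rbh_hits))
  prot <- read_hit_table(file.path(dir, "protein_hits.tsv"), tm, "reduced6",
                         target_is_taxon = TRUE)
  expect_true(all(prot$evalue >= 0))
  expect_equal(read_rates_table(file.path(dir, "rates.tsv")), exp$rates)
  expect_equal(read_domain_table(file.path(dir, "domains.tsv")), exp$domains)
  mc <- read_marker_config(file.path(dir, "markers_Cel.yaml"))
  expect_equal(mc$label, exp$species$Cel$marker_cfg$label)
  lad <- read_ladder_config(file.path(dir, "ladder.yaml"))
  expect_equal(lad$strata, exp$ladder$strata)
})

test_that("planted structure honours its own declared parameters", {
  p <- small_params()
  exp <- generate_experiment(p, seed = 9L)
  tr <- exp$truth
  # boundaries tile every specimen's sections in region order
  for (w in unique(tr$boundaries$specimen)) {
    b <- tr$boundaries[tr$boundaries$specimen == w, ]
    expect_equal(b$start[1L], 1L)
    expect_equal(b$end[nrow(b)], p$n_sections)
    expect_true(all(b$start[-1L] == head(b$end, -1L) + 1L))
  }
  # two-peak marker config: sperm regions share the msp set, ordinals 1 and 2
  mc <- exp$species$Ppa$marker_cfg
  sperm_labels <- tr$sperm_region_labels
  expect_equal(mc$peak[match(sperm_labels, mc$label)], c(1L, 2L))
  expect_identical(mc$markers[[match(sperm_labels[1L], mc$label)]],
                   mc$markers[[match(sperm_labels[2L], mc$label)]])
  # one indirect region flanked by marker-defined anchors
  expect_equal(sum(mc$kind == "indirect"), 1L)
  # rates: the true partner has the smallest dS among defined-omega rows
  defined <- exp$rates[!is.na(exp$rates$omega), ]
  by_gene <- split(defined$dS, defined$gene_a)
  truth_ds <- setNames(
    exp$rates$dS[match(paste(tr$rates$gene_a, tr$rates$true_partner),
                       paste(exp$rates$gene_a, exp$rates$gene_b))],
    tr$rates$gene_a)
  for (g in names(truth_ds)) {
    expect_equal(truth_ds[[g]], min(by_gene[[g]]))
  }
})

test_that("generated reference age distribution is close to the configured one", {
  p <- synth_params()  # full size: 3,000 genes
  exp <- generate_experiment(p, seed = 11L)
  strata <- exp$truth$strata
  plain <- strata$gene_id %in% sprintf("%s_g%04d", "Ppa", seq_len(p$n_genes))
  emp <- tabulate(strata$stratum[plain], length(p$stratum_distribution)) /
    sum(plain)
  tv <- sum(abs(emp - p$stratum_distribution)) / 2
  expect_lt(tv, 0.05)
})

test_that("a pipeline that reproduces the truth scores perfect recovery", {
  p <- small_params()
  exp <- generate_experiment(p, seed = 2L)
  tr <- exp$truth
  design <- exp$species$Ppa$design
  genes <- c(design$gene_ids, unique(design$markers$gene_id))
  regions <- design$labels
  regional <- matrix(FALSE, length(genes), length(regions),
                     dimnames = list(genes, regions))
  pairs <- tr$regional$Ppa
  regional[cbind(pairs$gene_id, pairs$region)] <- TRUE
  rp <- structure(list(
    gene_ids = genes, regions = regions,
    median_z = ifelse(regional, 2, 0),
    median_norm = matrix(1e-4, length(genes), length(regions),
                         dimnames = dimnames(regional)),
    expressed = regional | TRUE, regional = regional
  ), class = "region_profile")
  rep <- evaluate_recovery(
    exp$truth,
    profiles = list(Ppa = rp),
    orthologs = tr$orthologs,
    ages = tibble::tibble(gene_id = tr$strata$gene_id,
                          stratum = tr$strata$stratum, stratum_name = "x")
  )
  rec <- rep$regional_recovery
  expect_equal(rec$f1[rec$level == "gene_region"], 1)
  expect_equal(rec$f1[rec$level == "gene"], 1)
  expect_equal(rep$ortholog_recovery$f1, 1)
  expect_equal(rep$stratum_accuracy, 1)
})

test_that("stratum assignment from generated hits is exact (decoys never qualify)", {
  p <- small_params()
  exp <- generate_experiment(p, seed = 4L)
  ages <- assign_phylostrata(exp$protein_hits, exp$nucleotide_hits,
                             exp$ladder, universe = exp$truth$strata$gene_id)
  rep <- evaluate_recovery(exp$truth, ages = ages)
  expect_equal(rep$stratum_accuracy, 1)
  # mismatched universes are rejected
  bad <- ages
  bad$gene_id[1L] <- "alien_gene"
  expect_error(evaluate_recovery(exp$truth, ages = bad), "universe")
})

test_that("infeasible generator parameters are rejected", {
  expect_error(synth_params(n_regions = 50L, n_sections = 40L), "infeasible")
  expect_error(synth_params(n_sections = 12L, n_regions = 8L), "at least 2")
  expect_error(synth_params(stratum_distribution = c(0.5, 0.4)), "sum to 1")
  expect_error(synth_params(indirect_region = 1L), "interior")
})
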