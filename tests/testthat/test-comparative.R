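test_that("fisher_exact_2x2 matches enumeration and handles degenerate tables", {
  expect_equal(fisher_exact_2x2(c(0, 0, 0, 0))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2L))$p, 0.1)  # 2/20 tables
  expect_equal(fisher_exact_2x2(c(1, 1, 1, 1))$p, 1)

  tab <- c(2, 7, 8, 2)
  expect_equal(fisher_exact_2x2(tab)$p,
               oracle_fisher_two_sided(2, 7, 8, 2), tolerance = 1e-12)
  # agreement with the independent stats implementation on random tables
  set.seed(21)
  for (i in 1:50) {
    t4 <- rpois(4L, 6)
    expect_equal(fisher_exact_2x2(t4)$p,
                 fisher.test(matrix(t4, 2L))$p.value, tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(c(3, 0, 0, 3))$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(c(-1, 1, 1, 1)), "non-negative")
  # one-sided greater = upper hypergeometric tail
  expect_equal(fisher_exact_2x2(c(4, 1, 1, 4), alternative = "greater")$p,
               fisher.test(matrix(c(4, 1, 1, 4), 2L),
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("bh_fdr is the BH step-up and is permutation-stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5L)), rep(1, 5L))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1L))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])  # q returned in input order
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted-p order
  }
})

test_that("reciprocal-best-hit calls follow definition and tie rules", {
  hit <- function(q, t, ev, bs = 100) {
    tibble::tibble(query_id = q, target_id = t,
                   query_taxon = ifelse(startsWith(q, "a"), "A", "B"),
                   target_taxon = ifelse(startsWith(t, "a"), "A", "B"),
                   evalue = ev, bitscore = bs)
  }
  hits <- dplyr::bind_rows(
    hit("a1", "b1", 1e-40), hit("b1", "a1", 1e-40),  # mutual pair
    hit("a2", "b1", 1e-50), hit("b2", "a2", 1e-30),  # a2 -> b1 unrequited
    hit("a3", "b3", 1e-20), hit("b3", "a3", 1e-20),
    hit("a3", "a9", 1e-25)                           # within-species dominator
  )
  om <- call_rbh_orthologs(hits, "A", "B")
  expect_equal(om$gene_a, "a1")
  expect_equal(om$gene_b, "b1")
  # without inparalog rejection a3-b3 is recovered too
  om2 <- call_rbh_orthologs(hits, "A", "B",
                            reject_if_within_species_hit_better = FALSE)
  expect_setequal(om2$gene_a, c("a1", "a3"))

  # equal e-values: higher bitscore wins
  tie <- dplyr::bind_rows(hit("a1", "b1", 1e-10, bs = 100),
                          hit("a1", "b2", 1e-10, bs = 150),
                          hit("b2", "a1", 1e-10, bs = 150))
  omt <- call_rbh_orthologs(tie, "A", "B")
  expect_equal(omt$gene_b, "b2")

  # self-hits and above-threshold hits are ignored; empty input is fine
  noise <- dplyr::bind_rows(hit("a1", "a1", 1e-80), hit("a1", "b1", 0.5))
  expect_equal(nrow(call_rbh_orthologs(noise, "A", "B")), 0L)
})

test_that("RBH matches the brute-force scan and is symmetric in species order", {
  set.seed(31)
  for (i in 1:25) {
    hits <- random_hit_table(n_a = sample(5:20, 1L), n_b = sample(5:20, 1L),
                             n_hits = sample(40:150, 1L))
    got <- call_rbh_orthologs(hits, "A", "B", max_evalue = 1e-3)
    want <- oracle_rbh(hits, "A", "B", max_evalue = 1e-3)
    expect_setequal(paste(got$gene_a, got$gene_b),
                    paste(want$gene_a, want$gene_b))
    swapped <- call_rbh_orthologs(hits, "B", "A", max_evalue = 1e-3)
    expect_setequal(paste(got$gene_a, got$gene_b),
                    paste(swapped$gene_b, swapped$gene_a))
  }
})

make_region_profile <- function(regional, expressed = NULL, median_norm = NULL) {
  genes <- rownames(regional)
  regions <- colnames(regional)
  if (is.null(expressed)) expressed <- matrix(TRUE, nrow(regional), ncol(regional),
                                              dimnames = dimnames(regional))
  if (is.null(median_norm)) median_norm <- expressed * 1e-4
  structure(list(gene_ids = genes, regions = regions,
                 median_z = ifelse(regional, 2, -1),
                 median_norm = median_norm,
                 expressed = expressed, regional = regional),
            class = "region_profile")
}

test_that("within-species overlap of a region with itself is its regional count", {
  set.seed(12)
  regional <- matrix(runif(60L) < 0.3, 20L, 3L,
                     dimnames = list(sprintf("g%02d", 1:20), c("R1", "R2", "R3")))
  rp <- make_region_profile(regional)
  res <- region_overlap_tests(rp)
  for (r in rp$regions) {
    self <- res[res$region_a == r & res$region_b == r, ]
    expect_equal(self$k, sum(regional[, r]))
  }
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("cross-species overlap flags the conserved region pair", {
  genes_a <- sprintf("a%02d", 1:40)
  genes_b <- sprintf("b%02d", 1:40)
  reg_a <- matrix(FALSE, 40L, 2L, dimnames = list(genes_a, c("P1", "P2")))
  reg_b <- matrix(FALSE, 40L, 2L, dimnames = list(genes_b, c("C1", "C2")))
  reg_a[1:10, "P1"] <- TRUE   # orthologous genes 1-10 regional in P1 and C1
  reg_b[1:10, "C1"] <- TRUE
  reg_a[11:15, "P2"] <- TRUE  # disjoint memberships elsewhere
  reg_b[16:20, "C2"] <- TRUE
  orth <- tibble::tibble(gene_a = genes_a, gene_b = genes_b)
  res <- region_overlap_tests(make_region_profile(reg_a),
                              make_region_profile(reg_b), orth)
  top <- res[which.min(res$q), ]
  expect_equal(top$region_a, "P1")
  expect_equal(top$region_b, "C1")
  expect_equal(top$k, 10L)
  expect_lt(top$q, 0.05)
  # disjoint memberships share nothing and are unremarkable
  empty <- res[res$region_a == "P2" & res$region_b == "C2", ]
  expect_equal(empty$k, 0L)
  expect_gt(empty$p, 0.1)
  # cross-species mode requires an ortholog map
  expect_error(region_overlap_tests(make_region_profile(reg_a),
                                    make_region_profile(reg_b)),
               "orthologs")
})

test_that("domain enrichment finds a fully nested domain and not singletons", {
  set.seed(6)
  n <- 600L
  genes <- sprintf("g%03d", seq_len(n))
  regional <- matrix(FALSE, n, 2L, dimnames = list(genes, c("R1", "R2")))
  regional[1:50, "R1"] <- TRUE
  regional[51:100, "R2"] <- TRUE
  rp <- make_region_profile(regional)
  domains <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes[1:5], domain_id = "NEST"),     # inside R1
    tibble::tibble(gene_id = genes[300], domain_id = "SINGLE"),   # one member
    tibble::tibble(gene_id = sample(genes, 30L), domain_id = "RAND")
  )
  res <- domain_enrichment(rp, domains)
  nest <- res[res$region == "R1" & res$domain == "NEST", ]
  expect_equal(nest$k, 5L)
  expect_lt(nest$q, 0.05)
  single <- res[res$domain == "SINGLE", ]
  expect_true(all(single$q > 0.05))  # one gene can never be significant alone
  # a region with an empty regional set gets p = 1 everywhere
  rp2 <- make_region_profile(cbind(regional[, 1L, drop = FALSE],
                                   R3 = rep(FALSE, n)))
  res2 <- domain_enrichment(rp2, domains)
  expect_true(all(res2$p[res2$region == "R3"] == 1))
  # cumulative expression sums the members' median normalized counts
  expect_equal(nest$cumulative_expression, sum(rp$median_norm[genes[1:5], "R1"]))
})

test_that("domains outside the expressed universe are skipped with a warning", {
  regional <- matrix(c(TRUE, FALSE), 2L, 1L,
                     dimnames = list(c("g1", "g2"), "R1"))
  expressed <- matrix(c(TRUE, TRUE), 2L, 1L, dimnames = dimnames(regional))
  rp <- make_region_profile(regional, expressed)
  domains <- tibble::tibble(gene_id = c("g1", "zz"),
                            domain_id = c("PFA", "PFGONE"))
  expect_warning(res <- domain_enrichment(rp, domains), "PFGONE")
  expect_equal(unique(res$domain), "PFA")
})

test_that("region clustering by orthologs pairs up conserved regions", {
  genes_a <- sprintf("a%02d", 1:30)
  genes_b <- sprintf("b%02d", 1:30)
  regions <- c("R1", "R2", "R3")
  set.seed(44)
  base <- matrix(rnorm(90L), 30L, 3L)
  mz_a <- base + matrix(rnorm(90L, sd = 0.05), 30L, 3L)
  mz_b <- base + matrix(rnorm(90L, sd = 0.05), 30L, 3L)
  dimnames(mz_a) <- list(genes_a, regions)
  dimnames(mz_b) <- list(genes_b, regions)
  rp_a <- make_region_profile(mz_a > 1)
  rp_a$median_z <- mz_a
  rp_b <- make_region_profile(mz_b > 1)
  rp_b$median_z <- mz_b
  orth <- tibble::tibble(gene_a = genes_a, gene_b = genes_b)
  hc <- cluster_regions_by_orthologs(rp_a, rp_b, orth, "spA", "spB")
  # homologous regions merge first: each of the 3 first merges joins
  # spA:Rk with spB:Rk
  merges <- stats::cutree(hc, k = 3L)
  for (r in regions) {
    expect_equal(merges[[paste0("spA:", r)]], merges[[paste0("spB:", r)]])
  }
  # no qualifying pairs is an error
  rp0 <- rp_a
  rp0$regional[] <- FALSE
  rp_b0 <- rp_b
  rp_b0$regional[] <- FALSE
  expect_error(cluster_regions_by_orthologs(
    rp0, rp_b0, tibble::tibble(gene_a = character(), gene_b = character())),
    "ortholog")
})

test_that("section clustering separates planted transcriptome states", {
  set.seed(17)
  n_genes <- 80L
  state1 <- rnorm(n_genes)
  state2 <- rnorm(n_genes)
  z <- cbind(s1 = state1 + rnorm(n_genes, sd = 0.1),
             s2 = state1 + rnorm(n_genes, sd = 0.1),
             s3 = state2 + rnorm(n_genes, sd = 0.1),
             s4 = state2 + rnorm(n_genes, sd = 0.1))
  rownames(z) <- sprintf("g%02d", seq_len(n_genes))
  zp <- toy_zprofile(z)
  hc <- cluster_sections(list(zp))
  groups <- stats::cutree(hc, k = 2L)
  expect_equal(groups[["w1:s1"]], groups[["w1:s2"]])
  expect_equal(groups[["w1:s3"]], groups[["w1:s4"]])
  expect_false(groups[["w1:s1"]] == groups[["w1:s3"]])
  # identical sections merge at height 0; inverted profiles at distance 2
  z2 <- cbind(s1 = state1, s2 = state1, s3 = -state1)
  rownames(z2) <- rownames(z)
  hc2 <- cluster_sections(list(toy_zprofile(z2)))
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)
  expect_equal(max(hc2$height), 2, tolerance = 1e-12)
})
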