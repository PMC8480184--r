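# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the functions they verify.

# two-sided Fisher p by explicit hypergeometric enumeration with binomial
# coefficients (probability-ordering rule, 1e-7 relative tie tolerance)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# direct BH step-up with monotonicity enforcement
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# stratum per gene by scanning every hit row
oracle_phylostrata <- function(protein_hits, nucleotide_hits, ladder, universe) {
  taxon_stratum <- setNames(
    rep(seq_along(ladder$strata), lengths(ladder$strata)),
    unlist(ladder$strata)
  )
  vapply(universe, function(g) {
    best <- 1L
    if (nrow(protein_hits)) {
      for (i in seq_len(nrow(protein_hits))) {
        if (protein_hits$query_id[i] == g &&
            protein_hits$evalue[i] < ladder$protein_threshold) {
          best <- max(best, taxon_stratum[[protein_hits$target_taxon[i]]])
        }
      }
    }
    if (!is.null(nucleotide_hits) && nrow(nucleotide_hits)) {
      for (i in seq_len(nrow(nucleotide_hits))) {
        if (nucleotide_hits$query_id[i] == g &&
            nucleotide_hits$evalue[i] < ladder$nucleotide_threshold) {
          best <- max(best, taxon_stratum[[nucleotide_hits$target_taxon[i]]])
        }
      }
    }
    best
  }, integer(1L))
}

# O(n^2) reciprocal-best scan over the raw hit rows
oracle_rbh <- function(hits, taxon_a, taxon_b, max_evalue = 1e-3,
                       reject_within = TRUE) {
  h <- hits[hits$query_id != hits$target_id & hits$evalue < max_evalue &
              hits$query_taxon %in% c(taxon_a, taxon_b) &
              hits$target_taxon %in% c(taxon_a, taxon_b), , drop = FALSE]
  best_of <- function(gene, cross) {
    rows <- h[h$query_id == gene &
                (if (cross) h$query_taxon != h$target_taxon
                 else h$query_taxon == h$target_taxon), , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$target_id), , drop = FALSE]
    rows[1L, ]
  }
  genes_a <- sort(unique(h$query_id[h$query_taxon == taxon_a]))
  pairs <- list()
  for (g in genes_a) {
    ba <- best_of(g, cross = TRUE)
    if (is.null(ba)) next
    bb <- best_of(ba$target_id, cross = TRUE)
    if (is.null(bb) || bb$target_id != g) next
    if (reject_within) {
      dominated <- function(gene, cb) {
        wb <- best_of(gene, cross = FALSE)
        !is.null(wb) && (wb$evalue < cb$evalue ||
                           (wb$evalue == cb$evalue && wb$bitscore > cb$bitscore))
      }
      if (dominated(g, ba) || dominated(ba$target_id, bb)) next
    }
    pairs[[length(pairs) + 1L]] <- c(g, ba$target_id)
  }
  if (!length(pairs)) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  out <- do.call(rbind, pairs)
  data.frame(gene_a = out[, 1L], gene_b = out[, 2L])
}

# longest stop-free codon substring over all 3 forward frames, enumerated
# with cumulative stop counts over every (frame, start, end) window
oracle_orf <- function(seq) {
  tab <- setNames(as.character(Biostrings::GENETIC_CODE),
                  names(Biostrings::GENETIC_CODE))
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- ""
  best_start <- Inf
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1L) next
    starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    aa <- tab[substring(seq, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    stops <- cumsum(aa == "*")
    for (i in seq_len(n_codons)) {
      ok <- which(stops[i:n_codons] - (if (i > 1L) stops[i - 1L] else 0L) == 0L)
      if (!length(ok)) next
      len <- max(ok)  # longest stop-free window starting at codon i
      if (len > nchar(best) ||
          (len == nchar(best) && starts[i] < best_start)) {
        best <- paste(aa[i:(i + len - 1L)], collapse = "")
        best_start <- starts[i]
      }
    }
  }
  best
}

# small random fixtures -------------------------------------------------------

random_section_counts <- function(n_genes = 20L, n_sections = 6L,
                                  specimen = "w1") {
  m <- matrix(rpois(n_genes * n_sections, lambda = 8), n_genes, n_sections,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_sections))))
  section_counts(m, specimen_id = specimen)
}

random_hit_table <- function(n_a = 15L, n_b = 15L, n_hits = 120L) {
  ga <- sprintf("A_g%02d", seq_len(n_a))
  gb <- sprintf("B_g%02d", seq_len(n_b))
  all_genes <- c(ga, gb)
  q <- sample(all_genes, n_hits, replace = TRUE)
  t <- sample(all_genes, n_hits, replace = TRUE)
  tibble::tibble(
    query_id = q, target_id = t,
    query_taxon = ifelse(startsWith(q, "A_"), "A", "B"),
    target_taxon = ifelse(startsWith(t, "A_"), "A", "B"),
    evalue = 10^-runif(n_hits, 0, 30),
    bitscore = round(runif(n_hits, 30, 300), 1)
  )
}

toy_zprofile <- function(z, specimen = "w1") {
  # wrap an explicit z matrix (genes x sections) as a z_profile for
  # peak/segmentation tests; normalized filled with uniform positives
  structure(
    list(specimen_id = specimen,
         gene_ids = rownames(z), section_ids = colnames(z),
         normalized = matrix(1 / nrow(z), nrow(z), ncol(z),
                             dimnames = dimnames(z)),
         z = z),
    class = "z_profile"
  )
}
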