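# Complete-linkage clustering on 1 - Pearson correlation. Columns of `m` are
# the objects; genes with undefined values are dropped pairwise. Determinism:
# columns are sorted lexicographically by label before clustering so hclust's
# order-dependent tie handling cannot vary between runs.
pearson_hclust <- function(m, warn_prefix = "object") {
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 2L, sd, na.rm = TRUE)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate)) {
    warn(paste0("Excluding zero-variance ", warn_prefix, "s: ",
                paste(colnames(m)[degenerate], collapse = ", ")))
    m <- m[, !degenerate, drop = FALSE]
  }
  if (ncol(m) < 2L) abort("Need at least 2 objects with variance to cluster.")
  cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (anyNA(cc)) abort("Some object pairs share no defined values; cannot compute correlation.")
  hclust(as.dist(1 - cc), method = "complete")
}

#' Cluster sections across specimens by transcriptome correlation
#'
#' Sections from all specimens are clustered by complete linkage on
#' 1 - Pearson correlation of their z-score columns, computed over genes with
#' defined z in both sections. Sections in the same anatomical region are
#' expected to co-cluster. Leaves are labelled `specimen:section`.
#'
#' @param zps list of `z_profile`s.
#' @return an [stats::hclust] tree.
#' @export
cluster_sections <- function(zps) {
  genes <- Reduce(intersect, purrr::map(zps, "gene_ids"))
  cols <- purrr::map(zps, function(zp) {
    m <- zp$z[genes, , drop = FALSE]
    colnames(m) <- paste0(zp$specimen_id, ":", zp$section_ids)
    m
  })
  m <- do.call(cbind, cols)
  if (ncol(m) < 2L) abort("Need at least 2 sections.")
  pearson_hclust(m, warn_prefix = "section")
}

#' Cluster regions of two species on one-to-one ortholog profiles
#'
#' Every region of both species is represented by the pooled median z-scores
#' of the filtered one-to-one ortholog pairs (the species-a member for
#' a-regions, its partner for b-regions), and the combined region set is
#' clustered by complete linkage on 1 - Pearson. Pairs qualify when at least
#' one member is a regional gene somewhere in its species.
#'
#' @param rp_a,rp_b `region_profile`s of the two species.
#' @param orthologs tibble (`gene_a`, `gene_b`) of one-to-one pairs, with
#'   `gene_a` from the species of `rp_a`.
#' @param species_a,species_b labels used to prefix region names.
#' @return an [stats::hclust] tree over the regions of both species.
#' @export
cluster_regions_by_orthologs <- function(rp_a, rp_b, orthologs,
                                         species_a = "a", species_b = "b") {
  pairs <- orthologs |>
    filter(.data$gene_a %in% rp_a$gene_ids, .data$gene_b %in% rp_b$gene_ids)
  if (nrow(pairs)) {
    keep <- rowSums(rp_a$regional[pairs$gene_a, , drop = FALSE]) > 0 |
      rowSums(rp_b$regional[pairs$gene_b, , drop = FALSE]) > 0
    pairs <- pairs[keep, ]
  }
  if (nrow(pairs) == 0L) abort("No ortholog pairs pass the regional filter.")
  ma <- rp_a$median_z[pairs$gene_a, , drop = FALSE]
  mb <- rp_b$median_z[pairs$gene_b, , drop = FALSE]
  colnames(ma) <- paste0(species_a, ":", rp_a$regions)
  colnames(mb) <- paste0(species_b, ":", rp_b$regions)
  pearson_hclust(cbind(ma, mb), warn_prefix = "region")
}

#' Export a dendrogram as Newick
#'
#' @param hc an [stats::hclust] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
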