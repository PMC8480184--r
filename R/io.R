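#' Section count matrices
#'
#' A `section_counts` object holds one specimen's gene-by-section matrix of
#' raw transcript counts. Columns are cryosections in their physical
#' anterior-to-posterior cutting order; that order is significant and is
#' preserved by all readers and writers.
#'
#' @param counts integer matrix, genes as rows (rownames = gene ids), sections
#'   as columns (colnames = section ids, anterior first).
#' @param specimen_id single string naming the specimen.
#' @return A `section_counts` object.
#' @export
section_counts <- function(counts, specimen_id = "specimen") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene ids as rownames and section ids as colnames.")
  }
  if (ncol(counts) < 2L) {
    abort("A section-count matrix needs at least 2 sections.")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    abort(paste0("Duplicate gene ids: ", paste(head(dup, 5L), collapse = ", ")))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    abort(sprintf(
      "Counts must be non-negative integers; offending cell at gene '%s', section '%s' (value %s).",
      rownames(counts)[i[1L]], colnames(counts)[i[2L]], format(counts[bad[1L]])
    ))
  }
  storage.mode(counts) <- "integer"
  structure(
    list(specimen_id = as.character(specimen_id)[1L], counts = counts),
    class = "section_counts"
  )
}

#' @export
print.section_counts <- function(x, ...) {
  cat(sprintf(
    "<section_counts> specimen '%s': %d genes x %d sections (A-P)\n",
    x$specimen_id, nrow(x$counts), ncol(x$counts)
  ))
  invisible(x)
}

#' @export
dim.section_counts <- function(x) dim(x$counts)

#' Read a gene-by-section count matrix
#'
#' Reads a tab-separated count file: header row of section ids (in
#' anterior-to-posterior order), first column of gene ids, integer cells.
#' The file's column order is taken as the physical A-P cutting order.
#'
#' @param path path to a TSV file.
#' @param specimen_id specimen name; defaults to the file name without
#'   extension.
#' @return A [section_counts()] object.
#' @export
read_section_counts <- function(path, specimen_id = NULL) {
  specimen_id <- specimen_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) abort("Count file needs a gene-id column plus >= 2 sections.")
  gene_ids <- df[[1L]]
  mat <- as.matrix(df[-1L])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(gene_ids, colnames(mat))))
  bad <- which(is.na(num) | num < 0 | num != floor(num))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(num))
    abort(sprintf(
      "Non-integer or negative count at gene '%s', section '%s' (value '%s') in %s.",
      gene_ids[i[1L]], colnames(num)[i[2L]], mat[bad[1L]], path
    ))
  }
  section_counts(num, specimen_id = specimen_id)
}

#' Write a gene-by-section count matrix
#'
#' @param sc a [section_counts()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_section_counts <- function(sc, path) {
  stopifnot(inherits(sc, "section_counts"))
  df <- data.frame(gene_id = rownames(sc$counts), sc$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve gene ids to taxa through ordered prefix rules (longest prefix wins).
resolve_taxon <- function(ids, taxon_map) {
  prefixes <- names(taxon_map)[order(-nchar(names(taxon_map)))]
  out <- rep(NA_character_, length(ids))
  for (p in prefixes) {
    hit <- is.na(out) & startsWith(ids, p)
    out[hit] <- taxon_map[[p]]
  }
  if (anyNA(out)) {
    abort(paste0(
      "Cannot resolve taxon for ids: ",
      paste(head(unique(ids[is.na(out)]), 5L), collapse = ", ")
    ))
  }
  out
}

#' Read a homology hit table
#'
#' Reads BLAST-style tabular hits. Two dialects are supported:
#' `"blast12"`, the standard outfmt-6 layout
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), and `"reduced6"`
#' (qseqid sseqid pident length evalue bitscore). All rows are retained,
#' including hits above any downstream e-value threshold, and including
#' duplicates and self-hits; filtering is the caller's job.
#'
#' Taxa are resolved from gene-id prefixes via `taxon_map`, a named character
#' vector mapping id prefix to taxon name (e.g. `c(Ppa_ = "Ppa")`); ids that
#' match no prefix raise an error. Alternatively `target_is_taxon = TRUE`
#' treats the target column itself as a taxon name (phylostratigraphy-style
#' per-species databases).
#'
#' @param path TSV path (no header).
#' @param taxon_map named character vector of id-prefix -> taxon rules.
#' @param format `"blast12"` or `"reduced6"`.
#' @param target_is_taxon if `TRUE`, `target_taxon` is the target id itself
#'   and `taxon_map` is only applied to queries.
#' @return tibble with columns `query_id`, `target_id`, `query_taxon`,
#'   `target_taxon`, `evalue`, `bitscore`; row order as in the file.
#' @export
read_hit_table <- function(path, taxon_map,
                           format = c("blast12", "reduced6"),
                           target_is_taxon = FALSE) {
  format <- match.arg(format)
  ncols <- if (format == "blast12") 12L else 6L
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(tibble(query_id = character(), target_id = character(),
                  query_taxon = character(), target_taxon = character(),
                  evalue = double(), bitscore = double()))
  }
  if (ncol(raw) != ncols) {
    abort(sprintf("Expected %d columns for dialect '%s', found %d in %s.",
                  ncols, format, ncol(raw), path))
  }
  ev_col <- if (format == "blast12") 11L else 5L
  bs_col <- if (format == "blast12") 12L else 6L
  out <- tibble(
    query_id = as.character(raw[[1L]]),
    target_id = as.character(raw[[2L]]),
    evalue = as.numeric(raw[[ev_col]]),
    bitscore = as.numeric(raw[[bs_col]])
  )
  if (any(!is.finite(out$evalue)) || any(out$evalue < 0)) {
    abort("e-values must be finite and non-negative.")
  }
  out$query_taxon <- resolve_taxon(out$query_id, taxon_map)
  out$target_taxon <- if (target_is_taxon) out$target_id else
    resolve_taxon(out$target_id, taxon_map)
  out[, c("query_id", "target_id", "query_taxon", "target_taxon",
          "evalue", "bitscore")]
}

#' Write a hit table in reduced 6-column form
#'
#' @param hits tibble as returned by [read_hit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  df <- data.frame(hits$query_id, hits$target_id, 100, 0,
                   sprintf("%.17g", hits$evalue),
                   sprintf("%.17g", hits$bitscore))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-protein-domain table
#'
#' Two tab-separated columns (gene id, domain accession), one row per
#' membership; duplicated (gene, domain) pairs are collapsed on load.
#'
#' @param path TSV path (no header).
#' @return tibble with columns `gene_id`, `domain_id`, deduplicated.
#' @export
read_domain_table <- function(path) {
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(tibble(gene_id = character(), domain_id = character()))
  }
  distinct(tibble(gene_id = raw[[1L]], domain_id = raw[[2L]]))
}

#' @rdname read_domain_table
#' @param domains tibble of (`gene_id`, `domain_id`).
#' @export
write_domain_table <- function(domains, path) {
  utils::write.table(as.data.frame(domains[, c("gene_id", "domain_id")]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ortholog-pair evolutionary-rates table
#'
#' Tab-separated with header: `gene_a`, `gene_b`, `dN`, `dS`, `omega`.
#' `omega` may be `NA` (undefined, e.g. when dS = 0). Where `dS > 0` and
#' `omega` is given, consistency `omega == dN/dS` is enforced to a relative
#' tolerance of 1e-6.
#'
#' @param path TSV path.
#' @return tibble (`gene_a`, `gene_b`, `dN`, `dS`, `omega`).
#' @export
read_rates_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("gene_a", "gene_b", "dN", "dS", "omega")
  if (!all(need %in% names(df))) {
    abort(paste0("Rates table must have columns: ", paste(need, collapse = ", ")))
  }
  out <- as_tibble(df[need])
  if (any(out$dN < 0, na.rm = TRUE) || any(out$dS < 0, na.rm = TRUE) ||
      any(out$omega < 0, na.rm = TRUE)) {
    abort("dN, dS and omega must be non-negative.")
  }
  chk <- !is.na(out$omega) & !is.na(out$dS) & out$dS > 0 & !is.na(out$dN)
  if (any(chk)) {
    rel <- abs(out$omega[chk] - out$dN[chk] / out$dS[chk]) /
      pmax(out$omega[chk], .Machine$double.eps)
    if (any(rel > 1e-6)) {
      i <- which(chk)[which(rel > 1e-6)[1L]]
      abort(sprintf("omega inconsistent with dN/dS at row %d ('%s'/'%s').",
                    i, out$gene_a[i], out$gene_b[i]))
    }
  }
  out
}

#' @rdname read_rates_table
#' @param rates tibble of rates rows; `omega` `NA`s are written as "NA".
#' @export
write_rates_table <- function(rates, path) {
  utils::write.table(as.data.frame(rates[, c("gene_a", "gene_b", "dN", "dS", "omega")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a nucleotide FASTA file
#'
#' @param path FASTA path.
#' @return tibble (`id`, `sequence`) with unique ids and uppercased sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA ids: ",
                 paste(head(unique(ids[duplicated(ids)]), 5L), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    abort(paste0("Empty sequence for id: ", ids[which(nchar(seqs) == 0L)[1L]]))
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs tibble (`id`, `sequence`).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
tidy.section_counts <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE)) |>
    rlang::set_names(c("gene_id", "section_id", "count")) |>
    mutate(specimen_id = x$specimen_id, .before = 1L)
}
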