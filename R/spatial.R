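#' Normalize section counts and compute per-gene z-score profiles
#'
#' Counts are divided by the total transcript count of their section, so every
#' retained section's normalized column sums to 1; sections with a zero total
#' (cryosection dropout) are dropped with a warning first. Each gene's
#' normalized profile is then z-scored across that specimen's sections
#' (mean 0, sample standard deviation 1, n-1 denominator, as `scale()` does).
#' Genes whose normalized profile is constant across sections have no defined
#' z-score and get an `NA` row; downstream pooling excludes such rows rather
#' than treating them as zero enrichment.
#'
#' @param sc a [section_counts()] object.
#' @return a `z_profile` object: list with `specimen_id`, `gene_ids`,
#'   `section_ids` (retained, A-P order), `normalized` and `z` matrices.
#' @export
normalize_and_zscore <- function(sc) {
  stopifnot(inherits(sc, "section_counts"))
  totals <- colSums(sc$counts)
  if (all(totals == 0)) abort("All section totals are zero; nothing to normalize.")
  if (any(totals == 0)) {
    warn(paste0("Dropping zero-total sections: ",
                paste(colnames(sc$counts)[totals == 0], collapse = ", ")))
  }
  keep <- totals > 0
  counts <- sc$counts[, keep, drop = FALSE]
  normalized <- sweep(counts, 2L, colSums(counts), "/")
  mu <- rowMeans(normalized)
  s <- apply(normalized, 1L, sd)  # sample sd, n-1 denominator
  z <- (normalized - mu) / s
  z[s == 0, ] <- NA_real_
  structure(
    list(specimen_id = sc$specimen_id,
         gene_ids = rownames(counts),
         section_ids = colnames(counts),
         normalized = normalized, z = z),
    class = "z_profile"
  )
}

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf("<z_profile> specimen '%s': %d genes x %d sections (%d constant genes)\n",
              x$specimen_id, length(x$gene_ids), length(x$section_ids),
              sum(is.na(x$z[, 1L]))))
  invisible(x)
}

#' @export
tidy.z_profile <- function(x, ...) {
  long <- function(m, value) {
    as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
      rlang::set_names(c("gene_id", "section_id", value))
  }
  left_join(long(x$normalized, "normalized"), long(x$z, "z"),
            by = c("gene_id", "section_id")) |>
    mutate(specimen_id = x$specimen_id, .before = 1L)
}

#' Detect marker peaks along the A-P axis
#'
#' The marker signal is the per-section mean of the available markers'
#' z-scores, smoothed by a running median of odd width `smooth_window`
#' (width 1 disables smoothing). Peaks are maximal contiguous runs of
#' sections whose smoothed signal exceeds `min_z`, reported anterior to
#' posterior; the peak section is the run's argmax (ties go to the most
#' anterior section).
#'
#' @param zp a `z_profile`.
#' @param markers character vector of marker gene ids; markers absent from
#'   the profile are skipped with a warning.
#' @param min_z peak threshold on the smoothed mean-marker z signal.
#' @param smooth_window odd running-median width.
#' @param merge_gap runs separated by at most this many below-threshold
#'   sections are bridged into one peak (default 1: a single dropout section
#'   inside an expression domain does not split it; gaps of two or more
#'   sections keep peaks separate).
#' @return tibble with one row per peak: `start`, `end`, `peak` (1-based
#'   section indices along the retained A-P axis), `peak_section` (section
#'   id) and `height` (smoothed signal at the peak). Zero rows if no section
#'   exceeds `min_z`.
#' @export
detect_marker_peaks <- function(zp, markers, min_z = 1, smooth_window = 3L,
                                merge_gap = 1L) {
  stopifnot(inherits(zp, "z_profile"))
  if (smooth_window %% 2L != 1L) abort("`smooth_window` must be odd.")
  present <- intersect(markers, zp$gene_ids)
  if (length(present) < length(markers)) {
    warn(paste0("Markers absent from profile, skipped: ",
                paste(setdiff(markers, present), collapse = ", ")))
  }
  if (!length(present)) abort("No marker genes present in the profile.")
  signal <- unname(colMeans(zp$z[present, , drop = FALSE], na.rm = TRUE))
  signal[!is.finite(signal)] <- min_z - 1  # sections where no marker has a defined z
  smoothed <- if (smooth_window > 1L && length(signal) >= smooth_window) {
    as.numeric(runmed(signal, smooth_window, endrule = "median"))
  } else signal
  above <- smoothed > min_z
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  run_start <- starts[keep]
  run_end <- ends[keep]
  if (merge_gap > 0L && length(keep) > 1L) {
    merged_s <- run_start[1L]; merged_e <- run_end[1L]
    for (i in seq_along(run_start)[-1L]) {
      if (run_start[i] - merged_e[length(merged_e)] - 1L <= merge_gap) {
        merged_e[length(merged_e)] <- run_end[i]
      } else {
        merged_s <- c(merged_s, run_start[i])
        merged_e <- c(merged_e, run_end[i])
      }
    }
    run_start <- merged_s; run_end <- merged_e
  }
  purrr::map(seq_along(run_start), function(i) {
    s <- run_start[i]; e <- run_end[i]
    pk <- s + which.max(smoothed[s:e]) - 1L  # which.max: first max = most anterior
    tibble(start = s, end = e, peak = pk,
           peak_section = zp$section_ids[pk], height = smoothed[pk])
  }) |>
    bind_rows() -> out
  if (nrow(out) == 0L) {
    out <- tibble(start = integer(), end = integer(), peak = integer(),
                  peak_section = character(), height = double())
  }
  out
}

#' Segment a specimen's sections into anatomical regions
#'
#' Each marker-defined region is seeded by the configured ordinal peak of its
#' marker set (see [detect_marker_peaks()]); seeds must occur in configured
#' A-P order. Sections between two consecutive seeds go to an indirect region
#' configured between them if there is one ("sections strictly between the
#' anchors"); otherwise the gap is split at its midpoint, with the extra
#' section of an odd gap going to the anterior region. The first region
#' absorbs any leading sections, the last any trailing ones.
#'
#' @param zp a `z_profile`.
#' @param cfg a [marker_config()].
#' @param min_z,smooth_window,merge_gap passed to [detect_marker_peaks()].
#' @return a `region_assignment`: tibble (`specimen_id`, `section_index`,
#'   `section_id`, `region`) covering every section, regions contiguous and
#'   in configured order.
#' @export
segment_regions <- function(zp, cfg, min_z = 1, smooth_window = 3L,
                            merge_gap = 1L) {
  stopifnot(inherits(zp, "z_profile"), inherits(cfg, "marker_config"))
  n_sec <- length(zp$section_ids)
  midx <- which(cfg$kind == "marker")
  seeds <- purrr::map(midx, function(i) {
    pk <- detect_marker_peaks(zp, cfg$markers[[i]], min_z = min_z,
                              smooth_window = smooth_window,
                              merge_gap = merge_gap)
    if (nrow(pk) < cfg$peak[i]) {
      abort(sprintf(
        "Region '%s': peak ordinal %d requested but only %d peak(s) found for markers %s.",
        cfg$label[i], cfg$peak[i], nrow(pk),
        paste(cfg$markers[[i]], collapse = ",")
      ))
    }
    pk[cfg$peak[i], ]
  }) |> bind_rows()
  # seeds must be in configured A-P order and non-overlapping
  if (any(diff(seeds$peak) <= 0) || any(seeds$start[-1L] <= seeds$end[-nrow(seeds)])) {
    abort(paste0("Seeded marker peaks are not in configured A-P order: ",
                 paste(sprintf("%s@%d", cfg$label[midx], seeds$peak), collapse = ", ")))
  }
  region <- rep(NA_character_, n_sec)
  k <- nrow(seeds)
  start_at <- integer(k); end_at <- integer(k)
  start_at[1L] <- 1L; end_at[k] <- n_sec
  for (j in seq_len(k - 1L)) {
    gap <- if (seeds$start[j + 1L] - seeds$end[j] > 1L) {
      seq.int(seeds$end[j] + 1L, seeds$start[j + 1L] - 1L)
    } else integer()
    between <- which(cfg$kind == "indirect" &
                       cfg$left_anchor == cfg$label[midx[j]] &
                       cfg$right_anchor == cfg$label[midx[j + 1L]])
    if (length(between) == 1L) {
      region[gap] <- cfg$label[between]
      end_at[j] <- seeds$end[j]
      start_at[j + 1L] <- seeds$start[j + 1L]
    } else {
      n_ant <- ceiling(length(gap) / 2)  # odd gap: extra section to the anterior region
      end_at[j] <- seeds$end[j] + n_ant
      start_at[j + 1L] <- end_at[j] + 1L
    }
  }
  for (j in seq_len(k)) region[start_at[j]:end_at[j]] <- cfg$label[midx[j]]
  out <- tibble(
    specimen_id = zp$specimen_id,
    section_index = seq_len(n_sec),
    section_id = zp$section_ids,
    region = region
  )
  structure(out, class = c("region_assignment", class(out)),
            region_order = cfg$label)
}

#' Region boundaries of an assignment
#'
#' @param ra a `region_assignment`.
#' @return tibble (`region`, `start`, `end`) in A-P order.
#' @export
region_boundaries <- function(ra) {
  r <- rle(ra$region)
  ends <- cumsum(r$lengths)
  tibble(region = r$values, start = ends - r$lengths + 1L, end = ends)
}

#' Pool specimens into a region expression profile
#'
#' For every gene and region, all sections assigned to that region across all
#' specimens are pooled and the median z-score and median normalized count
#' taken. Undefined z entries (constant genes in a specimen) are excluded
#' from the median; a gene whose z is undefined in every pooled section has
#' an undefined pooled median and cannot be regional there. The gene universe
#' is restricted to genes detected (nonzero total) in at least
#' `min_specimens` specimens.
#'
#' Expressed genes have a positive median normalized count in the region;
#' regional genes have a pooled median z-score strictly greater than
#' `regional_z`. The two flags are independent criteria; set
#' `strict = TRUE` to additionally require `expressed` for `regional`.
#'
#' @param zps list of `z_profile`s (one per specimen).
#' @param ras list of matching `region_assignment`s.
#' @param min_specimens minimum number of specimens a gene must be detected
#'   in (default: all).
#' @param regional_z z-score threshold (strict inequality).
#' @param strict if `TRUE`, `regional` is ANDed with `expressed`.
#' @return a `region_profile`: list with `gene_ids`, `regions`, matrices
#'   `median_z`, `median_norm`, `expressed`, `regional`.
#' @export
pool_regions <- function(zps, ras, min_specimens = length(zps),
                         regional_z = 1, strict = FALSE) {
  stopifnot(length(zps) == length(ras), length(zps) >= 1L)
  region_order <- attr(ras[[1L]], "region_order") %||% unique(ras[[1L]]$region)
  for (i in seq_along(ras)) {
    if (!setequal(unique(ras[[i]]$region), unique(ras[[1L]]$region))) {
      abort("All specimens must share the same region label set.")
    }
    if (!identical(zps[[i]]$section_ids, ras[[i]]$section_id)) {
      abort(sprintf("Specimen %d: z-profile and assignment sections differ.", i))
    }
  }
  genes <- Reduce(intersect, purrr::map(zps, "gene_ids"))
  detected <- purrr::map(zps, function(zp) {
    rowSums(zp$normalized[genes, , drop = FALSE] > 0) > 0
  })
  n_det <- Reduce(`+`, detected)
  universe <- genes[n_det >= min_specimens]
  if (!length(universe)) abort("No genes detected in enough specimens.")

  regions <- intersect(region_order, unique(ras[[1L]]$region))
  pool_median <- function(field) {
    out <- matrix(NA_real_, length(universe), length(regions),
                  dimnames = list(universe, regions))
    for (r in regions) {
      cols <- purrr::map2(zps, ras, function(zp, ra) {
        zp[[field]][universe, ra$section_id[ra$region == r], drop = FALSE]
      })
      pooled <- do.call(cbind, cols)
      if (ncol(pooled) == 0L) {
        abort(sprintf("Region '%s' has no pooled sections.", r))
      }
      out[, r] <- apply(pooled, 1L, function(v) {
        v <- v[!is.na(v)]
        if (length(v)) median(v) else NA_real_
      })
    }
    out
  }
  median_z <- pool_median("z")
  median_norm <- pool_median("normalized")
  expressed <- median_norm > 0
  regional <- !is.na(median_z) & median_z > regional_z
  if (strict) regional <- regional & expressed
  structure(
    list(gene_ids = universe, regions = regions,
         median_z = median_z, median_norm = median_norm,
         expressed = expressed, regional = regional),
    class = "region_profile"
  )
}

#' @export
print.region_profile <- function(x, ...) {
  cat(sprintf("<region_profile> %d genes x %d regions; %d expressed, %d regional gene calls\n",
              length(x$gene_ids), length(x$regions),
              sum(rowSums(x$expressed) > 0), sum(x$regional)))
  invisible(x)
}

#' @export
tidy.region_profile <- function(x, ...) {
  long <- function(m, value) {
    as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
      rlang::set_names(c("gene_id", "region", value))
  }
  long(x$median_z, "median_z") |>
    left_join(long(x$median_norm, "median_norm"), by = c("gene_id", "region")) |>
    left_join(long(x$expressed, "expressed"), by = c("gene_id", "region")) |>
    left_join(long(x$regional, "regional"), by = c("gene_id", "region"))
}

#' @export
glance.region_profile <- function(x, ...) {
  tibble(
    n_genes = length(x$gene_ids),
    n_regions = length(x$regions),
    n_expressed_genes = sum(rowSums(x$expressed) > 0),
    n_regional_genes = sum(rowSums(x$regional) > 0),
    n_regional_calls = sum(x$regional)
  )
}

#' Regional gene sets of a region profile
#'
#' @param rp a `region_profile`.
#' @return named list: region -> character vector of regional genes.
#' @export
regional_gene_sets <- function(rp) {
  setNames(
    purrr::map(rp$regions, function(r) rp$gene_ids[rp$regional[, r]]),
    rp$regions
  )
}

#' Write region assignment / profile tables
#'
#' @param ras list of `region_assignment`s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_assignments <- function(ras, path) {
  readr::write_tsv(bind_rows(lapply(ras, as_tibble)), path)
  invisible(path)
}

#' @rdname write_region_assignments
#' @param rp a `region_profile`.
#' @export
write_region_profile <- function(rp, path) {
  readr::write_tsv(tidy.region_profile(rp), path)
  invisible(path)
}
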