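#' Marker-based region configuration
#'
#' Defines the ordered anatomical regions along the A-P axis and how each is
#' anchored. A region is either *marker-defined* — seeded by the k-th
#' anterior-to-posterior peak of the mean z-profile of its marker genes
#' (`peak` gives the ordinal, so a two-peak sperm marker can define two
#' separate regions as its first and second peak) — or *indirect*, receiving
#' the sections strictly between its two anchor regions (which must be the
#' marker-defined regions flanking it in configured order).
#'
#' @param regions a list; each element a list with `label`, and either
#'   `markers` (character vector) plus optional `peak` (default 1), or
#'   `between` (character vector of length 2: left and right anchor labels).
#' @return a `marker_config` object (a tibble with one row per region).
#' @export
marker_config <- function(regions) {
  rows <- purrr::map(regions, function(r) {
    if (is.null(r$label)) abort("Every region needs a `label`.")
    if (!is.null(r$markers)) {
      tibble(label = r$label, kind = "marker",
             markers = list(as.character(r$markers)),
             peak = as.integer(r$peak %||% 1L),
             left_anchor = NA_character_, right_anchor = NA_character_)
    } else if (!is.null(r$between)) {
      if (length(r$between) != 2L) abort("`between` needs exactly 2 anchor labels.")
      tibble(label = r$label, kind = "indirect", markers = list(character()),
             peak = NA_integer_,
             left_anchor = r$between[[1L]], right_anchor = r$between[[2L]])
    } else {
      abort(sprintf("Region '%s' needs `markers` or `between`.", r$label))
    }
  })
  cfg <- bind_rows(rows)
  validate_marker_config(cfg)
  structure(cfg, class = c("marker_config", class(cfg)))
}

validate_marker_config <- function(cfg) {
  if (anyDuplicated(cfg$label)) abort("Region labels must be unique.")
  if (any(cfg$kind == "marker" & (is.na(cfg$peak) | cfg$peak < 1L))) {
    abort("Peak ordinals must be >= 1.")
  }
  if (nrow(cfg) == 0L) abort("Config must define at least one region.")
  if (cfg$kind[1L] != "marker" || cfg$kind[nrow(cfg)] != "marker") {
    abort("First and last regions must be marker-defined (indirect regions need anchors on both sides).")
  }
  idx <- seq_len(nrow(cfg))
  for (i in idx[cfg$kind == "indirect"]) {
    la <- match(cfg$left_anchor[i], cfg$label)
    ra <- match(cfg$right_anchor[i], cfg$label)
    if (is.na(la) || is.na(ra)) {
      abort(sprintf("Region '%s': anchors must name other regions.", cfg$label[i]))
    }
    if (!(la < i && ra > i) ||
        cfg$kind[la] != "marker" || cfg$kind[ra] != "marker" ||
        ra - la != 2L) {
      abort(sprintf(
        "Region '%s' must sit alone between its marker-defined anchors '%s' and '%s'.",
        cfg$label[i], cfg$left_anchor[i], cfg$right_anchor[i]
      ))
    }
  }
  invisible(cfg)
}

#' Read or write a marker configuration (YAML)
#'
#' @param path YAML file with a top-level `regions` list; each entry has
#'   `label` and either `markers`/`peak` or `between`.
#' @return [marker_config()] object.
#' @export
read_marker_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$regions)) abort("Marker config YAML needs a `regions` list.")
  marker_config(y$regions)
}

#' @rdname read_marker_config
#' @param cfg a `marker_config`.
#' @export
write_marker_config <- function(cfg, path) {
  regions <- purrr::pmap(cfg, function(label, kind, markers, peak,
                                       left_anchor, right_anchor) {
    if (kind == "marker") {
      list(label = label, markers = as.list(markers), peak = peak)
    } else {
      list(label = label, between = list(left_anchor, right_anchor))
    }
  })
  yaml::write_yaml(list(regions = regions), path)
  invisible(path)
}

#' Ladder-phylogeny configuration for phylostratigraphy
#'
#' An ordered ladder of taxon groups defines the phylostrata: stratum 1 is the
#' focal species itself (genes with no qualifying homology outside it are
#' "orphan"-like), higher strata are progressively older splits. Each hit
#' assay carries its own qualifying e-value threshold (protein and nucleotide
#' searches; a hit qualifies strictly below the threshold).
#'
#' @param focal_taxon name of the focal species.
#' @param strata list of character vectors; element i is the taxon set of
#'   stratum i. Stratum 1 must be exactly the focal taxon.
#' @param protein_threshold,nucleotide_threshold positive qualifying e-value
#'   cutoffs (hits with `evalue < threshold` count as homology evidence).
#' @return a `ladder_config` object.
#' @export
ladder_config <- function(focal_taxon, strata,
                          protein_threshold = 1e-3,
                          nucleotide_threshold = 1e-5) {
  strata <- purrr::map(strata, as.character)
  if (!identical(strata[[1L]], as.character(focal_taxon))) {
    abort("Stratum 1 must contain exactly the focal taxon.")
  }
  all_taxa <- unlist(strata)
  if (anyDuplicated(all_taxa)) abort("Taxon sets of strata must be disjoint.")
  if (protein_threshold <= 0 || nucleotide_threshold <= 0) {
    abort("Thresholds must be > 0.")
  }
  structure(
    list(focal_taxon = focal_taxon, strata = strata,
         protein_threshold = protein_threshold,
         nucleotide_threshold = nucleotide_threshold),
    class = "ladder_config"
  )
}

#' @export
print.ladder_config <- function(x, ...) {
  cat(sprintf("<ladder_config> focal '%s', %d strata; e-value < %g (protein), < %g (nucleotide)\n",
              x$focal_taxon, length(x$strata),
              x$protein_threshold, x$nucleotide_threshold))
  invisible(x)
}

#' Read or write a ladder configuration (YAML)
#'
#' @param path YAML with keys `focal_taxon`, `strata` (list of taxon lists),
#'   `protein_threshold`, `nucleotide_threshold`.
#' @return [ladder_config()] object.
#' @export
read_ladder_config <- function(path) {
  y <- yaml::read_yaml(path)
  ladder_config(y$focal_taxon, y$strata,
                protein_threshold = y$protein_threshold %||% 1e-3,
                nucleotide_threshold = y$nucleotide_threshold %||% 1e-5)
}

#' @rdname read_ladder_config
#' @param ladder a `ladder_config`.
#' @export
write_ladder_config <- function(ladder, path) {
  yaml::write_yaml(list(
    focal_taxon = ladder$focal_taxon,
    strata = purrr::map(ladder$strata, as.list),
    protein_threshold = ladder$protein_threshold,
    nucleotide_threshold = ladder$nucleotide_threshold
  ), path)
  invisible(path)
}

# taxon -> stratum index lookup
ladder_taxon_strata <- function(ladder) {
  idx <- rep(seq_along(ladder$strata), lengths(ladder$strata))
  setNames(idx, unlist(ladder$strata))
}
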