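#' Does a transcript end in a poly-A tail?
#'
#' A poly-A tail is a terminal run of at least `min_run` adenines (the last
#' six or more nucleotides all being A, at the default). The run must reach
#' the 3' end; internal A stretches do not count.
#'
#' @param seq nucleotide sequence (character scalar or vector,
#'   case-insensitive).
#' @param min_run minimum terminal run length.
#' @return logical vector.
#' @export
has_polya_tail <- function(seq, min_run = 6L) {
  if (any(!nzchar(seq))) abort("Empty sequence.")
  m <- regexpr("A+$", toupper(seq))
  ifelse(m > 0L, attr(m, "match.length") >= min_run, FALSE)
}

# best protein hit per transcript under the shared (evalue, -bitscore) order
best_protein_hits <- function(protein_hits) {
  protein_hits |>
    arrange(.data$transcript_id, .data$evalue, desc(.data$bitscore),
            .data$target_id) |>
    distinct(.data$transcript_id, .keep_all = TRUE)
}

#' Select one representative isoform per gene
#'
#' Applies three cascading rules: (1) if exactly one isoform has a poly-A
#' tail, take it; (2) if several are tailed, take the tailed isoform whose
#' best protein hit (lowest e-value, bitscore tie-break) reaches furthest
#' toward the 3' end — by default the alignment end normalized by transcript
#' length, so long isoforms are not favoured merely for being long (set
#' `relative = FALSE` for absolute coordinates); ties go to the longer
#' isoform, then the lexicographically smaller id; (3) if no isoform is
#' tailed, or none of the tailed isoforms has a protein hit, take the longest
#' isoform (tie: lexicographic id).
#'
#' @param isoforms tibble (`gene_id`, `transcript_id`, `sequence`).
#' @param protein_hits optional tibble (`transcript_id`, `target_id`,
#'   `evalue`, `bitscore`, `query_alignment_end`) of protein hits
#'   (1-based alignment end on the transcript).
#' @param min_run poly-A definition, see [has_polya_tail()].
#' @param relative normalize the alignment end by transcript length.
#' @return tibble (`gene_id`, `transcript_id`, `rule`) with `rule` one of
#'   `"polyA"`, `"three_prime_alignment"`, `"longest"`.
#' @export
select_isoforms <- function(isoforms, protein_hits = NULL, min_run = 6L,
                            relative = TRUE) {
  best_hits <- if (!is.null(protein_hits) && nrow(protein_hits)) {
    best_protein_hits(protein_hits)
  } else {
    tibble(transcript_id = character(), query_alignment_end = double())
  }
  isoforms |>
    group_by(.data$gene_id) |>
    group_modify(function(df, key) {
      select_one_isoform(df, best_hits, min_run = min_run, relative = relative)
    }) |>
    ungroup()
}

select_one_isoform <- function(df, best_hits, min_run, relative) {
  df <- df |>
    mutate(len = nchar(.data$sequence),
           tailed = has_polya_tail(.data$sequence, min_run = min_run))
  longest <- function(d, rule) {
    d <- d |> arrange(desc(.data$len), .data$transcript_id)
    tibble(transcript_id = d$transcript_id[1L], rule = rule)
  }
  if (sum(df$tailed) == 1L) {
    return(tibble(transcript_id = df$transcript_id[df$tailed], rule = "polyA"))
  }
  if (sum(df$tailed) > 1L) {
    cand <- df |>
      filter(.data$tailed) |>
      inner_join(best_hits, by = "transcript_id")
    if (nrow(cand)) {
      cand <- cand |>
        mutate(end_score = if (relative) .data$query_alignment_end / .data$len
               else .data$query_alignment_end) |>
        arrange(desc(.data$end_score), desc(.data$len), .data$transcript_id)
      return(tibble(transcript_id = cand$transcript_id[1L],
                    rule = "three_prime_alignment"))
    }
  }
  longest(df, "longest")
}

# codon -> amino acid; codons with ambiguity letters translate to X and do
# not interrupt an open run
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Longest stop-free peptide of a transcript
#'
#' Translates the three forward frames codon by codon (the assembly is
#' strand-specific, so reverse frames are off by default; `six_frame = TRUE`
#' adds the reverse complement) and returns the longest maximal codon run
#' uninterrupted by a stop. A start codon is not required — partial peptides
#' count. Codons containing non-ACGT letters (e.g. N) translate to `X` and
#' do not break a run. Ties go to the most 5' start, then the lowest frame
#' index. Sequences shorter than one codon yield an empty peptide.
#'
#' @param seq nucleotide sequence (character scalar).
#' @param six_frame also scan the reverse complement.
#' @return peptide string (possibly empty).
#' @export
longest_orf_peptide <- function(seq, six_frame = FALSE) {
  seqs <- toupper(seq)
  if (six_frame) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
    return(longest_of(c(longest_orf_peptide(seqs), longest_orf_peptide(rc))))
  }
  n <- nchar(seqs)
  if (n < 3L) return("")
  tab <- codon_table()
  best <- ""
  best_start <- Inf
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1L) next
    starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seqs, starts, starts + 2L)
    aa <- tab[codons]
    aa[is.na(aa)] <- "X"
    is_stop <- aa == "*"
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    run_starts <- ends - r$lengths + 1L
    for (i in which(!r$values)) {
      len <- r$lengths[i]
      nt_start <- starts[run_starts[i]]
      if (len > nchar(best) ||
          (len == nchar(best) && len > 0L && nt_start < best_start)) {
        best <- paste(aa[run_starts[i]:ends[i]], collapse = "")
        best_start <- nt_start
      }
    }
  }
  best
}

longest_of <- function(x) x[order(-nchar(x))][1L]

#' Extract representative peptides for a transcriptome
#'
#' Convenience wrapper: pick one isoform per gene, then the longest ORF
#' peptide of each representative.
#'
#' @inheritParams select_isoforms
#' @return tibble (`gene_id`, `transcript_id`, `rule`, `peptide`).
#' @export
representative_peptides <- function(isoforms, protein_hits = NULL,
                                    min_run = 6L, relative = TRUE) {
  select_isoforms(isoforms, protein_hits, min_run = min_run,
                  relative = relative) |>
    left_join(isoforms |> select("transcript_id", "sequence"),
              by = "transcript_id") |>
    mutate(peptide = purrr::map_chr(.data$sequence, longest_orf_peptide)) |>
    select("gene_id", "transcript_id", "rule", "peptide")
}
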