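#' Chain-alignment coverage of transcripts
#'
#' Fraction of a transcript's exonic nucleotides lying inside the union of
#' the chain's target blocks. Each nucleotide is counted at most once even
#' when several chains overlap it, so stacked alignments cannot push the
#' fraction above 1.
#'
#' @param tx transcript set.
#' @param chains a `chain_set` from [read_chain()].
#' @return named numeric vector of covered fractions in `[0, 1]`;
#'   chromosomes absent from the chain file contribute 0.
#' @export
chain_coverage <- function(tx, chains) {
  blocks <- reduce(granges(chains$blocks), ignore.strand = TRUE)
  missing <- setdiff(unique(as.character(seqnames(unlist(tx, use.names = FALSE)))),
                     unique(as.character(seqnames(blocks))))
  if (length(missing)) {
    message("chromosome(s) absent from chain file (coverage 0): ",
            paste(missing, collapse = ", "))
  }
  ## seqlevel mismatch between transcripts and chains is the documented
  ## zero-coverage case, not a user error
  suppressWarnings(interval_overlap_fraction(tx, blocks))
}

#' Genome-alignment conservation class from two covered fractions
#'
#' @param frac_a,frac_b covered fractions against species A and B
#'   (e.g. human and mouse).
#' @param threshold coverage at or above which a transcript counts as
#'   conserved in that species (default 0.5).
#' @return character vector: `three_way` (both), `A_only`, `B_only`, or
#'   `species_specific` (neither).
#' @export
classify_genome_conservation <- function(frac_a, frac_b, threshold = 0.5) {
  stopifnot(all(frac_a >= 0 & frac_a <= 1), all(frac_b >= 0 & frac_b <= 1))
  a <- frac_a >= threshold
  b <- frac_b >= threshold
  ifelse(a & b, "three_way",
  ifelse(a, "A_only",
  ifelse(b, "B_only", "species_specific")))
}

#' Transcript-level homology from a BLAST hit table
#'
#' Merges the query-interval union of all hits per transcript; a transcript
#' is homologous when the union covers at least `min_cov` of its length.
#' Hits are assumed already filtered by e-value upstream.
#'
#' @param query_lengths named vector of transcript (query) lengths in nt.
#' @param hits hit table from [read_hits()].
#' @param min_cov minimum covered fraction of the query (default 0.2).
#' @return named logical vector over `names(query_lengths)`.
#' @export
transcript_homology <- function(query_lengths, hits, min_cov = 0.2) {
  ids <- names(query_lengths)
  covered <- setNames(numeric(length(ids)), ids)
  hits <- hits[hits$qseqid %in% ids, , drop = FALSE]
  if (nrow(hits)) {
    if (any(hits$qend > query_lengths[hits$qseqid])) {
      stop("hit coordinates exceed query length for: ",
           paste(head(unique(hits$qseqid[hits$qend > query_lengths[hits$qseqid]]), 5),
                 collapse = ", "))
    }
    ir <- reduce(split(IRanges(hits$qstart, hits$qend), hits$qseqid))
    cov <- sum(width(ir))
    covered[names(cov)] <- cov
  }
  covered / query_lengths >= min_cov
}

#' Tissue specificity stratified by conservation class
#'
#' Summarises the distribution of JS specificity scores within each
#' genome-conservation class and compares the `three_way` and
#' `species_specific` classes with a two-sided Mann-Whitney rank-sum test.
#'
#' @param calls data.frame with `transcript_id` and `genome_class` (as from
#'   [classify_genome_conservation()]).
#' @param spec data.frame with `transcript_id` and `js_score` (from
#'   [js_specificity()]).
#' @return list with `by_class` (per-class n, median and mean score) and
#'   `rank_sum` (htest, or `NULL` with `skipped = TRUE` when either class
#'   has fewer than 2 scored members).
#' @export
conservation_vs_specificity <- function(calls, spec) {
  m <- merge(calls, spec, by = "transcript_id")
  m <- m[!is.na(m$js_score), ]
  by_class <- do.call(rbind, lapply(split(m$js_score, m$genome_class), function(s) {
    data.frame(n = length(s), median = median(s), mean = mean(s))
  }))
  by_class$genome_class <- rownames(by_class)
  x <- m$js_score[m$genome_class == "three_way"]
  y <- m$js_score[m$genome_class == "species_specific"]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(by_class = by_class, rank_sum = NULL, skipped = TRUE))
  }
  list(by_class = by_class,
       rank_sum = wilcox.test(x, y, alternative = "two.sided", exact = FALSE),
       skipped = FALSE)
}
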