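#' Transcript sets
#'
#' A transcript set is the unit that flows through the pipeline: a
#' [GenomicRanges::GRangesList] of exons, one element per transcript, named
#' by `transcript_id`, with metadata columns `transcript_id`, `gene_id` and
#' `biotype` on the list. Exons within a transcript share one chromosome and
#' strand, are sorted by start and do not overlap.
#'
#' @param exons a `GRanges` of exons with metadata columns `transcript_id`,
#'   `gene_id` and (optionally) `biotype`; or a `GRangesList` already grouped
#'   per transcript carrying those columns on the list.
#' @return a validated `GRangesList` transcript set.
#' @examples
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 400)),
#'   strand = "+", transcript_id = "t1", gene_id = "g1", biotype = "novel")
#' tx <- transcript_set(ex)
#' exonic_length(tx) # 200
#' @export
transcript_set <- function(exons) {
  if (is(exons, "GRangesList")) {
    grl <- exons
    if (is.null(mcols(grl)$transcript_id)) mcols(grl)$transcript_id <- names(grl)
  } else {
    stopifnot(is(exons, "GRanges"))
    tid <- mcols(exons)$transcript_id
    if (is.null(tid) || anyNA(tid) || any(!nzchar(tid))) {
      stop("every exon needs a non-empty transcript_id")
    }
    tid <- factor(tid, levels = unique(tid))
    gid <- mcols(exons)$gene_id
    if (is.null(gid)) gid <- as.character(tid)
    bty <- mcols(exons)$biotype
    if (is.null(bty)) bty <- rep("novel", length(exons))
    meta <- data.frame(
      transcript_id = levels(tid),
      gene_id = as.character(gid)[match(levels(tid), as.character(tid))],
      biotype = as.character(bty)[match(levels(tid), as.character(tid))],
      stringsAsFactors = FALSE
    )
    mcols(exons) <- NULL
    grl <- split(exons, tid)
    mcols(grl) <- meta
  }
  grl <- sort(grl)
  validate_transcript_set(grl)
  grl
}

validate_transcript_set <- function(grl) {
  chrom_per_tx <- lengths(unique(seqnames(grl)))
  strand_per_tx <- lengths(unique(strand(grl)))
  if (any(chrom_per_tx != 1L) || any(strand_per_tx != 1L)) {
    bad <- names(grl)[chrom_per_tx != 1L | strand_per_tx != 1L]
    stop("transcripts with exons on multiple chromosomes/strands: ",
         paste(head(bad, 5), collapse = ", "))
  }
  n_disjoint <- lengths(reduce(grl, min.gapwidth = 0L))
  if (any(n_disjoint != lengths(grl))) {
    bad <- names(grl)[n_disjoint != lengths(grl)]
    stop("transcripts with overlapping exons: ", paste(head(bad, 5), collapse = ", "))
  }
  invisible(grl)
}

#' Exonic length of each transcript
#'
#' @param tx a transcript set from [transcript_set()] or [read_gtf()].
#' @return named integer vector of summed exon widths (nt).
#' @export
exonic_length <- function(tx) {
  setNames(sum(width(tx)), names(tx))
}

#' Genomic span of each transcript
#'
#' @param tx a transcript set.
#' @return `GRanges`, one range per transcript (exon union span), carrying the
#'   set's metadata columns.
#' @export
transcript_span <- function(tx) {
  sp <- unlist(range(tx), use.names = TRUE)
  mcols(sp) <- mcols(tx)
  sp
}

#' Gene spans of an annotation
#'
#' Collapses an annotated transcript set to one span per `gene_id`.
#'
#' @param annotation a transcript set.
#' @return `GRanges` named by gene id with a `gene_id` metadata column.
#' @export
gene_spans <- function(annotation) {
  sp <- transcript_span(annotation)
  gid <- factor(mcols(sp)$gene_id, levels = unique(mcols(sp)$gene_id))
  out <- unlist(range(split(sp, gid)), use.names = TRUE)
  mcols(out)$gene_id <- names(out)
  out
}
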