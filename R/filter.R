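#' Six-step hierarchical lncRNA filter
#'
#' Applies, in order: (1) drop mono-exonic transcripts; (2) drop transcripts
#' whose exons overlap an annotated exon on the same strand, except that
#' transcripts matching only annotated lncRNA exons are kept and flagged
#' `novel = FALSE`; (3) drop transcripts with exonic length below
#' `min_length`; (4) drop transcripts flagged protein-coding by any upstream
#' coding-potential caller; (5) drop transcripts homologous to canonical
#' structural ncRNA families, retaining those whose only matches are
#' conserved lncRNA models; (6) survivors are lncRNAs and receive a
#' positional category from [classify_position()]. Each removed transcript
#' records the first step that fired.
#'
#' @param transcripts transcript set of assembled candidates.
#' @param annotation transcript set of the reference annotation; entries with
#'   `biotype == "annotated_lncRNA"` are known lncRNAs, everything else is
#'   treated as an annotated (mostly protein-coding) element.
#' @param coding data.frame with columns `transcript_id` and one column per
#'   caller (values `"coding"`/`"noncoding"`); a transcript is coding if any
#'   caller says so.
#' @param ncrna data.frame with columns `transcript_id`, `family` where
#'   `family` is one of `miRNA`, `tRNA`, `snoRNA`, `rRNA`, `other_structural`,
#'   `lncRNA_model`; transcripts absent from the table have no matches.
#' @param min_length minimum exonic length in nt (default 200).
#' @param window distance window in nt for positional classification
#'   (default 2000).
#' @param missing_coding what to do with transcripts absent from `coding`:
#'   `"error"` (default) or `"noncoding"`.
#' @return data.frame of verdicts: `transcript_id`, `fate`
#'   (`retained`/`removed`), `step` (removal step or `retained`), `category`
#'   (positional class, `NA` if removed) and `novel`.
#' @export
run_filter_pipeline <- function(transcripts, annotation, coding, ncrna,
                                min_length = 200L, window = 2000L,
                                missing_coding = c("error", "noncoding")) {
  missing_coding <- match.arg(missing_coding)
  ids <- mcols(transcripts)$transcript_id
  step <- rep(NA_character_, length(ids))
  novel <- rep(TRUE, length(ids))

  ## step 1: multi-exonic only
  step[is.na(step) & lengths(transcripts) < 2L] <- "multi_exon"

  ## step 2: same-strand exonic overlap with annotated elements
  ann_ex <- unlist(annotation, use.names = FALSE)
  ann_bio <- rep(mcols(annotation)$biotype, lengths(annotation))
  ann_lnc_ex <- ann_ex[ann_bio == "annotated_lncRNA"]
  ann_other_ex <- ann_ex[ann_bio != "annotated_lncRNA"]
  hit_other <- overlapsAny(transcripts, ann_other_ex, ignore.strand = FALSE)
  hit_lnc <- overlapsAny(transcripts, ann_lnc_ex, ignore.strand = FALSE)
  step[is.na(step) & hit_other] <- "annotated_overlap"
  novel[hit_lnc & !hit_other] <- FALSE

  ## step 3: length
  step[is.na(step) & exonic_length(transcripts) < min_length] <- "length"

  ## step 4: coding potential (union over callers)
  verd_cols <- setdiff(colnames(coding), "transcript_id")
  any_coding <- apply(coding[, verd_cols, drop = FALSE] == "coding", 1L, any)
  coding_of <- setNames(any_coding, coding$transcript_id)
  known <- ids %in% names(coding_of)
  if (any(!known) && missing_coding == "error") {
    stop("transcripts missing from the coding-potential table: ",
         paste(head(ids[!known], 5), collapse = ", "))
  }
  is_coding <- ifelse(known, coding_of[ids], FALSE)
  step[is.na(step) & is_coding] <- "coding_potential"

  ## step 5: canonical ncRNA homology; lncRNA-model-only matches survive
  struct_fams <- c("miRNA", "tRNA", "snoRNA", "rRNA", "other_structural")
  hit_struct <- ids %in% ncrna$transcript_id[ncrna$family %in% struct_fams]
  step[is.na(step) & hit_struct] <- "ncrna_homology"

  retained <- is.na(step)
  step[retained] <- "retained"
  category <- rep(NA_character_, length(ids))
  if (any(retained)) {
    category[retained] <- classify_position(transcripts[retained], annotation,
                                            window = window)
  }
  data.frame(
    transcript_id = ids,
    fate = ifelse(retained, "retained", "removed"),
    step = step,
    category = category,
    novel = novel,
    stringsAsFactors = FALSE
  )
}

#' Positional classification of lncRNAs
#'
#' Assigns each transcript one of four mutually exclusive categories relative
#' to annotated genes (annotated lncRNAs themselves are excluded from the
#' reference so a re-assembled known lncRNA is not classified against
#' itself), with precedence antisense > intronic > cis_regulatory >
#' intergenic:
#' \itemize{
#'   \item `antisense`: any exon overlaps an annotated exon on the opposite
#'     strand;
#'   \item `intronic`: the transcript lies wholly inside an annotated gene
#'     span with no exonic overlap on either strand;
#'   \item `cis_regulatory`: the span is within `window` nt of an annotated
#'     gene span (either side, either strand) but neither of the above;
#'   \item `intergenic`: at least `window` nt away from every annotated gene.
#' }
#'
#' @param tx transcript set (or a subset) to classify.
#' @param annotation reference transcript set.
#' @param window distance threshold in nt (default 2000).
#' @return character vector of categories, one per transcript.
#' @export
classify_position <- function(tx, annotation, window = 2000L) {
  ref <- annotation[mcols(annotation)$biotype != "annotated_lncRNA"]
  ref_ex <- unlist(ref, use.names = FALSE)
  ref_gene <- gene_spans(ref)
  sp <- transcript_span(tx)

  ## antisense: exon/exon overlap on the opposite strand
  ref_ex_flip <- invertStrand(ref_ex)
  antisense <- overlapsAny(tx, ref_ex_flip, ignore.strand = FALSE)

  ## intronic: inside a gene span, no exonic overlap on either strand
  within_gene <- overlapsAny(sp, ref_gene, type = "within", ignore.strand = TRUE)
  exon_hit_any <- overlapsAny(tx, ref_ex, ignore.strand = TRUE)
  intronic <- within_gene & !exon_hit_any

  ## cis-regulatory: span closer than `window` to a gene span ("at least
  ## window away" counts as intergenic, so the boundary gap == window is
  ## intergenic)
  near <- overlapsAny(sp, ref_gene, maxgap = window - 1L, ignore.strand = TRUE)

  out <- ifelse(antisense, "antisense",
         ifelse(intronic, "intronic",
         ifelse(near, "cis_regulatory", "intergenic")))
  unname(out)
}

#' Fraction of exonic nucleotides covered by a feature set
#'
#' Generic overlap utility (e.g. CpG-island coverage of a transcript): the
#' fraction of a transcript's exonic bases lying in the union of `features`,
#' strand-blind.
#'
#' @param tx transcript set.
#' @param features `GRanges` of features.
#' @return numeric vector in `[0, 1]`, one value per transcript.
#' @export
interval_overlap_fraction <- function(tx, features) {
  feat <- reduce(granges(features), ignore.strand = TRUE)
  ex <- unlist(tx, use.names = FALSE)
  idx <- findOverlaps(ex, feat, ignore.strand = TRUE)
  covered_per_exon <- rep(0, length(ex))
  if (length(idx)) {
    ov <- width(pintersect(ex[queryHits(idx)], feat[subjectHits(idx)],
                           ignore.strand = TRUE))
    agg <- tapply(ov, queryHits(idx), sum)
    covered_per_exon[as.integer(names(agg))] <- agg
  }
  grp <- rep(seq_along(tx), lengths(tx))
  covered <- tapply(covered_per_exon, grp, sum)
  out <- as.numeric(covered) / as.numeric(exonic_length(tx))
  setNames(out, names(tx))
}
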