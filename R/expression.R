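#' RPKM from counts and exonic lengths
#'
#' RPKM = count / (exonic length / 1e3) / (library size / 1e6), with counts
#' taken as fragments (read pairs) for paired-end data. Zero counts map to
#' zero RPKM.
#'
#' @param cm a `count_matrix` (see [count_matrix()]).
#' @param lengths named vector of exonic lengths (nt) covering every counted
#'   transcript.
#' @return numeric matrix of RPKM with the dimnames of `cm$counts`.
#' @export
compute_rpkm <- function(cm, lengths) {
  ids <- rownames(cm$counts)
  if (!all(ids %in% names(lengths))) {
    stop("missing exonic length for: ",
         paste(head(setdiff(ids, names(lengths)), 5), collapse = ", "))
  }
  len <- lengths[ids]
  if (any(len <= 0)) stop("exonic lengths must be positive")
  sweep(cm$counts / (len / 1e3), 2L, cm$library_sizes / 1e6, "/")
}

#' Expression breadth per transcript
#'
#' Number of samples in which a transcript is expressed above `threshold`,
#' with the conventional summary bins: "restricted" (expressed in fewer than
#' 3 samples, but at least one) and "ubiquitous" (expressed in all samples).
#'
#' @param rpkm RPKM matrix, transcripts x samples.
#' @param threshold RPKM above which a transcript counts as expressed
#'   (default 0, i.e. RPKM > 0).
#' @return data.frame with `transcript_id`, `n_expressed`, and logical
#'   `restricted`, `ubiquitous`.
#' @export
expression_breadth <- function(rpkm, threshold = 0) {
  n <- rowSums(rpkm > threshold)
  data.frame(
    transcript_id = rownames(rpkm),
    n_expressed = as.integer(n),
    restricted = n > 0 & n < 3,
    ubiquitous = n == ncol(rpkm),
    stringsAsFactors = FALSE
  )
}

#' GC content of nucleotide sequences
#'
#' Percent (G + C) over unambiguous bases; `N` is excluded from the
#' denominator. Case-insensitive.
#'
#' @param seq character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return numeric vector of percentages; `NA` for empty or all-N sequences.
#' @export
gc_content <- function(seq) {
  if (is(seq, "DNAStringSet")) seq <- as.character(seq)
  up <- toupper(seq)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(up) - nchar(gsub(b, "", up, fixed = TRUE))
  }, numeric(length(up)))
  counts <- matrix(counts, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  denom <- rowSums(counts)
  out <- ifelse(denom == 0, NA_real_,
                100 * (counts[, "G"] + counts[, "C"]) / denom)
  setNames(out, names(seq))
}

#' SNP density over exonic nucleotides
#'
#' SNPs per kb of exonic sequence: the number of 1-nt SNP positions falling
#' in a transcript's exons divided by its exonic length in kb. Intronic SNPs
#' do not count.
#'
#' @param tx transcript set.
#' @param snps `GRanges` of 1-nt SNP positions (e.g. from [read_bed()]).
#' @return named numeric vector, SNPs per kb per transcript.
#' @export
snp_density <- function(tx, snps) {
  if (any(width(snps) != 1L)) stop("SNPs must be 1-nt intervals")
  n <- countOverlaps(tx, snps, ignore.strand = TRUE)
  setNames(as.numeric(n) / (as.numeric(exonic_length(tx)) / 1e3), names(tx))
}

#' Correlation-based sample clustering
#'
#' Average-linkage agglomeration of samples on 1 - Pearson correlation of
#' log2(RPKM + 1) over a transcript subset (conventionally the lncRNAs).
#'
#' @param rpkm RPKM matrix, transcripts x samples.
#' @param subset transcript ids to use (default: all rows).
#' @param pseudocount added before the log2 transform (default 1).
#' @return an object of class `hclust` over the samples.
#' @export
cluster_samples <- function(rpkm, subset = rownames(rpkm), pseudocount = 1) {
  if (ncol(rpkm) < 3L) stop("need at least 3 samples")
  x <- log2(rpkm[subset, , drop = FALSE] + pseudocount)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  d <- as.dist(1 - cor(x))
  hclust(d, method = "average")
}

#' Export a sample tree as Newick
#'
#' @param tree an `hclust` from [cluster_samples()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_tree <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
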