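# Independent brute-force oracles and compact fixture builders.
# These deliberately avoid the package's own code paths (GRanges set
# operations, matrix algebra) so they can certify them.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# build a transcript set from a compact spec:
# list(t1 = list(chrom="chr1", strand="+", exons=cbind(start, end)), ...)
# coordinates 1-based closed, biotype/gene_id optional
make_tx <- function(spec) {
  grs <- lapply(names(spec), function(id) {
    s <- spec[[id]]
    GRanges(s$chrom %||% "chr1",
            IRanges(s$exons[, 1], s$exons[, 2]),
            strand = s$strand %||% "+",
            transcript_id = id,
            gene_id = s$gene_id %||% id,
            biotype = s$biotype %||% "novel")
  })
  transcript_set(unlist(GRangesList(grs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-base membership oracle: fraction of exonic positions of one transcript
# (exon matrix, 1-based closed) inside any of the (start, end) feature rows
# on the same chromosome
bf_covered_fraction <- function(exons, feat_start, feat_end) {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i) exons[i, 1]:exons[i, 2]))
  if (length(feat_start) == 0) return(0)
  hit <- vapply(pos, function(p) any(p >= feat_start & p <= feat_end), logical(1))
  mean(hit)
}

# direct-summation Jensen-Shannon specificity (bits): max over tissues of
# 1 - sqrt(JSD(p, e_t))
bf_js_score <- function(e) {
  p <- e / sum(e)
  n <- length(p)
  scores <- vapply(seq_len(n), function(t) {
    q <- rep(0, n); q[t] <- 1
    m <- (p + q) / 2
    kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
    1 - sqrt((kl(p, m) + kl(q, m)) / 2)
  }, numeric(1))
  max(scores)
}

# triple-loop unsigned TOM oracle
bf_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# brute-force positional classifier over explicit exon/gene tables;
# reference genes given as list(gene_id, chrom, strand, span = c(s, e),
# exons = cbind(s, e))
bf_classify <- function(chrom, strand, exons, span, genes, window = 2000) {
  antisense <- FALSE; exon_hit_any <- FALSE; within <- FALSE; near <- FALSE
  for (g in genes) {
    if (g$chrom != chrom) next
    for (i in seq_len(nrow(exons))) {
      for (j in seq_len(nrow(g$exons))) {
        ov <- min(exons[i, 2], g$exons[j, 2]) - max(exons[i, 1], g$exons[j, 1])
        if (ov >= 0) {
          exon_hit_any <- TRUE
          if (g$strand != strand) antisense <- TRUE
        }
      }
    }
    if (span[1] >= g$span[1] && span[2] <= g$span[2]) within <- TRUE
    d <- max(0, g$span[1] - span[2] - 1, span[1] - g$span[2] - 1)
    if (d < window) near <- TRUE
  }
  if (antisense) return("antisense")
  if (within && !exon_hit_any) return("intronic")
  if (near) return("cis_regulatory")
  "intergenic"
}

# hypergeometric upper tail by exhaustive enumeration of study sets
bf_hyper_enum <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= K)  # genes 1..K carry the term
  mean(hits >= k)
}

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

small_config <- function(seed = 7L) {
  # de_log2fc 3: with only ~10 planted pair-contrasts, a 2%-per-test miss
  # probability at the default effect would make this tiny smoke fixture
  # flaky; the larger effect keeps its recovery contract deterministic
  sim_config(seed = seed, n_pcg = 60L, n_lnc_per_category = 3L,
             n_decoys_per_class = 2L, n_annotated_lnc = 2L,
             n_de = 5L, de_log2fc = 3,
             module_spec = list(list(size = 30L, rho = 0.8, trait = TRUE),
                                list(size = 30L, rho = 0.8, trait = FALSE)),
             n_noise_genes = 20L, n_module_lnc = 2L)
}
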