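#' MA-plot random-sampling test for two libraries without replicates
#'
#' Tests per-transcript counts from two libraries under the random-sampling
#' null: each library's count is Binomial(n, p) with a common transcript
#' probability p. With `M = log2 c1 - log2 c2` and
#' `A = (log2 c1 + log2 c2)/2`, a delta-method normal approximation gives
#' `E[M|A] = log2(n1/n2)` and
#' `Var[M|A] = (1 - p)/ln(2)^2 * (1/n1 + 1/n2) / p` with `p` estimated from
#' A as `2^A / sqrt(n1 n2)`. The variance is the marginal delta-method
#' variance of M at the abundance implied by A: across a transcriptome the
#' abundance distribution is diffuse, so A locates a transcript's abundance
#' but carries no further information about the log-ratio, and conditioning
#' on A must not shrink the variance below the marginal one (at equal
#' library sizes the two coincide). These moments are validated against a
#' Monte-Carlo binomial oracle in the test suite rather than taken on
#' faith. Zero counts get a pseudocount of 1 before the logs; transcripts
#' with both counts zero are returned with `NA` statistics and are excluded
#' from downstream calling.
#'
#' @param c1,c2 non-negative integer count vectors (same length).
#' @param n1,n2 positive library sizes (mapped read pairs).
#' @return data.frame with `M`, `A`, `z`, `p` (two-sided normal), and
#'   `log2FC` = M - log2(n1/n2), the library-size-normalised fold change.
#' @export
mars_test <- function(c1, c2, n1, n2) {
  if (n1 <= 0 || n2 <= 0) stop("library sizes must be positive")
  stopifnot(length(c1) == length(c2), all(c1 >= 0), all(c2 >= 0))
  both_zero <- c1 == 0 & c2 == 0
  k1 <- ifelse(c1 == 0, 1, c1)
  k2 <- ifelse(c2 == 0, 1, c2)
  M <- log2(k1) - log2(k2)
  A <- (log2(k1) + log2(k2)) / 2
  p_hat <- pmin(2^A / sqrt(n1 * n2), 1 - 1e-12)
  v <- (1 - p_hat) / (log(2)^2 * p_hat) * (1 / n1 + 1 / n2)
  z <- (M - log2(n1 / n2)) / sqrt(v)
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  out <- data.frame(M = M, A = A, z = z, p = p, log2FC = M - log2(n1 / n2))
  out[both_zero, ] <- NA_real_
  out
}

#' Calibration of the MA-plot test under its own sampling null
#'
#' Simulates two equal-size libraries under the random-sampling null: each
#' transcript gets a true abundance drawn log-normally, and both counts are
#' Poisson around the same expected value (the binomial sampling model at
#' small per-transcript probabilities). Returns the fraction of transcripts
#' rejected at each `alpha` — nominally equal to `alpha` when the
#' conditional moments are right.
#'
#' @param n_genes number of simulated transcripts.
#' @param library_size per-library mapped read pairs.
#' @param mean_log,sd_log log-normal parameters of expected counts.
#' @param alpha rejection levels to report.
#' @return named numeric vector of empirical rejection fractions.
#' @export
mars_null_calibration <- function(n_genes = 10000L, library_size = 2e7,
                                  mean_log = log(200), sd_log = 0.5,
                                  alpha = c(0.01, 0.05)) {
  mu <- exp(rnorm(n_genes, mean_log, sd_log))
  c1 <- rpois(n_genes, mu)
  c2 <- rpois(n_genes, mu)
  res <- mars_test(c1, c2, library_size, library_size)
  vapply(setNames(alpha, as.character(alpha)),
         function(a) mean(res$p < a, na.rm = TRUE), numeric(1))
}

#' Error rates of the DE rule on a planted mixture
#'
#' Simulates a two-library experiment in which a fraction of transcripts
#' carries a planted fold change and the rest follow the null sampling
#' model, then applies the conjunctive calling rule
#' (`|log2FC| >= log2(min_fc)` and BH `q < max_q`) and reports the
#' empirical false discovery rate and the recall of planted transcripts.
#'
#' @param n_genes number of transcripts.
#' @param frac_de fraction with a planted change.
#' @param fold_change planted fold change (applied in library 1).
#' @param library_size per-library mapped read pairs.
#' @param mean_log,sd_log log-normal parameters of expected counts.
#' @param min_fc,max_q calling thresholds.
#' @return list with `fdr`, `recall`, `n_called`.
#' @export
mars_mixture_rates <- function(n_genes = 10000L, frac_de = 0.1,
                               fold_change = 4, library_size = 2e7,
                               mean_log = log(200), sd_log = 0.5,
                               min_fc = 2, max_q = 0.05) {
  mu <- exp(rnorm(n_genes, mean_log, sd_log))
  is_de <- seq_len(n_genes) <= round(frac_de * n_genes)
  c1 <- rpois(n_genes, mu * ifelse(is_de, fold_change, 1))
  c2 <- rpois(n_genes, mu)
  res <- mars_test(c1, c2, library_size, library_size)
  q <- bh_adjust(res$p)
  called <- !is.na(q) & q < max_q & abs(res$log2FC) >= log2(min_fc)
  list(
    fdr = if (any(called)) mean(!is_de[called]) else 0,
    recall = mean(called[is_de]),
    n_called = sum(called)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), exposed under
#' the pipeline's own name so callers do not depend on the correction choice.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Call differential expression across stage pairs
#'
#' Runs [mars_test()] for each requested pair of samples, adjusts p-values
#' per pair with [bh_adjust()], and calls a transcript significant when
#' `|log2FC| >= log2(min_fc)` and `q < max_q` (conjunctive rule). Also
#' reports the union of significant sets and the Venn partition over pairs.
#'
#' @param cm `count_matrix` containing the stage samples.
#' @param pairs list of length-2 character vectors of sample labels, e.g.
#'   `list(c("muscle_D0", "muscle_D30"), ...)`.
#' @param min_fc minimum fold change (default 2).
#' @param max_q maximum BH-adjusted q (default 0.05).
#' @return list with `tests` (per-pair data.frames carrying `transcript_id`,
#'   MARS statistics, `q`, `significant`), `significant` (per-pair id sets),
#'   `union` (ids significant in any pair), and `venn` (counts per
#'   membership pattern).
#' @export
call_de <- function(cm, pairs, min_fc = 2, max_q = 0.05) {
  labels <- vapply(pairs, paste, character(1), collapse = "_vs_")
  tests <- list()
  sig <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    stopifnot(length(pr) == 2L, all(pr %in% colnames(cm$counts)))
    res <- mars_test(cm$counts[, pr[1]], cm$counts[, pr[2]],
                     cm$library_sizes[pr[1]], cm$library_sizes[pr[2]])
    res$transcript_id <- rownames(cm$counts)
    res$q <- bh_adjust(res$p)
    res$significant <- !is.na(res$q) & abs(res$log2FC) >= log2(min_fc) &
      res$q < max_q
    tests[[labels[i]]] <- res
    sig[[labels[i]]] <- res$transcript_id[res$significant]
  }
  union_ids <- unique(unlist(sig))
  membership <- vapply(sig, function(s) union_ids %in% s,
                       logical(length(union_ids)))
  if (length(union_ids) == 1L) membership <- matrix(membership, nrow = 1L,
                                                    dimnames = list(NULL, labels))
  pattern <- if (length(union_ids)) {
    apply(membership, 1L, function(r) paste(labels[r], collapse = "&"))
  } else character(0)
  list(tests = tests, significant = sig, union = union_ids,
       venn = table(pattern))
}

#' lncRNA-neighbour expression correlation
#'
#' Pairs each lncRNA with a protein-coding gene — the nearest gene by
#' span-to-span genomic distance for intergenic lncRNAs
#' (`nearest_intergenic`), the overlapped gene for intragenic ones
#' (`overlapped_intragenic`) — and computes the Pearson correlation of
#' log2(RPKM + 1) across samples.
#'
#' @param lnc_tx transcript set of lncRNAs.
#' @param categories named character vector of positional categories for
#'   `lnc_tx` (from [run_filter_pipeline()] / [classify_position()]).
#' @param pcg_tx transcript set of protein-coding genes.
#' @param rpkm RPKM matrix covering lncRNA transcripts and protein-coding
#'   genes (gene-level rows named by gene id).
#' @param pseudocount added before the log2 transform (default 1).
#' @return list with `pairs` (data.frame `lnc_id`, `pcg_id`, `relation`,
#'   `distance`, `r`), `mean_r` per relation, `fraction_positive` per
#'   relation, and `n_skipped` (lncRNAs with no gene on their chromosome).
#' @export
neighbor_correlation <- function(lnc_tx, categories, pcg_tx, rpkm,
                                 pseudocount = 1) {
  genes <- gene_spans(pcg_tx)
  sp <- transcript_span(lnc_tx)
  lnc_ids <- mcols(lnc_tx)$transcript_id
  categories <- categories[lnc_ids]
  rows <- list()
  n_skipped <- 0L
  lx <- log2(rpkm + pseudocount)
  for (i in seq_along(sp)) {
    same_chr <- as.character(seqnames(genes)) == as.character(seqnames(sp[i]))
    if (!any(same_chr)) { n_skipped <- n_skipped + 1L; next }
    cand <- genes[same_chr]
    if (categories[i] == "intergenic") {
      d <- distance(sp[i], cand, ignore.strand = TRUE)
      j <- which.min(d)
      relation <- "nearest_intergenic"
      dist_nt <- d[j]
    } else {
      ov <- which(overlapsAny(cand, sp[i], ignore.strand = TRUE))
      if (!length(ov)) { n_skipped <- n_skipped + 1L; next }
      j <- ov[1L]
      relation <- "overlapped_intragenic"
      dist_nt <- 0L
    }
    pcg_id <- mcols(cand)$gene_id[j]
    if (!(lnc_ids[i] %in% rownames(lx)) || !(pcg_id %in% rownames(lx))) next
    r <- suppressWarnings(cor(lx[lnc_ids[i], ], lx[pcg_id, ]))
    rows[[length(rows) + 1L]] <- data.frame(
      lnc_id = lnc_ids[i], pcg_id = pcg_id, relation = relation,
      distance = as.integer(dist_nt), r = r, stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc_id = character(0), pcg_id = character(0),
               relation = character(0), distance = integer(0), r = numeric(0))
  ok <- !is.na(pairs$r)
  list(
    pairs = pairs,
    mean_r = tapply(pairs$r[ok], pairs$relation[ok], mean),
    fraction_positive = tapply(pairs$r[ok] > 0, pairs$relation[ok], mean),
    n_skipped = n_skipped
  )
}
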