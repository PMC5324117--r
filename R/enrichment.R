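#' Hypergeometric over-representation test
#'
#' For every term with at least one study hit: with `N` background genes,
#' `K` of them annotated to the term, a study set of `n`, and `k` study
#' hits, the upper-tail p-value is
#' `P(X >= k) = sum_{j >= k} C(K, j) C(N - K, n - j) / C(N, n)`.
#' Over-representation only (no depletion test). q-values are BH-adjusted
#' across the tested terms; results are sorted by q then p.
#'
#' @param study character vector of study genes (must be a subset of
#'   `background`).
#' @param background character vector of background genes. The background
#'   should be the genes entering the analysis stage at hand, not the whole
#'   genome.
#' @param term_map data.frame `gene_id`, `term_id` (see [read_go()]); terms
#'   on genes outside the background are ignored.
#' @return data.frame: `term_id`, `k` (study hits), `n` (study size), `K`
#'   (background hits), `N` (background size), `p`, `q`, `fold`
#'   (`(k/n)/(K/N)`).
#' @examples
#' tm <- data.frame(gene_id = paste0("g", 1:5), term_id = "T1")
#' hypergeom_enrich(paste0("g", 1:5)[1:4], paste0("g", 1:20), tm)
#' @export
hypergeom_enrich <- function(study, background, term_map) {
  study <- unique(study)
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  missing <- setdiff(study, background)
  if (length(missing)) {
    stop("study genes absent from background: ",
         paste(head(missing, 5), collapse = ", "))
  }
  tm <- unique(term_map[term_map$gene_id %in% background,
                        c("gene_id", "term_id")])
  N <- length(background)
  n <- length(study)
  in_study <- tm$gene_id %in% study
  k_by_term <- table(tm$term_id[in_study])
  if (length(k_by_term) == 0L) {
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), fold = numeric(0)))
  }
  K_by_term <- table(tm$term_id)
  terms <- names(k_by_term)
  k <- as.integer(k_by_term[terms])
  K <- as.integer(K_by_term[terms])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = terms, k = k, n = n, K = K, N = N,
    p = p, q = bh_adjust(p), fold = (k / n) / (K / N),
    stringsAsFactors = FALSE
  )
  out[order(out$q, out$p, out$term_id), , drop = FALSE]
}
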