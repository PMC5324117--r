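#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency
#' `|cor|^power`, computes connectivities `k_i`, bins `log10 k` and
#' regresses `log10 p(k)` on the bin means; the fit index is the regression
#' R-squared, negated when the slope is positive (a scale-free degree
#' distribution must decay). The chosen power is the smallest with fit at
#' least `fit_min`; if none qualifies the conventional default 6 is returned
#' with a warning.
#'
#' @param expr expression matrix, genes x samples (log scale recommended).
#' @param powers candidate integer powers (default 1:20).
#' @param fit_min minimum acceptable fit (default 0.8).
#' @param n_bins number of connectivity bins (default 10).
#' @return list with `beta` and `fit_table` (power, fit, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, fit_min = 0.8,
                                n_bins = 10L) {
  expr <- drop_constant_rows(expr)
  r <- abs(cor(t(expr)))
  diag(r) <- 0
  fit <- mean_k <- numeric(length(powers))
  for (i in seq_along(powers)) {
    a <- r^powers[i]
    k <- rowSums(a)
    mean_k[i] <- mean(k)
    fit[i] <- scale_free_fit(k, n_bins)
  }
  tab <- data.frame(power = powers, fit = fit, mean_k = mean_k)
  ok <- which(fit >= fit_min)
  if (length(ok)) {
    beta <- powers[ok[1L]]
  } else {
    warning("no candidate power reached scale-free fit ", fit_min,
            "; falling back to 6")
    beta <- 6L
  }
  list(beta = beta, fit_table = tab)
}

scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  cuts <- cut(log10(k), breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3L) return(NA_real_)
  fitlm <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fitlm)$r.squared
  if (coef(fitlm)[2L] > 0) -r2 else r2
}

drop_constant_rows <- function(expr) {
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " constant gene row(s)")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  expr
}

#' Unsigned adjacency and topological overlap matrix
#'
#' Adjacency `a_ij = |pearson(x_i, x_j)|^beta` with unit diagonal, and the
#' standard unsigned TOM:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j`, `k_i = sum_u a_iu` (u != i), and `TOM_ii = 1`.
#'
#' @param expr expression matrix, genes x samples.
#' @param beta soft-threshold power (>= 1).
#' @return list of class `coexpression_network` with `adjacency`, `tom`,
#'   `beta`, `gene_ids`.
#' @export
adjacency_tom <- function(expr, beta = 6) {
  stopifnot(beta >= 1)
  r <- suppressWarnings(cor(t(expr)))  # zero-sd rows surface as the explicit
                                       # non-finite error below
  if (any(!is.finite(r))) {
    bad <- which(!is.finite(r), arr.ind = TRUE)[1L, ]
    stop("non-finite correlation between genes ",
         rownames(expr)[bad[1]], " and ", rownames(expr)[bad[2]])
  }
  a <- abs(r)^beta
  diag(a) <- 1
  k <- rowSums(a) - 1
  ## numerator sum_u!=i,j a_iu a_uj = (A %*% A)_ij - a_ii a_ij - a_ij a_jj
  num <- a %*% a - 2 * a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a) <- list(rownames(expr), rownames(expr))
  structure(list(adjacency = a, tom = tom, beta = beta,
                 gene_ids = rownames(expr)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network:", length(x$gene_ids), "genes, beta =", x$beta, "\n")
  invisible(x)
}

#' Module detection by static tree cut
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at
#' `cut_height` times the maximum merge height; clusters smaller than
#' `min_module_size` are labelled `"unassigned"`. Module labels are
#' `"M1", "M2", ...` ordered by decreasing size, so the labelling is stable
#' for a given input.
#'
#' @param tom topological overlap matrix (or a `coexpression_network`).
#' @param min_module_size minimum genes per module (default 30).
#' @param cut_height fraction of the maximum merge height (default 0.99).
#' @return named character vector of module labels per gene.
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = 0.99) {
  if (is(tom, "coexpression_network")) tom <- tom$tom
  d <- as.dist(1 - tom)
  tree <- hclust(d, method = "average")
  h <- cut_height * max(tree$height)
  raw <- cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  if (length(keep) == 0L) {
    labels <- rep("unassigned", length(raw))
  } else {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    map <- setNames(paste0("M", seq_along(ord)), ord)
    labels <- ifelse(as.character(raw) %in% keep, map[as.character(raw)],
                     "unassigned")
    if (length(keep) == 1L && all(labels == "M1")) {
      warning("all genes fall in a single module at the configured cut")
    }
  }
  setNames(labels, rownames(tom))
}

#' Module eigengenes and module membership (kME)
#'
#' Per module: member rows are standardised (mean 0, sd 1 across samples)
#' and the first principal component over samples — the eigengene, unit
#' norm — is extracted; its sign is fixed so the module's average
#' standardised profile correlates positively with it. kME is each gene's
#' Pearson correlation with its own module's eigengene.
#'
#' @param expr expression matrix, genes x samples.
#' @param module_labels named labels from [detect_modules()]; genes labelled
#'   `"unassigned"` are skipped (kME `NA`).
#' @return list with `eigengenes` (modules x samples), `kme` (named per-gene
#'   vector), `var_explained` (per module).
#' @export
module_eigengenes <- function(expr, module_labels) {
  module_labels <- module_labels[rownames(expr)]
  mods <- setdiff(unique(module_labels), "unassigned")
  mods <- mods[order(mods)]
  eig <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(mods, colnames(expr)))
  ve <- setNames(numeric(length(mods)), mods)
  kme <- setNames(rep(NA_real_, nrow(expr)), rownames(expr))
  for (m in mods) {
    rows <- which(module_labels == m)
    if (length(rows) < 2L) stop("module ", m, " has fewer than 2 genes")
    x <- expr[rows, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    if (any(sds == 0)) stop("constant gene row in module ", m)
    xs <- (x - rowMeans(x)) / sds
    sv <- svd(xs)
    if (sv$d[1L] == 0) stop("degenerate (rank-0) module ", m)
    e <- sv$v[, 1L]
    if (cor(colMeans(xs), e) < 0) e <- -e
    eig[m, ] <- e
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
    kme[rows] <- as.numeric(cor(t(x), e))
  }
  list(eigengenes = eig, kme = kme, var_explained = ve)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a per-sample trait
#' (e.g. the binary muscle vector: muscle samples 1, others 0), with
#' two-sided p-values from the t distribution on n - 2 df. Modules are
#' ranked by absolute correlation.
#'
#' @param eigengenes modules x samples matrix from [module_eigengenes()].
#' @param trait numeric per-sample vector (both classes present if binary).
#' @return data.frame `module`, `r`, `p`, sorted by decreasing `|r|`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  stopifnot(length(trait) == ncol(eigengenes))
  if (sd(trait) == 0) stop("trait vector is constant")
  n <- length(trait)
  r <- as.numeric(cor(t(eigengenes), trait))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(module = rownames(eigengenes), r = r, p = p,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r)), ]
}

#' Hub genes by module membership
#'
#' @param kme named per-gene kME vector from [module_eigengenes()].
#' @param module_labels named module labels; unassigned genes are never hubs.
#' @param kme_min minimum `|kME|` (default 0.9, the usual convention).
#' @return named logical vector.
#' @export
identify_hubs <- function(kme, module_labels, kme_min = 0.9) {
  lab <- module_labels[names(kme)]
  hub <- !is.na(kme) & abs(kme) >= kme_min & lab != "unassigned"
  setNames(as.logical(hub), names(kme))
}

#' Guilt-by-association functional inference for a lncRNA
#'
#' Retrieves the protein-coding genes whose expression significantly
#' correlates with the lncRNA across samples (correlation-test p-values,
#' BH-adjusted, `q < alpha`), and — when at least `min_genes` qualify —
#' tests the correlated set for GO-term over-representation against all
#' protein-coding genes in the expression matrix via [hypergeom_enrich()].
#'
#' @param lnc_id lncRNA row name in `expr`.
#' @param expr expression matrix, genes x samples (log scale recommended),
#'   containing the lncRNA and the protein-coding genes.
#' @param pcg_ids protein-coding gene row names to correlate against.
#' @param go_map data.frame `gene_id`, `term_id` (see [read_go()]).
#' @param min_genes minimum correlated-set size to assess (default 30).
#' @param alpha BH-adjusted significance cutoff for correlations
#'   (default 0.05).
#' @return list with `assessed` (logical), `correlated` (gene ids), and
#'   `enrichment` (data.frame from [hypergeom_enrich()], or `NULL` when not
#'   assessed).
#' @export
guilt_by_association <- function(lnc_id, expr, pcg_ids, go_map,
                                 min_genes = 30L, alpha = 0.05) {
  if (!(lnc_id %in% rownames(expr))) stop("lncRNA ", lnc_id, " absent from expr")
  pcg_ids <- intersect(pcg_ids, rownames(expr))
  x <- expr[lnc_id, ]
  n <- length(x)
  r <- as.numeric(cor(t(expr[pcg_ids, , drop = FALSE]), x))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  q <- bh_adjust(p)
  correlated <- pcg_ids[!is.na(q) & q < alpha]
  if (length(correlated) < min_genes) {
    return(list(assessed = FALSE, correlated = correlated, enrichment = NULL))
  }
  enr <- hypergeom_enrich(correlated, pcg_ids, go_map)
  list(assessed = TRUE, correlated = correlated, enrichment = enr)
}
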