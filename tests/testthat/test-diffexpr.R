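test_that("MARS statistic has the documented symmetry and arithmetic", {
  r <- mars_test(100, 100, 1e7, 1e7)
  expect_equal(r$M, 0); expect_equal(r$z, 0); expect_equal(r$p, 1)
  expect_equal(mars_test(100, 50, 1e7, 1e7)$M, 1)
  # antisymmetry: swapping (c1,n1) and (c2,n2) negates M and z, keeps p
  a <- mars_test(c(120, 30), c(80, 90), 2e7, 1e7)
  b <- mars_test(c(80, 90), c(120, 30), 1e7, 2e7)
  expect_equal(a$M, -b$M); expect_equal(a$z, -b$z); expect_equal(a$p, b$p)
  # both-zero rows are undefined
  expect_true(is.na(mars_test(0, 0, 1e7, 1e7)$z))
  expect_error(mars_test(10, 10, 0, 1e7), "positive")
})

test_that("conditional moments match the Monte-Carlo binomial oracle", {
  # the contract: simulate binomial count pairs over a diffuse transcript
  # abundance distribution (as in a transcriptome), stratify by A, and the
  # model's E[M|A] and Var[M|A] must reproduce the empirical moments,
  # including with unequal library sizes
  set.seed(101)
  n1 <- 2e6; n2 <- 1e6
  p <- 10^runif(50000, -4.5, -3)    # expected counts ~60-2000
  c1 <- rbinom(50000, n1, p)
  c2 <- rbinom(50000, n2, p)
  keep <- c1 > 0 & c2 > 0
  M <- log2(c1[keep]) - log2(c2[keep])
  A <- (log2(c1[keep]) + log2(c2[keep])) / 2
  strata <- cut(A, quantile(A, seq(0, 1, 0.25)), include.lowest = TRUE)
  for (s in levels(strata)) {
    idx <- strata == s
    p_hat <- 2^mean(A[idx]) / sqrt(n1 * n2)
    model_var <- (1 - p_hat) / (log(2)^2 * p_hat) * (1 / n1 + 1 / n2)
    expect_equal(mean(M[idx]), log2(n1 / n2), tolerance = 0.03)
    expect_equal(var(M[idx]), model_var, tolerance = 0.12)
  }
  # and the standardised statistic is close to N(0,1)
  r <- mars_test(c1[keep], c2[keep], n1, n2)
  expect_equal(mean(r$z), 0, tolerance = 0.02)
  expect_equal(var(r$z), 1, tolerance = 0.05)
})

test_that("null rejection rates are calibrated at nominal levels", {
  set.seed(7)
  rates <- mars_null_calibration(n_genes = 6000L)
  expect_lt(abs(rates[2] - 0.05), 0.01)
  expect_lt(abs(rates[1] - 0.01), 0.005)
})

test_that("BH adjustment reproduces the hand step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))  # monotone after sorting by p
})

test_that("DE calling applies the conjunctive rule and the Venn partition", {
  set.seed(15)
  counts <- matrix(rpois(300, 200), 100, 3,
                   dimnames = list(paste0("t", 1:100), c("D0", "D30", "D240")))
  counts[1:5, "D0"] <- counts[1:5, "D0"] * 8       # DE in D0-vs-D30 and D0-vs-D240
  counts[6, "D0"] <- round(counts[6, "D30"] * 1.5) # below FC 2: must not be called
  cm <- count_matrix(counts, c(D0 = 1e7, D30 = 1e7, D240 = 1e7))
  de <- call_de(cm, list(c("D0", "D30"), c("D30", "D240"), c("D0", "D240")))
  expect_true(all(paste0("t", 1:5) %in% de$significant$D0_vs_D30))
  expect_false("t6" %in% de$significant$D0_vs_D30)
  expect_setequal(de$union, unique(unlist(de$significant)))
  expect_equal(sum(de$venn), length(de$union))
})

test_that("planted mixture yields controlled FDR and high recall", {
  set.seed(23)
  rates <- mars_mixture_rates(n_genes = 6000L)
  expect_gte(rates$recall, 0.95)
  expect_lte(rates$fdr, 0.05 + 2 * sqrt(0.05 * 0.95 / rates$n_called))
})

test_that("neighbour correlation pairs lncRNAs with the right genes", {
  # two slots: lnc far from gene (intergenic), lnc inside intron (intragenic)
  pcg <- make_tx(list(
    TXG1 = list(exons = cbind(c(6001, 7201), c(6500, 7700)), gene_id = "G1",
                biotype = "protein_coding"),
    TXG2 = list(exons = cbind(c(46001, 47201), c(46500, 47700)), gene_id = "G2",
                biotype = "protein_coding")
  ))
  lnc <- make_tx(list(
    L1 = list(exons = cbind(c(12001, 12501), c(12400, 12900))),
    L2 = list(exons = cbind(c(46551, 46951), c(46700, 47100)))
  ))
  cats <- c(L1 = "intergenic", L2 = "intronic")
  prof <- rnorm(11, 5, 1)
  rpkm <- rbind(L1 = 2^prof, G1 = 2^prof,            # identical profiles
                L2 = 2^prof, G2 = 2^rev(prof))
  colnames(rpkm) <- paste0("s", 1:11)
  out <- neighbor_correlation(lnc, cats, pcg, rpkm)
  p1 <- out$pairs[out$pairs$lnc_id == "L1", ]
  expect_equal(p1$pcg_id, "G1")
  expect_equal(p1$relation, "nearest_intergenic")
  expect_gt(p1$distance, 0)
  expect_equal(p1$r, 1)
  p2 <- out$pairs[out$pairs$lnc_id == "L2", ]
  expect_equal(p2$relation, "overlapped_intragenic")
  expect_equal(p2$distance, 0L)
})

test_that("planted neighbour correlation is recovered in the mean", {
  set.seed(33)
  n_pairs <- 200; n_samp <- 30
  lnc_spec <- list(); pcg_spec <- list(); rows <- list()
  for (i in seq_len(n_pairs)) {
    base <- (i - 1) * 50000
    pcg_spec[[paste0("TXG", i)]] <- list(
      exons = cbind(base + c(6001, 7201), base + c(6500, 7700)),
      gene_id = paste0("G", i), biotype = "protein_coding")
    lnc_spec[[paste0("L", i)]] <- list(
      exons = cbind(base + c(12001, 12501), base + c(12400, 12900)))
    x <- rnorm(n_samp)
    y <- 0.4 * x + sqrt(1 - 0.16) * rnorm(n_samp)
    rows[[paste0("L", i)]] <- 2^(5 + x)
    rows[[paste0("G", i)]] <- 2^(5 + y)
  }
  rpkm <- do.call(rbind, rows)
  colnames(rpkm) <- paste0("s", 1:n_samp)
  out <- neighbor_correlation(
    make_tx(lnc_spec), setNames(rep("intergenic", n_pairs), names(lnc_spec)),
    make_tx(pcg_spec), rpkm)
  expect_equal(unname(out$mean_r["nearest_intergenic"]), 0.4, tolerance = 0.05)
})
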