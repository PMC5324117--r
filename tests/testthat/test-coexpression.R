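module_matrix <- function(seed = 1, sizes = c(50, 50, 50), rho = 0.8,
                          n_samp = 30, trait_first = TRUE, noise = 0) {
  set.seed(seed)
  trait <- c(rep(0, n_samp - 10), rep(1, 10))
  rows <- list(); labels <- character(0)
  for (m in seq_along(sizes)) {
    f <- if (m == 1 && trait_first) trait + rnorm(n_samp, 0, 0.3) else rnorm(n_samp)
    f <- scale(f)[, 1]
    x <- sqrt(rho) * matrix(f, sizes[m], n_samp, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(sizes[m] * n_samp), sizes[m], n_samp)
    rows[[m]] <- x
    labels <- c(labels, rep(paste0("mod", m), sizes[m]))
  }
  if (noise > 0) {
    rows[[length(rows) + 1]] <- matrix(rnorm(noise * n_samp), noise, n_samp)
    labels <- c(labels, rep("unassigned", noise))
  }
  x <- do.call(rbind, rows)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samp))
  list(x = x, labels = setNames(labels, rownames(x)), trait = setNames(trait, colnames(x)))
}

test_that("adjacency and TOM satisfy their structural invariants", {
  mm <- module_matrix(seed = 4, sizes = c(20, 20), noise = 10)
  nw <- adjacency_tom(mm$x, beta = 6)
  for (m in list(nw$adjacency, nw$tom)) {
    expect_true(isSymmetric(m))
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
  # two identical profiles in a 2-gene network: a = TOM = 1
  x2 <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  nw2 <- adjacency_tom(x2, beta = 6)
  expect_equal(unname(nw2$adjacency["a", "b"]), 1)
  expect_equal(unname(nw2$tom["a", "b"]), 1)
  # constant row gives non-finite correlation -> error naming genes
  bad <- rbind(mm$x, const = rep(1, ncol(mm$x)))
  expect_error(adjacency_tom(bad), "non-finite")
})

test_that("TOM equals the brute-force triple loop to 1e-10", {
  set.seed(10)
  x <- matrix(rnorm(50 * 12), 50, 12)
  rownames(x) <- paste0("g", 1:50)
  nw <- adjacency_tom(x, beta = 6)
  expect_equal(max(abs(nw$tom - bf_tom(nw$adjacency))), 0, tolerance = 1e-10)
})

test_that("the scale-free fit index recognises degree-law shapes", {
  set.seed(66)
  k_pareto <- (1 - runif(5000))^(-1 / 1.5)  # p(k) ~ k^-2.5
  expect_gt(lncmap:::scale_free_fit(k_pareto), 0.9)
  # uniform degrees: p(k) rises with k in log bins, so the fit is negated
  expect_lt(lncmap:::scale_free_fit(runif(5000, 1, 10)), 0)
})

test_that("soft-threshold selection picks the smallest qualifying power", {
  mm <- module_matrix(seed = 6, sizes = c(15, 15), n_samp = 10)
  expect_warning(res <- pick_soft_threshold(mm$x, powers = 1:3, fit_min = 0.999),
                 "falling back to 6")
  expect_equal(res$beta, 6L)
  expect_equal(res$fit_table$power, 1:3)
  # mean connectivity decreases with the power
  expect_true(all(diff(res$fit_table$mean_k) < 0))
  # with heavy-tailed hub structure the fit floor is attainable and the
  # smallest qualifying power is chosen, reproducibly across seeds
  betas <- vapply(1:4, function(s) {
    set.seed(s)
    ns <- 200; ngene <- 500
    lam <- 0.95 * runif(ngene)^3   # many peripheral genes, few hubs
    x <- lam %o% rnorm(ns) +
      sqrt(1 - lam^2) * matrix(rnorm(ngene * ns), ngene)
    rownames(x) <- paste0("g", seq_len(ngene))
    res <- pick_soft_threshold(x, powers = 1:6, fit_min = 0.4)
    fits <- res$fit_table$fit
    expect_identical(res$beta, res$fit_table$power[which(fits >= 0.4)[1]])
    res$beta
  }, integer(1))
  expect_equal(length(unique(betas)), 1L)
})

test_that("module detection recovers planted blocks exactly", {
  mm <- module_matrix(seed = 2, sizes = c(50, 50, 50), rho = 0.9,
                      trait_first = FALSE)
  nw <- adjacency_tom(mm$x, beta = 6)
  mods <- detect_modules(nw)
  expect_equal(adjusted_rand_index(mods, mm$labels), 1.0)
  # cross-check our ARI against the mclust implementation
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(mods, mm$labels),
               mclust::adjustedRandIndex(mods, mm$labels))
})

test_that("pure-noise expression leaves most genes unassigned", {
  set.seed(14)
  x <- matrix(rnorm(150 * 30), 150, 30)
  rownames(x) <- paste0("g", 1:150)
  mods <- detect_modules(adjacency_tom(x, beta = 6))
  expect_gt(mean(mods == "unassigned"), 0.5)
})

test_that("duplicating every gene row preserves the partition structure", {
  mm <- module_matrix(seed = 12, sizes = c(40, 40), rho = 0.9,
                      trait_first = FALSE)
  x2 <- rbind(mm$x, mm$x + matrix(rnorm(length(mm$x), 0, 1e-6), nrow(mm$x)))
  rownames(x2) <- c(rownames(mm$x), paste0(rownames(mm$x), "_dup"))
  mods2 <- detect_modules(adjacency_tom(x2, beta = 6))
  truth2 <- setNames(rep(mm$labels, 2), rownames(x2))
  expect_equal(adjusted_rand_index(mods2, truth2), 1.0)
  expect_equal(sort(unname(table(mods2))), sort(unname(table(mm$labels) * 2)))
})

test_that("eigengenes behave like a first principal component", {
  # identical rows: |kME| = 1 for all members, sign convention positive
  x <- matrix(rep(c(1, 3, 2, 5, 4, 6), each = 4), 4, byrow = FALSE) +
    matrix(rnorm(24, 0, 1e-9), 4)
  rownames(x) <- paste0("g", 1:4); colnames(x) <- paste0("s", 1:6)
  labels <- setNames(rep("M1", 4), rownames(x))
  eg <- module_eigengenes(x, labels)
  expect_equal(unname(abs(eg$kme)), rep(1, 4), tolerance = 1e-6)
  xs <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_gt(cor(colMeans(xs), eg$eigengenes["M1", ]), 0)
  expect_equal(unname(sqrt(sum(eg$eigengenes["M1", ]^2))), 1)

  # variance explained matches a direct SVD oracle
  mm <- module_matrix(seed = 3, sizes = c(30, 30), trait_first = FALSE)
  eg2 <- module_eigengenes(mm$x, mm$labels)
  for (m in c("mod1", "mod2")) {
    xm <- mm$x[mm$labels == m, ]
    xm <- (xm - rowMeans(xm)) / apply(xm, 1, sd)
    d <- svd(xm)$d
    expect_equal(unname(eg2$var_explained[m]), d[1]^2 / sum(d^2),
                 tolerance = 1e-10)
  }

  # member order does not change the eigengene (sign fixed by convention)
  perm <- sample(nrow(mm$x))
  eg3 <- module_eigengenes(mm$x[perm, ], mm$labels[perm])
  expect_equal(eg3$eigengenes, eg2$eigengenes, tolerance = 1e-8)
})

test_that("module-trait correlation ranks the planted trait module first", {
  mm <- module_matrix(seed = 5)
  eg <- module_eigengenes(mm$x, mm$labels)
  mtc <- module_trait_correlation(eg$eigengenes, mm$trait)
  expect_equal(mtc$module[1], "mod1")
  expect_lt(mtc$p[1], 0.001)
  # eigengene equal to the trait: r = 1; orthogonal contrast: r near 0
  egx <- rbind(t1 = scale(mm$trait)[, 1] / sqrt(sum(scale(mm$trait)[, 1]^2)))
  m1 <- module_trait_correlation(egx, mm$trait)
  expect_equal(m1$r, 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(eg$eigengenes, rep(1, 30)), "constant")

  # planted trait module tops |r| in nearly all seeds
  hits <- vapply(1:20, function(s) {
    mmi <- module_matrix(seed = 100 + s)
    egi <- module_eigengenes(mmi$x, mmi$labels)
    module_trait_correlation(egi$eigengenes, mmi$trait)$module[1] == "mod1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("hub flags follow the kME threshold within assigned modules", {
  kme <- c(a = 0.95, b = 0.5, c = -0.92, d = 0.99)
  labels <- c(a = "M1", b = "M1", c = "M1", d = "unassigned")
  hubs <- identify_hubs(kme, labels)
  expect_equal(unname(hubs), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("guilt-by-association recovers a planted term and refuses small sets", {
  cfg <- sim_config(seed = 21L)
  net <- generate_network_data(cfg)
  x <- log2(compute_rpkm(net$counts, net$lengths) + 1)
  gba <- guilt_by_association(net$lnc_ids[1], x, net$pcg_ids, net$go_map)
  expect_true(gba$assessed)
  expect_gte(length(gba$correlated), 30)
  planted <- unname(net$go_truth["mod1"])
  expect_true(planted %in% gba$enrichment$term_id[gba$enrichment$q < 0.05])

  # an uncorrelated lncRNA is not assessed
  set.seed(99)
  x2 <- rbind(x, lonely = rnorm(ncol(x)))
  gba2 <- guilt_by_association("lonely", x2, net$pcg_ids, net$go_map)
  expect_false(gba2$assessed)
  expect_null(gba2$enrichment)
  # raising min_genes above the correlated-set size refuses assessment
  gba3 <- guilt_by_association(net$lnc_ids[1], x, net$pcg_ids, net$go_map,
                               min_genes = length(net$pcg_ids) + 1L)
  expect_false(gba3$assessed)
  expect_error(guilt_by_association("absent", x, net$pcg_ids, net$go_map),
               "absent")
})
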