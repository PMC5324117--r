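make_chain_set <- function(starts, ends, chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(starts, ends), strand = "+")
  mcols(gr) <- S4Vectors::DataFrame(
    q_name = "q", q_start = 0L, q_end = width(gr), q_strand = "+",
    chain_id = as.character(seq_along(gr)), score = 1000)
  structure(list(species_pair = "test", blocks = gr, headers = NULL),
            class = "chain_set")
}

test_that("chain coverage counts exonic bases once and matches the oracle", {
  tx <- make_tx(list(t1 = list(exons = cbind(c(1, 501), c(400, 1100)))))  # 1000 nt
  cs <- make_chain_set(c(1, 501), c(400, 700))  # covers 400 + 200 = 600
  expect_equal(unname(chain_coverage(tx, cs)), 0.6)
  none <- make_chain_set(5000, 6000)
  expect_equal(unname(chain_coverage(tx, none)), 0.0)
  # two chains covering the same exons: unique counting keeps it at 1
  dbl <- make_chain_set(c(1, 501, 1, 501), c(400, 1100, 400, 1100))
  expect_equal(unname(chain_coverage(tx, dbl)), 1.0)
  # chromosome absent from the chain file
  other <- make_chain_set(1, 1000, chrom = "chr9")
  expect_equal(unname(chain_coverage(tx, other)), 0.0)

  set.seed(55)
  for (i in 1:60) {
    e1 <- sort(sample(1:3000, 2)); e2 <- sort(sample(3500:7000, 2))
    exons <- rbind(e1, e2)
    bs <- sort(sample(1:7500, 8))
    cs <- make_chain_set(bs[c(1, 3, 5, 7)], bs[c(2, 4, 6, 8)])
    txi <- make_tx(list(tt = list(exons = exons)))
    got <- unname(chain_coverage(txi, cs))
    want <- bf_covered_fraction(exons, bs[c(1, 3, 5, 7)], bs[c(2, 4, 6, 8)])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("genome-conservation classes follow the >= threshold rule", {
  expect_equal(classify_genome_conservation(0.8, 0.7), "three_way")
  expect_equal(classify_genome_conservation(0.6, 0.1), "A_only")
  expect_equal(classify_genome_conservation(0.1, 0.5), "B_only")
  expect_equal(classify_genome_conservation(0.49, 0.49), "species_specific")
  expect_equal(classify_genome_conservation(0.5, 0.5), "three_way")  # boundary
  # species-label swap is symmetric
  set.seed(2)
  fa <- runif(100); fb <- runif(100)
  c1 <- classify_genome_conservation(fa, fb)
  c2 <- classify_genome_conservation(fb, fa)
  expect_equal(c2[c1 == "A_only"], rep("B_only", sum(c1 == "A_only")))
  expect_equal(c1 %in% c("three_way", "species_specific"),
               c2 %in% c("three_way", "species_specific"))
})

test_that("transcript homology merges the query-interval union", {
  lens <- c(t1 = 1000, t2 = 1000, t3 = 1000)
  hits <- data.frame(
    qseqid = c("t1", "t3", "t3"), sseqid = "s", pident = 90,
    length = c(300, 100, 100), mismatch = 0, gapopen = 0,
    qstart = c(1, 1, 51), qend = c(300, 100, 150),
    sstart = 1, send = 100, evalue = 1e-6, bitscore = 50)
  hom <- transcript_homology(lens, hits)
  expect_true(hom[["t1"]])    # 30% single hit
  expect_false(hom[["t2"]])   # no hits
  expect_false(hom[["t3"]])   # 10% + 10% overlapping by 5% -> union 15%
  bad <- hits; bad$qend[1] <- 1500
  expect_error(transcript_homology(lens, bad), "exceed")
})

test_that("planted conservation classes are recovered exactly", {
  cfg <- small_config(seed = 13L)
  ann <- generate_annotation(cfg)
  cons <- generate_conservation(ann, cfg)
  tr <- cons$conservation_truth
  tx <- ann$transcripts[tr$transcript_id]
  fh <- chain_coverage(tx, cons$chains$human)
  fm <- chain_coverage(tx, cons$chains$mouse)
  # realised fractions match the planted ones to 1-nt rounding
  expect_equal(unname(fh), tr$frac_human, tolerance = 2 / 400)
  expect_equal(unname(fm), tr$frac_mouse, tolerance = 2 / 400)
  expect_equal(unname(classify_genome_conservation(fh, fm)), tr$genome_class)
  # pig-specific transcripts intersect no blocks at all
  specific <- tr$transcript_id[tr$genome_class == "species_specific"]
  expect_true(all(fh[specific] == 0 & fm[specific] == 0))
  # planted transcript-level homology
  qlen <- exonic_length(tx)
  expect_equal(unname(transcript_homology(qlen, cons$hits$human)),
               tr$homology_human)
  expect_equal(unname(transcript_homology(qlen, cons$hits$mouse)),
               tr$homology_mouse)
})

test_that("conservation-specificity comparison detects a planted shift", {
  set.seed(77)
  mk <- function(n, conc) {
    # concentrated vectors have higher JS specificity
    t(vapply(seq_len(n), function(i) {
      e <- runif(11)
      e[sample(11, 1)] <- e[sample(11, 1)] + conc
      e
    }, numeric(11)))
  }
  expr <- rbind(mk(200, 30), mk(200, 0))
  rownames(expr) <- paste0("t", 1:400)
  js <- js_specificity(expr)
  calls <- data.frame(transcript_id = rownames(expr),
                      genome_class = rep(c("three_way", "species_specific"),
                                         each = 200))
  out <- conservation_vs_specificity(calls, js)
  expect_false(out$skipped)
  expect_lt(out$rank_sum$p.value, 0.05)
  expect_gt(out$by_class["three_way", "median"],
            out$by_class["species_specific", "median"])
  # too-small class is skipped
  small <- conservation_vs_specificity(calls[c(1, 201), ], js)
  expect_true(small$skipped)
})
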