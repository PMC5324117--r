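ref_annotation <- function() {
  # one protein-coding gene chr1:6001-8900 (+), exons 6001-6500, 7201-7700,
  # 8401-8900; one annotated lncRNA chr1:15001-16100 (+)
  make_tx(list(
    TX_G1 = list(exons = cbind(c(6001, 7201, 8401), c(6500, 7700, 8900)),
                 strand = "+", gene_id = "G1", biotype = "protein_coding"),
    ANN_L1 = list(exons = cbind(c(15001, 15801), c(15500, 16100)),
                  strand = "+", gene_id = "LG1", biotype = "annotated_lncRNA")
  ))
}

noncoding_table <- function(ids, coding_ids = character(0)) {
  data.frame(transcript_id = ids,
             cnci = ifelse(ids %in% coding_ids, "coding", "noncoding"),
             cpc = "noncoding", stringsAsFactors = FALSE)
}

test_that("each filter step fires in order and records the first failure", {
  ann <- ref_annotation()
  tx <- make_tx(list(
    mono = list(exons = cbind(40001, 45000), strand = "+"),          # 5 kb, 1 exon
    short = list(exons = cbind(c(40001, 40201), c(40080, 40270)), strand = "+"),
    overlap_sense = list(exons = cbind(c(6201, 7001), c(6700, 7400)), strand = "+"),
    coding_tx = list(exons = cbind(c(40001, 41001), c(40500, 41500)), strand = "+"),
    struct_rna = list(exons = cbind(c(50001, 51001), c(50500, 51500)), strand = "+"),
    lnc_model = list(exons = cbind(c(60001, 61001), c(60500, 61500)), strand = "+"),
    known_copy = list(exons = cbind(c(15001, 15801), c(15500, 16100)), strand = "+"),
    clean = list(exons = cbind(c(70001, 71001), c(70500, 71500)), strand = "+")
  ))
  ids <- mcols(tx)$transcript_id
  ncrna <- data.frame(
    transcript_id = c("struct_rna", "lnc_model"),
    family = c("snoRNA", "lncRNA_model"), stringsAsFactors = FALSE)
  v <- run_filter_pipeline(tx, ann, noncoding_table(ids, "coding_tx"), ncrna)
  fate <- setNames(v$step, v$transcript_id)
  expect_equal(fate[["mono"]], "multi_exon")
  expect_equal(fate[["short"]], "length")
  expect_equal(fate[["overlap_sense"]], "annotated_overlap")
  expect_equal(fate[["coding_tx"]], "coding_potential")
  expect_equal(fate[["struct_rna"]], "ncrna_homology")
  expect_equal(fate[["lnc_model"]], "retained")  # lncRNA-model-only match survives
  expect_equal(fate[["clean"]], "retained")
  # re-assembled known lncRNA bypasses the overlap step, flagged not-novel
  expect_equal(fate[["known_copy"]], "retained")
  expect_false(v$novel[v$transcript_id == "known_copy"])
  expect_true(v$novel[v$transcript_id == "clean"])
  # exhaustiveness: retained + removed partition the input
  expect_equal(sum(v$fate == "retained") + sum(v$fate == "removed"), length(ids))
  expect_true(all(!is.na(v$category[v$fate == "retained"])))
  expect_true(all(is.na(v$category[v$fate == "removed"])))
})

test_that("verdicts are invariant to transcript input order", {
  sim <- generate_annotation(small_config())
  v1 <- run_filter_pipeline(sim$transcripts, sim$annotation, sim$coding,
                            sim$ncrna)
  perm <- sample(length(sim$transcripts))
  v2 <- run_filter_pipeline(sim$transcripts[perm], sim$annotation,
                            sim$coding, sim$ncrna)
  v2 <- v2[match(v1$transcript_id, v2$transcript_id), ]
  rownames(v2) <- NULL
  expect_equal(v1, v2)
})

test_that("missing coding-potential entries error by default, configurable", {
  ann <- ref_annotation()
  tx <- make_tx(list(t1 = list(exons = cbind(c(40001, 41001), c(40500, 41500)))))
  empty_nc <- data.frame(transcript_id = character(0), family = character(0))
  expect_error(run_filter_pipeline(tx, ann, noncoding_table("other"), empty_nc),
               "coding-potential")
  v <- run_filter_pipeline(tx, ann, noncoding_table("other"), empty_nc,
                           missing_coding = "noncoding")
  expect_equal(v$fate, "retained")
})

test_that("positional categories follow the documented precedence", {
  ann <- ref_annotation()
  cases <- make_tx(list(
    far = list(exons = cbind(c(40001, 41001), c(40500, 41500)), strand = "+"),
    anti = list(exons = cbind(c(6201, 7001), c(6700, 7400)), strand = "-"),
    intr = list(exons = cbind(c(6551, 6951), c(6800, 7150)), strand = "+"),
    cis_up = list(exons = cbind(c(3601, 4401), c(4100, 4900)), strand = "+"),
    cis_down = list(exons = cbind(c(9401, 10001), c(9900, 10400)), strand = "-")
  ))
  got <- classify_position(cases, ann)
  expect_equal(got, c("intergenic", "antisense", "intronic",
                      "cis_regulatory", "cis_regulatory"))
})

test_that("classifier agrees with a brute-force per-base oracle", {
  set.seed(31)
  ann <- ref_annotation()
  genes <- list(list(gene_id = "G1", chrom = "chr1", strand = "+",
                     span = c(6001, 8900),
                     exons = cbind(c(6001, 7201, 8401), c(6500, 7700, 8900))))
  n_agree <- 0L
  n_cases <- 400L
  for (i in seq_len(n_cases)) {
    s1 <- sample(1000:12000, 1)
    w1 <- sample(100:600, 1); gap <- sample(50:400, 1); w2 <- sample(100:600, 1)
    exons <- cbind(c(s1, s1 + w1 + gap), c(s1 + w1 - 1, s1 + w1 + gap + w2 - 1))
    strand <- sample(c("+", "-"), 1)
    tx <- make_tx(list(tt = list(exons = exons, strand = strand)))
    got <- classify_position(tx, ann)
    want <- bf_classify("chr1", strand, exons, c(exons[1, 1], exons[2, 2]), genes)
    if (identical(got, want)) n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, n_cases)
})

test_that("interval_overlap_fraction matches hand and brute-force counts", {
  tx <- make_tx(list(t1 = list(exons = cbind(c(1, 201), c(100, 300)))))
  # feature (50,250) 0-based = 51..250 1-based: covers 50 + 50 of 200
  feat <- GRanges("chr1", IRanges(51, 250))
  expect_equal(unname(interval_overlap_fraction(tx, feat)), 0.5)
  expect_equal(unname(interval_overlap_fraction(tx, tx[["t1"]])), 1.0)
  expect_equal(unname(interval_overlap_fraction(
    tx, GRanges("chr1", IRanges(1000, 2000)))), 0.0)

  set.seed(17)
  for (i in 1:50) {
    e1 <- sort(sample(1:500, 2)); e2 <- sort(sample(600:1100, 2))
    exons <- rbind(e1, e2)
    fs <- sort(sample(1:1200, 6))
    feat <- GRanges("chr1", IRanges(fs[c(1, 3, 5)], fs[c(2, 4, 6)]))
    txi <- make_tx(list(tt = list(exons = exons)))
    got <- unname(interval_overlap_fraction(txi, feat))
    want <- bf_covered_fraction(exons, fs[c(1, 3, 5)], fs[c(2, 4, 6)])
    expect_equal(got, want, tolerance = 1e-12)
  }
})
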