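#' Simulation configuration
#'
#' Defaults define the standard study conditions emulated by the generator:
#' a compact annotated genome (one chromosome per 50 protein-coding genes,
#' genes well spaced so the 2 kb positional geometry is realisable), 20
#' planted lncRNAs per positional category, 10 decoys per rejection class,
#' 11 tissue samples (9 organs plus skeletal muscle at postnatal days 0, 30
#' and 240), negative-binomial counts, and a separate 30-sample matrix with
#' block-correlated co-expression modules tied to a binary muscle trait.
#'
#' @param seed integer RNG seed.
#' @param n_pcg number of protein-coding genes (>= number of planted
#'   elements).
#' @param n_lnc_per_category planted lncRNAs per positional category.
#' @param n_decoys_per_class decoys per rejection class (mono-exonic, short,
#'   annotated-overlap, coding).
#' @param n_annotated_lnc known lncRNAs present in the annotation and
#'   re-assembled in the transcript set.
#' @param library_size per-sample mapped read pairs.
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param frac_tissue_specific fraction of planted lncRNAs expressed in a
#'   single tissue.
#' @param n_de number of planted stage-differential transcripts.
#' @param de_log2fc planted log2 fold change between muscle stages.
#' @param specific_rpkm,ubiquitous_rpkm planted RPKM levels.
#' @param module_spec list of `list(size, rho, trait)` module definitions
#'   for the network matrix.
#' @param n_network_samples,n_network_muscle network matrix design: total
#'   samples and how many are muscle (trait = 1).
#' @param n_noise_genes unstructured genes added to the network matrix.
#' @param n_module_lnc lncRNAs planted into the first module.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 42L, n_pcg = 200L, n_lnc_per_category = 20L,
                       n_decoys_per_class = 10L, n_annotated_lnc = 5L,
                       library_size = 2e7, dispersion = 0.05,
                       frac_tissue_specific = 0.5, n_de = 30L, de_log2fc = 2,
                       specific_rpkm = 8, ubiquitous_rpkm = 2, de_rpkm = 8,
                       module_spec = list(
                         list(size = 50L, rho = 0.8, trait = TRUE),
                         list(size = 50L, rho = 0.8, trait = FALSE),
                         list(size = 50L, rho = 0.8, trait = FALSE)
                       ),
                       n_network_samples = 30L, n_network_muscle = 10L,
                       n_noise_genes = 100L, n_module_lnc = 5L) {
  cfg <- list(
    seed = as.integer(seed), n_pcg = as.integer(n_pcg),
    n_lnc_per_category = as.integer(n_lnc_per_category),
    n_decoys_per_class = as.integer(n_decoys_per_class),
    n_annotated_lnc = as.integer(n_annotated_lnc),
    library_size = library_size, dispersion = dispersion,
    frac_tissue_specific = frac_tissue_specific, n_de = as.integer(n_de),
    de_log2fc = de_log2fc, specific_rpkm = specific_rpkm,
    ubiquitous_rpkm = ubiquitous_rpkm, de_rpkm = de_rpkm,
    module_spec = module_spec,
    n_network_samples = as.integer(n_network_samples),
    n_network_muscle = as.integer(n_network_muscle),
    n_noise_genes = as.integer(n_noise_genes),
    n_module_lnc = as.integer(n_module_lnc),
    tissues = c("adipose", "heart", "kidney", "liver", "lung", "ovary",
                "spleen", "testis", "muscle_D0", "muscle_D30", "muscle_D240")
  )
  stopifnot(cfg$n_pcg >= 1L, cfg$n_lnc_per_category >= 1L,
            cfg$dispersion >= 0,
            all(vapply(module_spec, function(m) m$rho > 0 && m$rho <= 1, logical(1))))
  n_elements <- 4L * cfg$n_lnc_per_category + 4L * cfg$n_decoys_per_class +
    cfg$n_annotated_lnc
  if (n_elements > cfg$n_pcg) {
    stop("requested ", n_elements, " planted elements but only ", cfg$n_pcg,
         " gene slots; increase n_pcg to at least ", n_elements)
  }
  class(cfg) <- "sim_config"
  cfg
}

## slot-local 0-based exon offsets for each planted element kind
.slot_geometry <- list(
  gene = list(exons = cbind(c(6000, 7200, 8400), c(6500, 7700, 8900))),
  intergenic = list(exons = cbind(c(12000, 12700), c(12400, 13100))),
  antisense = list(exons = cbind(c(6200, 7000), c(6700, 7400))),
  intronic = list(exons = cbind(c(6550, 6950), c(6800, 7150))),
  cis_regulatory = list(exons = cbind(c(3600, 4400), c(4100, 4900))),
  annotated_lnc = list(exons = cbind(c(15000, 15800), c(15500, 16100))),
  mono_exonic = list(exons = cbind(12000, 13200)),
  short = list(exons = cbind(c(12000, 12300), c(12080, 12370))),
  annotated_overlap = list(exons = cbind(c(6200, 7000), c(6700, 7400))),
  coding = list(exons = cbind(c(12000, 12700), c(12400, 13100)))
)
.slot_width <- 20000L
.slots_per_chrom <- 50L

slot_exons <- function(kind, slot0, chrom, strand, tid, gid, biotype) {
  g <- .slot_geometry[[kind]]$exons
  GRanges(chrom, IRanges(slot0 + g[, 1] + 1L, slot0 + g[, 2]),
          strand = strand, transcript_id = tid, gene_id = gid,
          biotype = biotype)
}

#' Generate the synthetic annotation and assembled transcript set
#'
#' Lays out protein-coding genes on evenly spaced 20 kb slots (gene spacing
#' >= 6 kb) and plants, one element per slot: lncRNAs of the four positional
#' categories (intergenic >= 2 kb from any gene; antisense overlapping an
#' annotated exon on the opposite strand; intronic wholly inside an intron;
#' cis-regulatory within 2 kb of a gene span without exon overlap), known
#' lncRNAs re-assembled in the transcript set, and decoys for each filter
#' step (mono-exonic; < 200 nt; same-strand annotated overlap; coding —
#' flagged in the emitted coding-potential table). Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` and `transcripts` (transcript sets),
#'   `coding` and `ncrna` tables, `sequences` (DNAStringSet for the
#'   assembled transcripts), `snps` (`GRanges`), and `truth` (planted
#'   categories, decoy steps, novelty).
#' @export
generate_annotation <- function(config = sim_config()) {
  set.seed(config$seed)
  n_chrom <- ceiling(config$n_pcg / .slots_per_chrom)
  chrom_of <- function(slot) paste0("chr", (slot - 1L) %/% .slots_per_chrom + 1L)
  slot0_of <- function(slot) ((slot - 1L) %% .slots_per_chrom) * .slot_width

  gene_strand <- sample(c("+", "-"), config$n_pcg, replace = TRUE)
  ann <- list()
  for (i in seq_len(config$n_pcg)) {
    gid <- sprintf("PCG_%04d", i)
    ann[[length(ann) + 1L]] <- slot_exons("gene", slot0_of(i), chrom_of(i),
                                          gene_strand[i], paste0("TX_", gid),
                                          gid, "protein_coding")
  }

  categories <- c("intergenic", "antisense", "intronic", "cis_regulatory")
  plan <- data.frame(
    kind = c(rep(categories, each = config$n_lnc_per_category),
             rep("annotated_lnc", config$n_annotated_lnc),
             rep(c("mono_exonic", "short", "annotated_overlap", "coding"),
                 each = config$n_decoys_per_class)),
    stringsAsFactors = FALSE
  )
  plan$slot <- seq_len(nrow(plan))
  plan$transcript_id <- sprintf("%s_%03d",
                                toupper(sub("_regulatory", "", plan$kind)),
                                seq_len(nrow(plan)))

  tx <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(plan))) {
    kind <- plan$kind[i]
    slot <- plan$slot[i]
    host_strand <- gene_strand[slot]
    strand_i <- if (kind == "antisense") {
      setdiff(c("+", "-"), host_strand)
    } else if (kind %in% c("intronic", "annotated_overlap", "annotated_lnc")) {
      host_strand
    } else {
      sample(c("+", "-"), 1L)
    }
    tid <- plan$transcript_id[i]
    if (kind == "annotated_lnc") {
      lnc_gid <- sprintf("LNCG_%03d", i)
      ann[[length(ann) + 1L]] <- slot_exons("annotated_lnc", slot0_of(slot),
                                            chrom_of(slot), strand_i,
                                            paste0("ANN_", tid), lnc_gid,
                                            "annotated_lncRNA")
      tx[[length(tx) + 1L]] <- slot_exons("annotated_lnc", slot0_of(slot),
                                          chrom_of(slot), strand_i, tid, tid,
                                          "novel")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = tid, role = "lncRNA", category = "intergenic",
        novel = FALSE, step = NA_character_, stringsAsFactors = FALSE)
    } else if (kind %in% categories) {
      tx[[length(tx) + 1L]] <- slot_exons(kind, slot0_of(slot),
                                          chrom_of(slot), strand_i, tid, tid,
                                          "novel")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = tid, role = "lncRNA", category = kind, novel = TRUE,
        step = NA_character_, stringsAsFactors = FALSE)
    } else {
      tx[[length(tx) + 1L]] <- slot_exons(kind, slot0_of(slot),
                                          chrom_of(slot), strand_i, tid, tid,
                                          "novel")
      step <- switch(kind, mono_exonic = "multi_exon", short = "length",
                     annotated_overlap = "annotated_overlap",
                     coding = "coding_potential")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = tid, role = "decoy", category = NA_character_,
        novel = NA, step = step, stringsAsFactors = FALSE)
    }
  }

  seqinfo <- Seqinfo(paste0("chr", seq_len(n_chrom)),
                     rep(.slots_per_chrom * .slot_width + 10000L, n_chrom))
  annotation <- transcript_set(suppressWarnings(unlist(GRangesList(ann))))
  transcripts <- transcript_set(suppressWarnings(unlist(GRangesList(tx))))
  truth <- do.call(rbind, truth_rows)

  ## coding-potential table: two upstream callers; coding decoys are flagged
  ## by at least one of them
  ids <- mcols(transcripts)$transcript_id
  is_coding_decoy <- ids %in% truth$transcript_id[truth$step %in% "coding_potential"]
  caller2 <- ifelse(is_coding_decoy & runif(length(ids)) < 0.5, "coding",
                    "noncoding")
  coding <- data.frame(
    transcript_id = ids,
    cnci = ifelse(is_coding_decoy, "coding", "noncoding"),
    cpc = caller2,
    stringsAsFactors = FALSE
  )

  ## ncRNA homology: a quarter of planted lncRNAs match conserved lncRNA
  ## models exclusively (and must survive filter step 5)
  lnc_ids <- truth$transcript_id[truth$role == "lncRNA"]
  model_hit <- lnc_ids[seq_along(lnc_ids) %% 4L == 0L]
  ncrna <- data.frame(transcript_id = model_hit,
                      family = rep("lncRNA_model", length(model_hit)),
                      stringsAsFactors = FALSE)

  ## transcript sequences with class-typical GC content
  gc <- ifelse(ids %in% lnc_ids, 0.478, 0.45)
  sequences <- random_dna(exonic_length(transcripts), gc)
  names(sequences) <- ids

  ## SNPs at class-typical exonic densities (per kb), plus PCG exons
  snps <- c(
    place_snps(transcripts[truth$transcript_id[truth$role == "lncRNA"]], 15.47),
    place_snps(annotation[mcols(annotation)$biotype == "protein_coding"], 8.57)
  )
  snps <- sort(snps)

  list(annotation = annotation, transcripts = transcripts, coding = coding,
       ncrna = ncrna, sequences = sequences, snps = snps,
       truth = truth, seqinfo = seqinfo, config = config)
}

random_dna <- function(lengths, gc) {
  gc <- rep_len(gc, length(lengths))
  seqs <- vapply(seq_along(lengths), function(i) {
    probs <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE,
                 prob = probs), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

place_snps <- function(tx, per_kb) {
  ex <- unlist(tx, use.names = FALSE)
  n <- rpois(length(ex), width(ex) / 1e3 * per_kb)
  pos <- unlist(lapply(seq_along(ex), function(i) {
    if (n[i] == 0L) return(integer(0))
    sort(sample(start(ex)[i]:end(ex)[i], min(n[i], width(ex)[i])))
  }))
  if (length(pos) == 0L) return(GRanges())
  chrom <- rep(as.character(seqnames(ex)), vapply(seq_along(ex), function(i)
    min(n[i], width(ex)[i]), integer(1)))
  GRanges(chrom, IRanges(pos, width = 1L), strand = "*")
}

#' Generate the 11-sample tissue count matrix with planted expression truth
#'
#' Counts follow a negative-binomial model with
#' `mean = RPKM * exonic_length/1e3 * library_size/1e6` and configured
#' dispersion (Poisson at dispersion 0). Planted structure: protein-coding
#' genes are ubiquitous; a configured fraction of planted lncRNAs is
#' expressed in exactly one tissue (zero elsewhere), the rest are
#' ubiquitous; a planted subset is stage-differential between skeletal
#' muscle samples with the configured log2 fold change; the nearest
#' protein-coding gene of each intergenic lncRNA receives a correlated
#' log-expression component so neighbour correlation is positive by
#' construction.
#'
#' @param ann result of [generate_annotation()].
#' @param config the [sim_config()] (defaults to `ann$config`).
#' @return list with `counts` (a `count_matrix` over assembled transcripts
#'   plus protein-coding genes), `rpkm_planted` (the noise-free RPKM
#'   matrix), `lengths`, and truth tables `specificity_truth`
#'   (`transcript_id`, `tissue` or "ubiquitous") and `de_truth`
#'   (`transcript_id`, `pair`, `log2fc`).
#' @export
generate_expression <- function(ann, config = ann$config) {
  set.seed(config$seed + 1L)
  tissues <- config$tissues
  truth <- ann$truth
  lnc_ids <- truth$transcript_id[truth$role == "lncRNA"]
  decoy_ids <- truth$transcript_id[truth$role == "decoy"]
  pcg_ids <- unique(mcols(ann$annotation)$gene_id[
    mcols(ann$annotation)$biotype == "protein_coding"])

  tx_len <- exonic_length(ann$transcripts)
  pcg_len <- setNames(
    as.numeric(exonic_length(ann$annotation))[
      match(pcg_ids, mcols(ann$annotation)$gene_id)], pcg_ids)
  lengths <- c(tx_len, pcg_len)

  ids <- c(names(tx_len), pcg_ids)
  rpkm <- matrix(0, length(ids), length(tissues),
                 dimnames = list(ids, tissues))

  ## lncRNAs: tissue-specific vs ubiquitous, round-robin over tissues
  n_spec <- round(config$frac_tissue_specific * length(lnc_ids))
  spec_ids <- lnc_ids[seq_len(n_spec)]
  spec_tissue <- tissues[(seq_along(spec_ids) - 1L) %% length(tissues) + 1L]
  ubiq_ids <- setdiff(lnc_ids, spec_ids)
  for (i in seq_along(spec_ids)) {
    rpkm[spec_ids[i], spec_tissue[i]] <- config$specific_rpkm
  }
  rpkm[ubiq_ids, ] <- config$ubiquitous_rpkm
  rpkm[decoy_ids, ] <- 1

  ## protein-coding genes: ubiquitous log-normal baseline
  pcg_base <- exp(rnorm(length(pcg_ids), log(20), 0.5))
  rpkm[pcg_ids, ] <- pcg_base

  specificity_truth <- data.frame(
    transcript_id = c(spec_ids, ubiq_ids),
    tissue = c(spec_tissue, rep("ubiquitous", length(ubiq_ids))),
    stringsAsFactors = FALSE
  )

  ## planted stage-differential transcripts (ubiquitous lncRNAs so both
  ## stages have signal); pattern: high in one muscle stage
  de_ids <- ubiq_ids[seq_len(min(config$n_de, length(ubiq_ids)))]
  stage <- c("muscle_D0", "muscle_D30", "muscle_D240")
  high_stage <- stage[(seq_along(de_ids) - 1L) %% 3L + 1L]
  rpkm[de_ids, ] <- config$de_rpkm  # high-count baseline so the planted
                                    # change is recoverable over NB noise
  for (i in seq_along(de_ids)) {
    rpkm[de_ids[i], high_stage[i]] <-
      rpkm[de_ids[i], high_stage[i]] * 2^config$de_log2fc
  }
  pair_names <- c("muscle_D0_vs_muscle_D30", "muscle_D30_vs_muscle_D240",
                  "muscle_D0_vs_muscle_D240")
  de_truth <- do.call(rbind, lapply(seq_along(de_ids), function(i) {
    lfc <- c(
      log2(rpkm[de_ids[i], "muscle_D0"] / rpkm[de_ids[i], "muscle_D30"]),
      log2(rpkm[de_ids[i], "muscle_D30"] / rpkm[de_ids[i], "muscle_D240"]),
      log2(rpkm[de_ids[i], "muscle_D0"] / rpkm[de_ids[i], "muscle_D240"])
    )
    data.frame(transcript_id = de_ids[i], pair = pair_names, log2fc = lfc,
               stringsAsFactors = FALSE)
  }))

  ## correlated neighbour structure: each intergenic lncRNA's host-slot gene
  ## tracks the lncRNA's log profile
  inter_ids <- truth$transcript_id[truth$role == "lncRNA" &
                                   truth$category == "intergenic" &
                                   truth$novel %in% TRUE]
  for (tid in intersect(inter_ids, rownames(rpkm))) {
    sp <- transcript_span(ann$transcripts[tid])
    gsp <- gene_spans(ann$annotation[mcols(ann$annotation)$biotype == "protein_coding"])
    same <- as.character(seqnames(gsp)) == as.character(seqnames(sp))
    j <- which(same)[which.min(distance(sp, gsp[same], ignore.strand = TRUE))]
    gid <- mcols(gsp)$gene_id[j]
    prof <- log2(rpkm[tid, ] + 1)
    if (sd(prof) > 0) {
      z <- (prof - mean(prof)) / sd(prof)
      rpkm[gid, ] <- 2^(log2(rpkm[gid, ]) + 0.5 * z)
    }
  }

  mu <- rpkm * (lengths[ids] / 1e3) * (config$library_size / 1e6)
  counts <- draw_nb(mu, config$dispersion)
  dimnames(counts) <- dimnames(rpkm)
  cm <- count_matrix(counts,
                     setNames(rep(config$library_size, length(tissues)),
                              tissues))
  list(counts = cm, rpkm_planted = rpkm, lengths = lengths,
       specificity_truth = specificity_truth, de_truth = de_truth)
}

draw_nb <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) {
    matrix(rpois(n, mu), nrow = nrow(mu))
  } else {
    matrix(rnbinom(n, mu = mu, size = 1 / dispersion), nrow = nrow(mu))
  }
}

#' Generate chain files and hit tables with planted conservation classes
#'
#' For each planted lncRNA, a 4-way genome-conservation class is drawn with
#' realistic prevalences (three-way conserved most common, then
#' mouse-only, human-only, species-specific) and chain blocks are laid
#' down along the transcript's exons to realise the planted covered
#' fraction per species (species-specific transcripts get no blocks).
#' BLAST-style hit tables plant transcript-level homology: homologous
#' transcripts get a hit covering 30% of the query, non-homologous ones
#' either none or a 10% hit.
#'
#' @param ann result of [generate_annotation()].
#' @param config the [sim_config()].
#' @return list with `chains` (named list of `chain_set`, species "human"
#'   and "mouse"), `hits` (named list of hit tables), and
#'   `conservation_truth` (`transcript_id`, planted fractions, class,
#'   per-species homology).
#' @export
generate_conservation <- function(ann, config = ann$config) {
  set.seed(config$seed + 2L)
  truth <- ann$truth
  lnc_ids <- truth$transcript_id[truth$role == "lncRNA"]
  classes <- sample(c("three_way", "A_only", "B_only", "species_specific"),
                    length(lnc_ids), replace = TRUE,
                    prob = c(0.575, 0.067, 0.128, 0.23))
  hi <- function(n) runif(n, 0.55, 0.95)
  lo <- function(n) runif(n, 0.05, 0.45)
  n <- length(lnc_ids)
  frac_a <- ifelse(classes == "three_way", hi(n),
            ifelse(classes == "A_only", hi(n),
            ifelse(classes == "B_only", lo(n), 0)))
  frac_b <- ifelse(classes == "three_way", hi(n),
            ifelse(classes == "B_only", hi(n),
            ifelse(classes == "A_only", lo(n), 0)))
  hom_a <- runif(n) < 0.45
  hom_b <- runif(n) < 0.29

  tx <- ann$transcripts[lnc_ids]
  chains <- list(
    human = build_chain(tx, setNames(frac_a, lnc_ids), "human"),
    mouse = build_chain(tx, setNames(frac_b, lnc_ids), "mouse")
  )
  hits <- list(
    human = build_hits(tx, setNames(hom_a, lnc_ids), "HUMAN"),
    mouse = build_hits(tx, setNames(hom_b, lnc_ids), "MOUSE")
  )
  conservation_truth <- data.frame(
    transcript_id = lnc_ids, frac_human = frac_a, frac_mouse = frac_b,
    genome_class = classes, homology_human = hom_a, homology_mouse = hom_b,
    stringsAsFactors = FALSE
  )
  list(chains = chains, hits = hits, conservation_truth = conservation_truth)
}

## lay chain blocks over the 5'-most exonic nucleotides of each transcript
## until round(frac * exonic_length) bases are covered
build_chain <- function(tx, frac, species) {
  headers <- list(); blocks <- list(); q_off <- 0L
  lens <- exonic_length(tx)
  for (i in seq_along(tx)) {
    target_n <- round(frac[i] * lens[i])
    if (target_n < 1L) next
    ex <- sort(tx[[i]])
    covered <- IRanges()
    left <- target_n
    for (j in seq_along(ex)) {
      take <- min(left, width(ex)[j])
      if (take > 0L) {
        covered <- c(covered, IRanges(start(ex)[j], width = take))
        left <- left - take
      }
      if (left == 0L) break
    }
    sizes <- width(covered)
    t0 <- start(covered) - 1L
    chain_id <- as.character(length(headers) + 1L)
    chrom <- as.character(seqnames(ex))[1L]
    q_name <- paste0("q", species, "_", chain_id)
    hd <- data.frame(
      score = 1000 + i, t_name = chrom, t_size = 1010000L,
      t_strand = "+", t_start = t0[1L], t_end = t0[length(t0)] + sizes[length(sizes)],
      q_name = q_name, q_size = sum(sizes), q_strand = "+",
      q_start = 0L, q_end = sum(sizes), chain_id = chain_id,
      stringsAsFactors = FALSE
    )
    q0 <- cumsum(c(0L, sizes[-length(sizes)]))
    gr <- GRanges(chrom, IRanges(t0 + 1L, t0 + sizes), strand = "+")
    mcols(gr) <- DataFrame(q_name = q_name, q_start = q0, q_end = q0 + sizes,
                           q_strand = "+", chain_id = chain_id,
                           score = hd$score)
    headers[[length(headers) + 1L]] <- hd
    blocks[[length(blocks) + 1L]] <- gr
    q_off <- q_off + sum(sizes)
  }
  structure(
    list(species_pair = paste0("pig_to_", species),
         blocks = if (length(blocks)) unlist(GRangesList(blocks)) else GRanges(),
         headers = if (length(headers)) do.call(rbind, headers) else NULL),
    class = "chain_set"
  )
}

build_hits <- function(tx, homologous, subject_prefix) {
  lens <- exonic_length(tx)
  rows <- list()
  for (i in seq_along(tx)) {
    tid <- names(lens)[i]
    if (homologous[i]) {
      len <- max(ceiling(0.3 * lens[i]), ceiling(0.2 * lens[i]) + 2L)
    } else {
      if (runif(1) < 0.5) next
      len <- max(floor(0.1 * lens[i]), 10L)
    }
    len <- min(len, lens[i])
    rows[[length(rows) + 1L]] <- data.frame(
      qseqid = tid, sseqid = paste0(subject_prefix, "_", i), pident = 85.0,
      length = len, mismatch = round(0.15 * len), gapopen = 0L,
      qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = 1e-5, bitscore = 100.0, stringsAsFactors = FALSE
    )
  }
  if (length(rows)) do.call(rbind, rows) else empty_hits()
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Generate the 30-sample network expression matrix with planted modules
#'
#' Genes in each configured module share a latent factor; for trait-linked
#' modules the factor is the binary muscle vector plus Gaussian noise
#' (sd 0.3), for others it is standard normal. Gene log2-expression is
#' `sqrt(rho) * factor + sqrt(1 - rho) * noise` (so the planted
#' within-module correlation is `rho`), mapped to RPKM around a baseline of
#' 32 and converted to low-dispersion negative-binomial counts. Unstructured
#' noise genes and a handful of module-member lncRNAs are added, plus a GO
#' map in which each module's protein-coding genes carry one planted term.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a `count_matrix`, genes x 30 samples),
#'   `lengths`, `trait` (binary muscle vector), `module_truth` (named
#'   labels: `mod1`, `mod2`, ..., `unassigned`), `go_map`, `go_truth`
#'   (planted term per module), `lnc_ids` and `pcg_ids`.
#' @export
generate_network_data <- function(config = sim_config()) {
  set.seed(config$seed + 3L)
  ns <- config$n_network_samples
  trait <- c(rep(0, ns - config$n_network_muscle),
             rep(1, config$n_network_muscle))
  samples <- sprintf("NS%02d", seq_len(ns))
  names(trait) <- samples

  spec <- config$module_spec
  gene_rows <- list(); labels <- character(0); gids <- character(0)
  for (m in seq_along(spec)) {
    sz <- spec[[m]]$size; rho <- spec[[m]]$rho
    f <- if (isTRUE(spec[[m]]$trait)) trait + rnorm(ns, 0, 0.3) else rnorm(ns)
    f <- (f - mean(f)) / sd(f)
    x <- sqrt(rho) * matrix(f, sz, ns, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(sz * ns), sz, ns)
    gene_rows[[m]] <- x
    labels <- c(labels, rep(paste0("mod", m), sz))
    gids <- c(gids, sprintf("NPCG_m%d_%03d", m, seq_len(sz)))
  }
  if (config$n_noise_genes > 0L) {
    noise <- matrix(rnorm(config$n_noise_genes * ns), config$n_noise_genes, ns)
    gene_rows[[length(gene_rows) + 1L]] <- noise
    labels <- c(labels, rep("unassigned", config$n_noise_genes))
    gids <- c(gids, sprintf("NPCG_bg_%03d", seq_len(config$n_noise_genes)))
  }

  ## lncRNAs tracking module 1's factor
  lnc_ids <- character(0)
  if (config$n_module_lnc > 0L) {
    f1 <- colMeans(gene_rows[[1L]])
    lnc <- matrix(f1, config$n_module_lnc, ns, byrow = TRUE) +
      matrix(rnorm(config$n_module_lnc * ns, 0, 0.3), config$n_module_lnc, ns)
    gene_rows[[length(gene_rows) + 1L]] <- lnc
    labels <- c(labels, rep("mod1", config$n_module_lnc))
    lnc_ids <- sprintf("NLNC_%02d", seq_len(config$n_module_lnc))
    gids <- c(gids, lnc_ids)
  }

  x <- do.call(rbind, gene_rows)
  rownames(x) <- gids
  colnames(x) <- samples
  rpkm <- 2^(log2(32) + x)
  lengths <- setNames(rep(1000, length(gids)), gids)
  mu <- rpkm * (lengths / 1e3) * (config$library_size / 1e6)
  counts <- draw_nb(mu, 0.02)
  dimnames(counts) <- dimnames(x)
  pcg_ids <- setdiff(gids, lnc_ids)

  terms <- setNames(sprintf("GO:MOD%d", seq_along(spec)),
                    paste0("mod", seq_along(spec)))
  pcg_labels <- labels[seq_along(pcg_ids)]
  keep <- pcg_labels != "unassigned"
  go_rows <- data.frame(gene_id = pcg_ids[keep],
                        term_id = unname(terms[pcg_labels[keep]]),
                        stringsAsFactors = FALSE)
  bg_terms <- do.call(rbind, lapply(1:5, function(b) {
    members <- sample(pcg_ids, round(0.3 * length(pcg_ids)))
    data.frame(gene_id = members, term_id = sprintf("GO:BG%02d", b),
               stringsAsFactors = FALSE)
  }))
  go_map <- unique(rbind(go_rows, bg_terms))
  rownames(go_map) <- NULL

  list(
    counts = count_matrix(counts, setNames(rep(config$library_size, ns), samples)),
    lengths = lengths, trait = trait,
    module_truth = setNames(labels, gids),
    go_map = go_map, go_truth = terms,
    lnc_ids = lnc_ids, pcg_ids = pcg_ids
  )
}

#' Generate and write the full synthetic dataset
#'
#' Runs [generate_annotation()], [generate_expression()],
#' [generate_conservation()] and [generate_network_data()] and writes every
#' file the pipeline reads (GTF, FASTA, coding/ncRNA tables, counts TSVs,
#' SNP BED, chain files, hit tables, GO map, trait TSV) plus a `truth.json`.
#' Identical seed and config give byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with all generated objects, truths, and `paths`.
#' @export
simulate_lnc_dataset <- function(config = sim_config(), dir = tempfile("lncsim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  expr <- generate_expression(ann, config)
  cons <- generate_conservation(ann, config)
  net <- generate_network_data(config)

  p <- function(f) file.path(dir, f)
  write_gtf(ann$annotation, p("annotation.gtf"))
  write_gtf(ann$transcripts, p("transcripts.gtf"))
  Biostrings::writeXStringSet(ann$sequences, p("transcripts.fa"))
  write.table(ann$coding, p("coding.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ann$ncrna, p("ncrna.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(ann$snps, p("snps.bed"))
  write_counts(expr$counts, p("counts.tsv"))
  write_chain(cons$chains$human, p("pig_to_human.chain"))
  write_chain(cons$chains$mouse, p("pig_to_mouse.chain"))
  write_hits(cons$hits$human, p("hits_human.tsv"))
  write_hits(cons$hits$mouse, p("hits_mouse.tsv"))
  write_counts(net$counts, p("network_counts.tsv"))
  write_go(net$go_map, p("go_map.tsv"))
  write.table(data.frame(sample = names(net$trait), muscle = net$trait),
              p("trait.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    filter = ann$truth,
    specificity = expr$specificity_truth,
    de = expr$de_truth,
    conservation = cons$conservation_truth,
    modules = as.list(net$module_truth),
    go = as.list(net$go_truth)
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)

  paths <- list(
    annotation = p("annotation.gtf"), transcripts = p("transcripts.gtf"),
    fasta = p("transcripts.fa"), coding = p("coding.tsv"),
    ncrna = p("ncrna.tsv"), snps = p("snps.bed"), counts = p("counts.tsv"),
    chain_human = p("pig_to_human.chain"), chain_mouse = p("pig_to_mouse.chain"),
    hits_human = p("hits_human.tsv"), hits_mouse = p("hits_mouse.tsv"),
    network_counts = p("network_counts.tsv"), go_map = p("go_map.tsv"),
    trait = p("trait.tsv"), truth = p("truth.json")
  )
  invisible(list(annotation = ann, expression = expr, conservation = cons,
                 network = net, truth = truth, paths = paths, dir = dir,
                 config = config))
}
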