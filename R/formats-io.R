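#' Read a GTF file into a transcript set
#'
#' Parses `exon` features (Ensembl GTF dialect) and groups them per
#' transcript. Coordinates arrive 1-based inclusive and are held as
#' `GRanges`; conversion to/from other on-disk conventions happens only in
#' the readers and writers.
#'
#' @param path path to a GTF file.
#' @return a transcript set (see [transcript_set()]); the `biotype` column is
#'   taken from the `transcript_biotype` attribute, defaulting to `"novel"`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  tid <- mcols(gr)$transcript_id
  if (is.null(tid) || anyNA(tid)) stop("exon feature without transcript_id in ", path)
  ex <- granges(gr)
  mcols(ex)$transcript_id <- tid
  gid <- mcols(gr)$gene_id
  mcols(ex)$gene_id <- if (is.null(gid)) tid else gid
  bty <- mcols(gr)$transcript_biotype
  mcols(ex)$biotype <- if (is.null(bty)) "novel" else ifelse(is.na(bty), "novel", bty)
  transcript_set(ex)
}

#' Write a transcript set as GTF
#'
#' Emits one `exon` line per exon with `gene_id`, `transcript_id` and
#' `transcript_biotype` attributes, in transcript order. Deterministic, so
#' generator output round-trips byte-identically through
#' `write_gtf(read_gtf(path))`.
#'
#' @param tx transcript set.
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path, source = "lncmap") {
  ex <- unlist(tx, use.names = FALSE)
  per_tx <- lengths(tx)
  tid <- rep(mcols(tx)$transcript_id, per_tx)
  gid <- rep(mcols(tx)$gene_id, per_tx)
  bty <- rep(mcols(tx)$biotype, per_tx)
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; transcript_biotype \"%s\";",
    as.character(seqnames(ex)), source, start(ex), end(ex),
    as.character(strand(ex)), gid, tid, bty
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Each ungapped alignment block becomes one target/query interval pair.
#' Query blocks on the `-` strand are normalised to forward-strand
#' coordinates at parse time, so downstream code never sees reverse
#' coordinates. On-disk chain coordinates are 0-based half-open; the returned
#' target blocks are 1-based closed `GRanges`.
#'
#' @param path path to a chain file.
#' @param species_pair label for the target/query assembly pair.
#' @return a `chain_set`: list with `species_pair`, `blocks` (target `GRanges`
#'   with per-block query coordinates and `chain_id`), and `headers`
#'   (per-chain data.frame used to re-emit the file).
#' @export
read_chain <- function(path, species_pair = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^chain\\b", lines)
  if (length(hdr_idx) == 0L) stop("no chain headers in ", path)
  headers <- list(); blocks <- list()
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (ci in seq_along(hdr_idx)) {
    h <- strsplit(trimws(lines[hdr_idx[ci]]), "[ \t]+")[[1]]
    if (length(h) != 13L) stop("malformed chain header at line ", hdr_idx[ci])
    hd <- list(
      score = as.numeric(h[2]),
      t_name = h[3], t_size = as.integer(h[4]), t_strand = h[5],
      t_start = as.integer(h[6]), t_end = as.integer(h[7]),
      q_name = h[8], q_size = as.integer(h[9]), q_strand = h[10],
      q_start = as.integer(h[11]), q_end = as.integer(h[12]),
      chain_id = h[13]
    )
    if (hd$t_strand != "+") stop("chain target strand must be '+' (line ", hdr_idx[ci], ")")
    body <- lines[(hdr_idx[ci] + 1L):(bounds[ci + 1L] - 1L)]
    body <- body[!grepl("^chain\\b", body)]
    parts <- strsplit(trimws(body), "[ \t]+")
    sizes <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    dt <- vapply(parts, function(p) if (length(p) >= 2) as.integer(p[2]) else 0L, integer(1))
    dq <- vapply(parts, function(p) if (length(p) >= 3) as.integer(p[3]) else 0L, integer(1))
    if (sum(sizes) + sum(dt) != hd$t_end - hd$t_start ||
        sum(sizes) + sum(dq) != hd$q_end - hd$q_start) {
      stop("chain ", hd$chain_id, ": block sizes do not sum to the header span")
    }
    t0 <- hd$t_start + cumsum(c(0L, (sizes + dt)[-length(sizes)]))
    q0 <- hd$q_start + cumsum(c(0L, (sizes + dq)[-length(sizes)]))
    q_fwd_start <- if (hd$q_strand == "-") hd$q_size - (q0 + sizes) else q0
    gr <- GRanges(hd$t_name, IRanges(t0 + 1L, t0 + sizes), strand = "+")
    mcols(gr) <- DataFrame(
      q_name = hd$q_name, q_start = q_fwd_start, q_end = q_fwd_start + sizes,
      q_strand = hd$q_strand, chain_id = hd$chain_id, score = hd$score
    )
    blocks[[ci]] <- gr
    headers[[ci]] <- as.data.frame(hd, stringsAsFactors = FALSE)
  }
  structure(
    list(
      species_pair = species_pair,
      blocks = unlist(GRangesList(blocks)),
      headers = do.call(rbind, headers)
    ),
    class = "chain_set"
  )
}

#' @export
print.chain_set <- function(x, ...) {
  cat("chain_set:", x$species_pair, "-", nrow(x$headers), "chains,",
      length(x$blocks), "blocks\n")
  invisible(x)
}

#' Write a chain set back to UCSC chain format
#'
#' @param chains a `chain_set` from [read_chain()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(chains$headers))) {
    hd <- chains$headers[i, ]
    b <- chains$blocks[chains$blocks$chain_id == hd$chain_id]
    b <- b[order(start(b))]
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                       format(hd$score, scientific = FALSE), hd$t_name, hd$t_size,
                       hd$t_start, hd$t_end, hd$q_name, hd$q_size, hd$q_strand,
                       hd$q_start, hd$q_end, hd$chain_id), con)
    t0 <- start(b) - 1L
    sizes <- width(b)
    q0 <- if (hd$q_strand == "-") hd$q_size - b$q_end else b$q_start
    n <- length(b)
    if (n > 1L) {
      dt <- t0[-1L] - (t0[-n] + sizes[-n])
      dq <- q0[-1L] - (q0[-n] + sizes[-n])
      writeLines(sprintf("%d\t%d\t%d", sizes[-n], dt, dq), con)
    }
    writeLines(c(sprintf("%d", sizes[n]), ""), con)
  }
  invisible(path)
}

#' Read a count matrix with library sizes
#'
#' The counts TSV dialect: a first line `#library_sizes:<TAB>v1<TAB>v2...`,
#' then a header `transcript_id<TAB><sample labels>`, then one integer row
#' per transcript. Library sizes are mapped read pairs per sample; they are
#' carried explicitly because per-feature count files cannot recover them.
#'
#' @param path path to the TSV.
#' @return a `count_matrix`: list with integer matrix `counts`
#'   (transcripts x samples) and numeric `library_sizes` named by sample.
#' @export
read_counts <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!startsWith(lines[1], "#library_sizes:")) {
    stop("counts file must start with a '#library_sizes:' line: ", path)
  }
  lib <- as.numeric(strsplit(lines[1], "\t")[[1]][-1])
  hdr <- strsplit(lines[2], "\t")[[1]]
  samples <- hdr[-1]
  if (length(lib) != length(samples)) {
    stop("library_sizes line has ", length(lib), " values for ",
         length(samples), " samples")
  }
  if (any(lib <= 0)) stop("library sizes must be positive")
  df <- read.table(path, sep = "\t", skip = 2L, header = FALSE,
                   col.names = hdr, check.names = FALSE,
                   colClasses = c("character", rep("numeric", length(samples))))
  if (anyDuplicated(df[[1]])) {
    stop("duplicate transcript rows: ",
         paste(head(unique(df[[1]][duplicated(df[[1]])]), 5), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- samples
  if (any(m < 0)) stop("negative counts in ", path)
  count_matrix(m, setNames(lib, samples))
}

#' Construct a count matrix
#'
#' @param counts non-negative integer matrix, transcripts x samples.
#' @param library_sizes positive per-sample totals (mapped read pairs),
#'   named like `colnames(counts)`.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, library_sizes) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative counts")
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0)) {
    stop("library_sizes must be positive, one per sample")
  }
  names(library_sizes) <- colnames(counts)
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Write a count matrix in the counts-TSV dialect
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#library_sizes:", format(cm$library_sizes, scientific = FALSE, trim = TRUE)),
                   collapse = "\t"), con)
  writeLines(paste(c("transcript_id", colnames(cm$counts)), collapse = "\t"), con)
  body <- apply(cm$counts, 1L, function(r) paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(cm$counts), body, sep = "\t"), con)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Query coordinates are orientation-normalised so
#' `qstart <= qend`.
#'
#' @param path path to the 12-column TSV (no header).
#' @return data.frame of hits; zero rows allowed.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty_hits())
  df <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                   stringsAsFactors = FALSE)
  if (any(df$length < 1)) stop("alignment_length < 1 in ", path)
  flip <- df$qstart > df$qend
  tmp <- df$qstart[flip]; df$qstart[flip] <- df$qend[flip]; df$qend[flip] <- tmp
  df
}

#' Write a hit table in BLAST outfmt-6 order
#' @param hits data.frame as returned by [read_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' BED is 0-based half-open on disk; returned `GRanges` are 1-based closed.
#'
#' @param path path to a BED file.
#' @return `GRanges`; strand is `*` for BED3.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns: ", path)
  str <- if (ncol(df) >= 6L) df[[6]] else "*"
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]), strand = str)
  if (ncol(df) >= 4L) mcols(gr)$name <- df[[4]]
  gr
}

#' Write intervals as BED
#'
#' @param gr `GRanges` to write (1-based closed, converted to BED's 0-based
#'   half-open). Writes BED6 when strand or names are informative, else BED3.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  has6 <- any(as.character(strand(gr)) != "*") || !is.null(mcols(gr)$name)
  if (has6) {
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- rep(".", length(gr))
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", as.character(seqnames(gr)),
                     start(gr) - 1L, end(gr), nm,
                     sub("\\*", ".", as.character(strand(gr))))
  } else {
    lines <- sprintf("%s\t%d\t%d", as.character(seqnames(gr)),
                     start(gr) - 1L, end(gr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-GO-term map
#'
#' Two tab-separated columns, `gene_id` and `term_id`; duplicate memberships
#' are collapsed.
#'
#' @param path path to the TSV (no header).
#' @return data.frame with columns `gene_id`, `term_id`, one row per
#'   distinct membership.
#' @export
read_go <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("gene_id", "term_id"),
                   stringsAsFactors = FALSE)
  unique(df)
}

#' Write a gene-to-GO-term map
#' @param go data.frame with `gene_id`, `term_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_go <- function(go, path) {
  write.table(unique(go[, c("gene_id", "term_id")]), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
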