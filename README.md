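# lncmap

`lncmap` is an R package for building and characterising a long non-coding
RNA (lncRNA) catalogue from multi-tissue, multi-stage bulk RNA-seq — the
"BodyMap" style of analysis used to annotate lncRNAs in livestock and model
mammals. It covers the full path from an assembled transcriptome to
functional hypotheses:

1. **Discovery** — a six-step hierarchical filter over assembled
   transcripts: keep multi-exonic transcripts; drop same-strand overlaps
   with annotated exons (known lncRNAs are kept and flagged not-novel);
   drop transcripts shorter than 200 nt; drop transcripts any
   coding-potential caller flags as coding; drop homologs of canonical
   structural ncRNAs (transcripts matching only conserved lncRNA models
   survive). Survivors are classified positionally as *intergenic*
   (≥ 2 kb from any gene), *antisense* (opposite-strand exon overlap),
   *intronic*, or *cis-regulatory* (within 2 kb of a gene), with precedence
   antisense > intronic > cis-regulatory > intergenic.
2. **Expression** — RPKM (fragments per kb of exonic length per million
   mapped read pairs), expression breadth, GC content, SNP density, and
   correlation-based sample clustering.
3. **Tissue specificity** — the Jensen–Shannon score
   `1 − sqrt(JSD(p, e_t))` maximised over tissues `t`, where `p` is the
   normalised expression profile and `e_t` the single-tissue extreme
   pattern (log base 2, so the score lies in [0, 1] and equals 1 exactly
   for single-tissue expression); tissue association by the conjunctive
   rule Z ≥ 1.5 and RPKM ≥ 0.5, with skeletal-muscle stages merged.
4. **Conservation** — per-species covered fraction of exonic bases under
   UCSC chain alignments (each base counted once), classified at the 50%
   threshold into three-way / A-only / B-only / species-specific; plus
   transcript-level homology when the union of BLAST hits covers ≥ 20% of
   the query.
5. **Differential expression** — the replicate-free MA-plot
   random-sampling test between stage libraries:
   `z = (M − log2(n1/n2)) / sqrt(Var[M|A])` with
   `Var[M|A] = (1 − p)/ln(2)² · (1/n1 + 1/n2)/p`, `p = 2^A/sqrt(n1·n2)`,
   BH correction, and the conjunctive call |FC| ≥ 2 and q < 0.05; plus
   lncRNA–neighbour-gene expression correlation.
6. **Co-expression network** — unsigned weighted adjacency `|cor|^β`
   (soft threshold chosen by scale-free fit, default β = 6), topological
   overlap, average-linkage module detection with a static tree cut,
   module eigengenes (first principal component), eigengene–trait
   correlation against a binary muscle vector, kME hub calling, and
   guilt-by-association GO inference for lncRNAs via the hypergeometric
   over-representation test.

Every stage is exercised end-to-end on a **synthetic dataset with planted
ground truth**: `simulate_lnc_dataset()` emits a miniature annotated
genome (GTF), transcript FASTA, coding-potential and ncRNA-homology
tables, an 11-tissue count matrix, SNP BED, chain files and hit tables
with planted conservation classes, a 30-sample module-structured network
matrix, a GO map — and a `truth.json` recording every planted label.

## Worked example

```r
library(lncmap)
report <- run_full_pipeline(seed = 42)
print(report)
```

```
lncmap end-to-end synthetic run (seed 42)
  filter: precision 1.000, recall 1.000, categories 1.000
  specificity: planted-tissue recall 1.000; 85 specific (84 single-tissue)
  conservation: class accuracy 1.000, homology accuracy 1.000
  DE: recall 1.000, empirical FDR 0.070
  network: module ARI 1.000, top trait module M1 (r = 0.813)
  checks: 11/11 passing
```

The run generates the default synthetic dataset (200 protein-coding genes,
20 planted lncRNAs per positional category, 40 decoys, seed 42), reads
every file back through the format layer, and scores each stage against
the planted truth: the filter retains exactly the planted lncRNAs with
their planted categories and removes every decoy at its planted step; the
planted tissue of every tissue-specific transcript is recovered by the
Z/RPKM association rule; chain coverage reproduces the planted
conservation classes without error; stage-differential transcripts are
recalled at the rate the noise model allows; and the planted co-expression
modules are recovered exactly (adjusted Rand index 1.0) with the
trait-linked module ranking first against the muscle vector.

Individual operations work standalone:

```r
js_specificity(rbind(liver_only = c(rep(0, 10), 8), broad = rep(2, 11)))
#>            transcript_id  js_score best_tissue  tied
#> liver_only    liver_only 1.0000000    tissue11 FALSE
#> broad              broad 0.1200672     tissue1  TRUE

hypergeom_enrich(c(paste0("g", 1:4), "g6"), paste0("g", 1:20),
                 data.frame(gene_id = paste0("g", 1:5), term_id = "T1"))
#>   term_id k n K  N           p           q fold
#> 1      T1 4 5 5 20 0.004901961 0.004901961  3.2
```

A thin command-line wrapper over the same functions lives at
`inst/cli/lncmap.R` (subcommands `all`, `simulate`, `filter`, `expr`,
`specificity`, `conserve`, `de`, `network`, `enrich`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lncmap.R",package="lncmap"))')" \
    all --seed 42 --outdir out/
```

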