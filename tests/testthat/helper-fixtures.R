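# Tiny hand-built annotations used across tests; constructed in code so the
# expected geometry is explicit at the call site.

# one coding gene (2 exons) on +, one lncRNA (2 exons) on -, one mono-exonic
# coding gene with CDS, all on chr1
toy_annotation <- function() {
  transcripts <- data.frame(
    transcript_id = c("tx_cod", "tx_lnc", "tx_mono"),
    gene_id = c("g_cod", "g_lnc", "g_mono"),
    biotype = c("coding", "lncRNA", "coding"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
  exons <- rbind(
    data.frame(chrom = "chr1", start = c(1000, 2000), end = c(1400, 2600),
               name = "g_cod", strand = "+", transcript_id = "tx_cod",
               gene_id = "g_cod"),
    data.frame(chrom = "chr1", start = c(5000, 6000), end = c(5300, 6500),
               name = "g_lnc", strand = "-", transcript_id = "tx_lnc",
               gene_id = "g_lnc"),
    data.frame(chrom = "chr1", start = 9000, end = 9900, name = "g_mono",
               strand = "+", transcript_id = "tx_mono", gene_id = "g_mono")
  )
  cds <- rbind(
    data.frame(chrom = "chr1", start = c(1100, 2000), end = c(1400, 2400),
               name = "g_cod", strand = "+", transcript_id = "tx_cod",
               gene_id = "g_cod"),
    data.frame(chrom = "chr1", start = 9100, end = 9700, name = "g_mono",
               strand = "+", transcript_id = "tx_mono", gene_id = "g_mono")
  )
  annotation_set(transcripts, exons, cds)
}

# minimal count experiment: 2 pre + 2 post samples over the given matrix
toy_count_matrix <- function(counts) {
  n <- ncol(counts)
  stopifnot(n %% 2 == 0)
  meta <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    phase = rep(c("pre", "post"), each = n / 2),
    capture = "toy",
    replicate = paste0("r", rep(seq_len(n / 2), 2)),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, meta)
}
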