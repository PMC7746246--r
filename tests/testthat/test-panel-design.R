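test_that("GWAS SNP filtering is strict and deduplicates associations", {
  snps <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs1"),
    chrom = "chr1", pos = c(100, 200, 300, 100),
    pvalue = c(1e-9, 5e-8, 1e-7, 1e-9),
    phenotype = c("pd", "pd", "pd", "pd")
  )
  out <- filter_gwas_snps(snps, 5e-8)
  expect_equal(out$snp_id, "rs1")      # 5e-8 itself excluded (strict <)
  # same SNP, different phenotype survives deduplication
  snps$phenotype[4] <- "scz"
  expect_equal(nrow(filter_gwas_snps(snps, 5e-8)), 2)
  expect_equal(nrow(filter_gwas_snps(snps[0, ], 5e-8)), 0)
  expect_error(filter_gwas_snps(data.frame(snp_id = "rs1"), 5e-8), "pvalue")
})

test_that("SNP-to-block assignment honours tier preference", {
  snps <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(500, 5500, 9999999), pvalue = 1e-10)
  tiers <- list(gintervals("chr1", 0, 1000),
                gintervals("chr1", c(0, 5000), c(1000, 6000)))
  res <- assign_snps_to_blocks(snps, tiers, chroms = "chr1")
  a <- res$assignments
  expect_equal(a$tier[a$snp_id == "a"], 1)   # tier 1 wins, tier 2 unconsulted
  expect_equal(a$tier[a$snp_id == "b"], 2)
  expect_true("c" %in% res$unassigned)
  # SNP overlapping two blocks of one set is assigned to both
  multi <- list(gintervals("chr1", c(400, 450), c(600, 700)))
  res2 <- assign_snps_to_blocks(snps[1, ], multi)
  expect_equal(nrow(res2$assignments), 2)
  # SNP off the declared universe warns and is unassigned
  expect_warning(res3 <- assign_snps_to_blocks(
    data.frame(snp_id = "z", chrom = "chrZ", pos = 5, pvalue = 1e-10),
    tiers, chroms = "chr1"))
  expect_equal(res3$unassigned, "z")
})

test_that("coding-free block filter drops any coding overlap, even 1 nt", {
  ann <- toy_annotation()   # coding gene spans 1000-2600
  blocks <- gintervals("chr1", c(0, 2599, 4000), c(900, 3000, 4500))
  out <- coding_free_blocks(blocks, ann)
  expect_equal(out$start, c(0, 4000))  # 1-nt overlap at 2599 removed
  # block overlapping only the lncRNA (5000-6500) is retained
  lnc_block <- gintervals("chr1", 5100, 5200)
  expect_equal(nrow(coding_free_blocks(lnc_block, ann)), 1)
})

test_that("lncRNA proximity uses a gene-level trigger", {
  ann <- toy_annotation()   # lncRNA exons (5000,5300) and (6000,6500)
  # block 9 kb from the nearest exon: both exons of the gene returned
  blocks <- gintervals("chr1", 15500, 16000)
  out <- proximal_lncrna_exons(blocks, ann, window = 50000)
  expect_equal(nrow(out), 2)
  expect_setequal(out$start, c(5000, 6000))
  # 60 kb away with a 50 kb window: excluded
  expect_equal(nrow(proximal_lncrna_exons(gintervals("chr1", 66500, 67000),
                                          ann, window = 50000)), 0)
  # annotation without lncRNAs
  ann2 <- ann
  ann2$transcripts$biotype <- "coding"
  expect_equal(nrow(proximal_lncrna_exons(blocks, ann2)), 0)
})

test_that("coding trim respects the gap >= margin convention", {
  ann <- toy_annotation()   # coding extent 1000-2600
  # target ending at gap exactly 50 from the coding extent is untouched
  tgt <- gintervals("chr1", 900, 950)
  expect_equal(trim_near_coding(tgt, ann, margin = 50)$end, 950)
  # gap 49 is trimmed
  tgt2 <- gintervals("chr1", 900, 951)
  expect_equal(trim_near_coding(tgt2, ann, margin = 50)$end, 950)
  # no coding genes: identity
  ann2 <- ann
  ann2$transcripts$biotype <- "lncRNA"
  expect_equal(trim_near_coding(tgt, ann2, 50)[, c("start", "end")],
               tgt[, c("start", "end")])
})

test_that("repeat filter selects classes and validates them", {
  reps <- gintervals("chr1", c(1000, 3000), c(1100, 3100),
                     name = c("rRNA", "LINE"))
  tgt <- gintervals("chr1", 0, 5000)
  out <- rna_repeat_filter(tgt, reps, margin = 50, classes = "rRNA")
  # only the rRNA repeat (plus 50 nt) removed; LINE untouched
  expect_equal(out$start, c(0, 1150))
  expect_equal(out$end, c(950, 5000))
  expect_error(rna_repeat_filter(tgt, reps, 50, classes = "7SL"),
               "unknown repeat class")
  # margin 0, no overlap: identity
  far <- gintervals("chr1", 10000, 10100)
  expect_equal(rna_repeat_filter(far, reps, 0)[, c("start", "end")],
               far[, c("start", "end")])
})

test_that("probing classification applies >= and > thresholds as stated", {
  sh <- data.frame(gene_id = c("a", "b", "c", "d"),
                   neuronal = c(0.006, 0.001, 0.004, 0.005),
                   encode1 = c(0.01, 0.051, 0.05, 0.0))
  out <- classify_tf_probing(sh)
  expect_equal(out$class, c("partial", "partial", "full", "partial"))
  expect_error(classify_tf_probing(transform(sh, neuronal = c(2, 0, 0, 0))),
               "\\[0, 1\\]")
})

test_that("partial probing follows transcript orientation", {
  # + strand multi-exonic: penultimate exon 80 nt -> whole exon;
  # final exon 500 nt -> first 150 nt
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", biotype = "coding",
                   chrom = "c1", strand = "+")
  ex <- data.frame(chrom = "c1", start = c(100, 1000, 2000),
                   end = c(400, 1080, 2500), name = "g1", strand = "+",
                   transcript_id = "t1", gene_id = "g1")
  ann <- annotation_set(tx, ex)
  out <- partial_probe_targets(ann, "t1")
  expect_equal(out$start, c(1000, 2000))
  expect_equal(out$end, c(1080, 2150))

  # - strand: same exon layout; penultimate exon is now (1000,1080) read
  # from the right, final exon is (100,400): "first 150" at its high end
  tx$strand <- "-"; ex$strand <- "-"
  ann <- annotation_set(tx, ex)
  out <- partial_probe_targets(ann, "t1")
  expect_equal(out$start, c(250, 1000))
  expect_equal(out$end, c(400, 1080))

  # - strand final exon example: last exon in transcript order has the
  # lowest coordinates; "first 150 nt" maps to its highest coordinates
  ex2 <- data.frame(chrom = "c1", start = c(2000, 5000),
                    end = c(2500, 5200), name = "g1", strand = "-",
                    transcript_id = "t1", gene_id = "g1")
  ann2 <- annotation_set(tx, ex2)
  out2 <- partial_probe_targets(ann2, "t1")
  final <- out2[out2$start < 3000, ]
  expect_equal(final$start, 2350)
  expect_equal(final$end, 2500)

  # mono-exonic: last 200 nt of CDS; error when CDS absent
  tx3 <- data.frame(transcript_id = "t3", gene_id = "g3",
                    biotype = "coding", chrom = "c1", strand = "+")
  ex3 <- data.frame(chrom = "c1", start = 100, end = 2000, name = "g3",
                    strand = "+", transcript_id = "t3", gene_id = "g3")
  cds3 <- data.frame(chrom = "c1", start = 200, end = 1100, name = "g3",
                     strand = "+", transcript_id = "t3", gene_id = "g3")
  ann3 <- annotation_set(tx3, ex3, cds3)
  out3 <- partial_probe_targets(ann3, "t3")
  expect_equal(out3$start, 900)
  expect_equal(out3$end, 1100)
  ann4 <- annotation_set(tx3, ex3)
  expect_error(partial_probe_targets(ann4, "t3"), "t3")
})

test_that("intronic controls centre in the longest surviving piece", {
  # single gene, one clean 1000 nt intron, nothing else nearby
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", biotype = "coding",
                   chrom = "c1", strand = "+")
  ex <- data.frame(chrom = "c1", start = c(10000, 12000),
                   end = c(11000, 13000), name = "g1", strand = "+",
                   transcript_id = "t1", gene_id = "g1")
  ann <- annotation_set(tx, ex)
  out <- design_intronic_controls("g1", ann, gintervals(), gintervals(),
                                  ann_margin = 0)
  # intron (11000,12000): middle 200 nt at offset floor((1000-200)/2) = 400
  expect_equal(out$start, 11400)
  expect_equal(out$end, 11600)
  expect_equal(out$name, "g1")

  # all pieces <= min_piece: gene omitted (strict "over")
  out2 <- design_intronic_controls("g1", ann, gintervals(), gintervals(),
                                   ann_margin = 400)
  expect_equal(nrow(out2), 0)  # piece is exactly 200 after 400-nt trims

  # two surviving pieces: the longest is chosen
  ex3 <- data.frame(chrom = "c1", start = c(1000, 2000, 3000),
                    end = c(1500, 2300, 3450), name = "g1", strand = "+",
                    transcript_id = "t1", gene_id = "g1")
  ann3 <- annotation_set(tx, ex3)
  out3 <- design_intronic_controls("g1", ann3, gintervals(), gintervals(),
                                   ann_margin = 0, min_piece = 200,
                                   control_len = 200)
  # introns 500 and 700 nt; the 700 nt piece (2300,3000) wins
  expect_equal(out3$start, 2300 + 250)
  expect_error(design_intronic_controls("g1", ann3, gintervals(),
                                        gintervals(), control_len = 500),
               "control_len")
})

test_that("intronic controls clear exons, repeats and ESTs by their margins", {
  set.seed(21)
  gen <- generate_annotation(n_genes = 25, chrom_len = 4e5, seed = 21)
  ann <- gen$annotation
  genes <- unique(ann$transcripts$gene_id)
  ctrl <- design_intronic_controls(genes, ann, ann$tracks$repeats,
                                   ann$tracks$ests)
  if (nrow(ctrl)) {
    L <- 4e5
    exon_mask <- dilate_mask(mask_from_intervals(ann$exons, L), 500)
    rep_mask <- dilate_mask(mask_from_intervals(ann$tracks$repeats, L), 100)
    est_mask <- dilate_mask(mask_from_intervals(ann$tracks$ests, L), 50)
    ctrl_mask <- mask_from_intervals(ctrl, L)
    expect_false(any(ctrl_mask & exon_mask))
    expect_false(any(ctrl_mask & rep_mask))
    expect_false(any(ctrl_mask & est_mask))
    expect_true(all(interval_length(ctrl) == 200))
  } else {
    skip("no intronic control survived on this toy genome")
  }
})

test_that("spike-in regions are dropped, padded and boundary-shifted", {
  sl <- c(s1 = 1000)
  # symmetric pad of an even deficit
  out <- prepare_spikein_targets(gintervals("s1", 100, 140), sl)
  expect_equal(c(out$start, out$end), c(95, 145))
  # under 30 nt dropped
  expect_equal(nrow(prepare_spikein_targets(gintervals("s1", 100, 129), sl)),
               0)
  # boundary-shifted pad reaches exactly 50
  out2 <- prepare_spikein_targets(gintervals("s1", 0, 35), sl)
  expect_equal(c(out2$start, out2$end), c(0, 50))
  # interior odd deficit pads to 51 with equal flanks
  out3 <- prepare_spikein_targets(gintervals("s1", 100, 135), sl)
  expect_equal(interval_length(out3), 51)
  expect_equal(out3$start, 92)
  # >= 50 nt unchanged
  out4 <- prepare_spikein_targets(gintervals("s1", 10, 70), sl)
  expect_equal(c(out4$start, out4$end), c(10, 70))
  expect_error(prepare_spikein_targets(gintervals("s1", 900, 1100), sl),
               "bounds")
})

test_that("panel assembly accounts bases correctly and ignores group order", {
  g1 <- gintervals("c1", 0, 1000)
  g2 <- gintervals("c1", 5000, 7000)
  p <- assemble_panel("toy", list(a = g1, b = g2))
  expect_equal(p$total_bases, 3000)
  # overlapping groups: union accounting via per-base oracle
  g3 <- gintervals("c1", c(500, 800), c(900, 1500))
  p2 <- assemble_panel("toy", list(a = g1, b = g3))
  L <- 2000
  expect_equal(p2$total_bases,
               sum(mask_from_intervals(rbind(g1, g3), L)))
  # order invariance
  p3 <- assemble_panel("toy", list(b = g3, a = g1))
  expect_equal(p3$total_bases, p2$total_bases)
  expect_equal(p3$targets, p2$targets)
  expect_error(assemble_panel("toy", list(a = gintervals())), "empty")
})

test_that("assembled panels attribute genes by overlap", {
  ann <- toy_annotation()
  p <- assemble_panel("toy", list(x = gintervals("chr1", 1200, 1300),
                                  y = gintervals("chr1", 5100, 5200)), ann)
  expect_setequal(panel_genes(p), c("g_cod", "g_lnc"))
})
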