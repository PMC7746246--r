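test_that("generated annotations are deterministic and well-formed", {
  g1 <- generate_annotation(n_genes = 30, chrom_len = 4e5, seed = 7)
  g2 <- generate_annotation(n_genes = 30, chrom_len = 4e5, seed = 7)
  expect_identical(g1$annotation$exons, g2$annotation$exons)
  expect_identical(g1$snps, g2$snps)
  expect_equal(nrow(g1$annotation$transcripts), 30)
  # written files are byte-identical under the same seed
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(g1$annotation, f1)
  write_gtf(g2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_annotation(n_genes = 500, chrom_len = 1e5),
               "infeasible")
})

test_that("generated intron gaps equal the exon-complement oracle", {
  gen <- generate_annotation(n_genes = 15, chrom_len = 2e5, seed = 3)
  ann <- gen$annotation
  for (tid in ann$transcripts$transcript_id[1:5]) {
    ex <- ann$exons[ann$exons$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) next
    span_mask <- logical(2e5)
    span_mask[(min(ex$start) + 1):max(ex$end)] <- TRUE
    intron_mask <- span_mask & !mask_from_intervals(ex, 2e5)
    introns <- intervals_from_mask(intron_mask)
    expect_equal(introns$start, ex$end[-nrow(ex)])
    expect_equal(introns$end, ex$start[-1])
  }
})

test_that("pre-capture sampling is exact-depth multinomial with dropout", {
  p <- capture_sim_params(n_genes = 300, depth_pre = 2e5, n_replicates = 3,
                          dropout_kappa = 100, seed = 17)
  tr <- simulate_capture_truth(p)
  pre <- simulate_pre_capture(tr)
  expect_equal(unname(colSums(pre$counts)), rep(2e5, 3))
  # genes dropped from a replicate have zero counts in that replicate
  for (r in 1:3) {
    dropped_r <- tr$gene_ids[tr$dropout[, r]]
    if (length(dropped_r)) {
      expect_true(all(pre$counts[dropped_r, r] == 0))
    }
  }
  # fully dropped genes are zero in every pre replicate
  dropped <- tr$gene_ids[tr$dropout_all]
  if (length(dropped)) {
    expect_true(all(pre$counts[dropped, ] == 0))
  }
  # kappa 0: no dropout at all
  tr0 <- simulate_capture_truth(capture_sim_params(n_genes = 300,
                                                   dropout_kappa = 0,
                                                   seed = 17))
  expect_false(any(tr0$dropout))
})

test_that("sampled gene means track the expression truth (LLN)", {
  p <- capture_sim_params(n_genes = 100, depth_pre = 1e6, n_replicates = 8,
                          spike_frac = 0, seed = 23)
  tr <- simulate_capture_truth(p)
  pre <- simulate_pre_capture(tr)
  lam <- tr$lambda_cpm
  est <- rowMeans(pre$counts[tr$gene_ids, ])
  # expected count per replicate = lambda_cpm * depth / 1e6 = lambda_cpm
  keep <- lam > 50
  se <- sqrt(lam[keep] / 8)
  z <- (est[keep] - lam[keep]) / se
  expect_true(mean(abs(z) < 3) > 0.99)
})

test_that("neutral capture leaves the sampling distribution unchanged", {
  p <- capture_sim_params(n_genes = 200, capture_efficiency = 1,
                          capture_spread = 0, spike_frac = 0,
                          depth_post = 1e6, seed = 31)
  tr <- simulate_capture_truth(p)
  expect_equal(tr$expected_ef, 1, tolerance = 1e-12)
  post <- simulate_post_capture(tr)
  est <- rowMeans(post$counts[tr$gene_ids, ])
  keep <- tr$lambda_cpm > 50
  z <- (est[keep] - tr$lambda_cpm[keep]) / sqrt(tr$lambda_cpm[keep] / 4)
  expect_true(mean(abs(z) < 3) > 0.99)
})

test_that("post on-target share matches the closed form", {
  # p = 0.01, C = 100 -> expected post share 0.5025
  p <- capture_sim_params(n_genes = 1000, targeted_fraction = 0.01,
                          capture_efficiency = 100, spike_frac = 0,
                          exclude_top_expressed = 0, seed = 41)
  tr <- simulate_capture_truth(p)
  pp <- tr$p_pre
  expect_equal(tr$p_post, 100 * pp / (100 * pp + 1 - pp), tolerance = 1e-12)
})

test_that("rescued genes reappear post-capture at sufficient depth", {
  p <- capture_sim_params(n_genes = 500, targeted_fraction = 0.1,
                          capture_efficiency = 100, dropout_kappa = 800,
                          depth_pre = 1e6, depth_post = 1e6, seed = 19)
  sim <- simulate_capture_experiment(p)
  tr <- sim$truth
  rescued_truth <- tr$gene_ids[tr$dropout_all & tr$targeted]
  expect_gt(length(rescued_truth), 0)
  expect_true(all(rowSums(sim$pre$counts[rescued_truth, , drop = FALSE])
                  == 0))
  expect_true(all(rowSums(sim$post$counts[rescued_truth, , drop = FALSE])
                  > 0))
})

test_that("spike-in ladders follow the dilution geometry", {
  lad <- generate_spikein_ladder(n_spikes = 8, top_conc = 1024,
                                 dilution = 2, seed = 5)
  expect_equal(max(lad$concentration) / min(lad$concentration), 128)
  expect_equal(lad$concentration, 1024 / 2^(0:7))
  lad2 <- generate_spikein_ladder(n_spikes = 8, top_conc = 1024,
                                  dilution = 2, seed = 5)
  expect_identical(lad, lad2)
  expect_true(any(lad$targeted) && any(!lad$targeted))
  expect_error(generate_spikein_ladder(n_spikes = 3), "at least 4")
})

test_that("scenario bundles expose their stated study conditions", {
  ng <- make_scenario("ng-like", seed = 2)
  # panel mass: targeted genes hold under 1% of transcriptome mass
  mass <- sum(ng$truth$lambda_cpm[ng$truth$targeted]) /
    sum(ng$truth$lambda_cpm)
  expect_lt(mass, 0.01)
  lc <- make_scenario("low-complexity-minibulk", seed = 2)
  expect_gte(mean(lc$truth$dropout_all[lc$truth$targeted]), 0.05)
  expect_error(make_scenario("nope"), "arg")
})

test_that("scenario files are reproduced byte-identically under one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_scenario("tf-like", seed = 4, outdir = d1)
  make_scenario("tf-like", seed = 4, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
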