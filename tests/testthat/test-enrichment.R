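test_that("CPM normalization conserves column totals", {
  m <- matrix(c(10, 90, 0, 50, 150, 0), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  cpm <- cpm_normalize(m)
  expect_equal(cpm[, "a"], c(g1 = 1e5, g2 = 9e5, g3 = 0))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  set.seed(3)
  r <- matrix(rpois(600, 20), nrow = 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:10)))
  expect_equal(unname(colSums(cpm_normalize(r))), rep(1e6, 10),
               tolerance = 1e-9)
  bad <- cbind(m, z = c(0, 0, 0))
  expect_error(cpm_normalize(bad), "z")
  # cross-check against the field-standard implementation
  if (requireNamespace("edgeR", quietly = TRUE)) {
    expect_equal(cpm_normalize(r), edgeR::cpm(r), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("on-target fraction matches counts and brute-force overlap", {
  gc <- c(g1 = 68, g2 = 32)
  expect_equal(on_target_fraction(panel = "g1", gene_counts = gc), 0.68)
  # whole-genome panel: 1.0
  panel <- gintervals("c1", 0, 1e5)
  set.seed(14)
  reads <- random_intervals(500, 1e5, max_len = 100)
  expect_equal(on_target_fraction(reads = reads, panel = panel), 1.0)
  # BED mode equals a per-read brute-force overlap check
  tgt <- random_intervals(20, 1e5, max_len = 2000)
  frac <- on_target_fraction(reads = reads, panel = tgt)
  brute <- mean(vapply(seq_len(nrow(reads)), function(i) {
    any(reads$start[i] < tgt$end & tgt$start < reads$end[i])
  }, logical(1)))
  expect_equal(frac, brute)
  expect_error(on_target_fraction(panel = "g1", gene_counts = gc,
                                  total_reads = 0), "positive")
})

test_that("sample enrichment factor is post over pre", {
  expect_equal(sample_enrichment_factor(0.0025, 0.6875), 275)
  expect_equal(sample_enrichment_factor(0.4, 0.4), 1)
  expect_true(is.na(sample_enrichment_factor(0, 0.5)))
  expect_error(sample_enrichment_factor(-0.1, 0.5), "\\[0, 1\\]")
  expect_equal(median_sample_ef(c(10, 20, NA, 30)), 20)
})

test_that("sample EF matches the closed form of the generative model", {
  p <- capture_sim_params(n_genes = 800, targeted_fraction = 0.05,
                          capture_efficiency = 50, spike_frac = 0,
                          n_replicates = 4, seed = 8)
  sim <- simulate_capture_experiment(p)
  tr <- sim$truth
  # constant C, no dropout: expected EF follows C / (C p + 1 - p)
  pC <- tr$p_pre
  expect_equal(tr$expected_ef, 50 / (50 * pC + 1 - pC), tolerance = 1e-12)
  ot <- function(m) sum(m[tr$target_ids, ]) / sum(m)
  ef_hat <- ot(sim$post$counts) / ot(sim$pre$counts)
  q <- tr$p_post
  n_pre <- sum(sim$pre$counts); n_post <- sum(sim$post$counts)
  se <- tr$expected_ef *
    sqrt((1 - q) / (q * n_post) + (1 - pC) / (pC * n_pre))
  expect_lt(abs(ef_hat - tr$expected_ef), 3 * se)
})

test_that("gene enrichment categories partition targeted genes", {
  pre <- matrix(c(2, 0, 0, 3, 2, 0, 0, 3), ncol = 2,
                dimnames = list(c("a", "b", "c", "d"), c("p1", "p2")))
  post <- matrix(c(200, 5, 0, 1, 200, 5, 0, 1), ncol = 2,
                 dimnames = list(c("a", "b", "c", "d"), c("q1", "q2")))
  enr <- gene_enrichment(pre, post, targeted_genes = c("a", "b", "c", "d"))
  expect_equal(enr$category, c("enriched", "rescued", "undetected",
                               "not_enriched"))
  expect_equal(enr$ef_raw[1], 100)
  expect_equal(enr$ef_log[4], log2(1 / 3 + 1))
  # ef_raw 0 -> ef_log 0 with pseudocount 1
  post0 <- post; post0["d", ] <- 0
  enr0 <- gene_enrichment(pre, post0, targeted_genes = "d")
  expect_equal(enr0$ef_log, 0)
  # partition: every gene exactly one category
  expect_equal(sort(table(enr$category)), sort(table(enr$category)))
  expect_equal(sum(table(enr$category)), 4)
  # success rate: of 2 genes detected pre, 1 enriched
  expect_equal(attr(enr, "success_rate"), 50)
  expect_error(gene_enrichment(pre, post, targeted_genes = "zz"), "zz")
})

test_that("success rate is 100 when capture scales all genes up", {
  set.seed(4)
  pre <- matrix(rpois(80, 50) + 1, ncol = 4,
                dimnames = list(paste0("g", 1:20), paste0("p", 1:4)))
  post <- pre * 7
  enr <- gene_enrichment(pre, post, targeted_genes = paste0("g", 1:20))
  expect_equal(attr(enr, "success_rate"), 100)
  expect_true(all(enr$category == "enriched"))
})

test_that("not-enriched genes land in (0,1) on the pseudocount log scale", {
  pre <- matrix(c(10, 8), ncol = 2, dimnames = list("g", c("p1", "p2")))
  post <- matrix(c(4, 2), ncol = 2, dimnames = list("g", c("q1", "q2")))
  enr <- gene_enrichment(pre, post, "g")
  expect_true(enr$ef_raw < 1 && enr$ef_raw > 0)
  expect_true(enr$ef_log > 0 && enr$ef_log < 1)
})

test_that("replicate CV matches sd/mean and needs two replicates", {
  m <- matrix(c(8, 12), nrow = 1, dimnames = list("g", c("r1", "r2")))
  expect_equal(unname(replicate_cv(m)), sd(c(8, 12)) / 10)
  expect_equal(unname(replicate_cv(m)), 0.2828427, tolerance = 1e-6)
  ident <- matrix(5, nrow = 3, ncol = 4,
                  dimnames = list(letters[1:3], paste0("r", 1:4)))
  expect_equal(unname(replicate_cv(ident)), c(0, 0, 0))
  expect_error(replicate_cv(m[, 1, drop = FALSE]), "2 replicates")
})

test_that("paired CV comparison detects halved post-capture variability", {
  set.seed(9)
  pre_cv <- setNames(runif(40, 0.2, 1), paste0("g", 1:40))
  post_cv <- pre_cv / 2
  res <- compare_cv(pre_cv, post_cv)
  expect_equal(res$direction, "post_lower")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n_pairs, 40)
  # small n uses the exact distribution
  res2 <- compare_cv(pre_cv[1:12], post_cv[1:12])
  expect_lt(res2$p_value, 0.05)
})

test_that("group CV stratifies strictly above vs at-or-below threshold", {
  ef <- c(2, 2, 2, 8, 1, 9)
  pre <- c(10, 20, 30, 0.5, 0.9, 1.0)
  res <- group_cv(ef, pre, threshold = 1)
  expect_equal(res$n_above, 3)   # pre == 1 goes below
  expect_equal(res$n_below, 3)
  expect_equal(res$cv_above, 0)
  expect_gt(res$cv_below, res$cv_above)
  expect_true(is.na(group_cv(ef[1], pre[1], 1)$cv_below))
  expect_error(group_cv(ef, pre, 0), "positive")
})

test_that("read-balance validation passes on equality", {
  res <- validate_read_balance(
    c(a = 1e6, b = 5e5, c = 8e5),
    c(a = 8e5, b = 8e5, c = 8e5))
  expect_equal(res$pass, c(TRUE, FALSE, TRUE))
  expect_error(validate_read_balance(c(a = 1), c(b = 1)), "unpaired")
})

test_that("stage correlation assigns samples to their source profile", {
  set.seed(12)
  ref <- matrix(rlnorm(500 * 5, 3, 1), ncol = 5,
                dimnames = list(paste0("g", 1:500), paste0("st", 1:5)))
  # sample identical to stage 3: correlation exactly 1
  samp <- ref[, 3, drop = FALSE]
  colnames(samp) <- "s1"
  res <- stage_correlation(samp, ref)
  expect_equal(res$assignment$stage, "st3")
  expect_equal(res$assignment$correlation, 1)
  # noisy replicate columns averaged per stage first
  ref2 <- cbind(ref, ref + matrix(rlnorm(2500, 0, 0.1), ncol = 5))
  colnames(ref2) <- paste0("c", 1:10)
  stages <- rep(paste0("st", 1:5), 2)
  res2 <- stage_correlation(samp, ref2, stages = stages)
  expect_equal(ncol(res2$correlations), 5)
  expect_equal(res2$assignment$stage, "st3")
  # constant profile errors
  flat <- matrix(1, nrow = 500, ncol = 1,
                 dimnames = list(rownames(ref), "flat"))
  expect_error(stage_correlation(flat, ref), "constant")
  expect_error(stage_correlation(samp[1:2, , drop = FALSE], ref), "shared")
})
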