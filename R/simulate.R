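#' Parameters of the capture generative model
#'
#' The simulator draws per-gene expression levels from a log-normal
#' distribution (normalized to CPM over genes), selects a targeted gene set
#' among genes outside the top expression stratum (capture designs avoid the
#' most abundant transcripts), assigns each targeted gene a capture
#' efficiency C (log-normal around `capture_efficiency`), and samples reads
#' multinomially at fixed depth so library sizes are exact. Low-input
#' (mini-bulk) dropout removes gene g from each pre-capture replicate
#' library independently with probability exp(-lambda_g / dropout_kappa),
#' so lowly expressed genes are missing from some or all replicates;
#' capture can rescue them because the post-capture library is sampled
#' from the undropped transcript pool. Setting `dropout_post = TRUE` applies the same mask post
#' capture instead, modelling loss at library construction, which capture
#' cannot rescue.
#'
#' @param n_genes number of genes.
#' @param targeted_fraction fraction of genes on the capture panel.
#' @param expr_sdlog log-normal sd of expression (log scale).
#' @param depth_pre,depth_post reads per library.
#' @param capture_efficiency mean capture efficiency C of targeted species.
#' @param capture_spread log-scale sd of per-gene capture efficiency.
#' @param carryover sampling weight multiplier of non-targeted species
#'   post-capture (1 = neutral carry-over).
#' @param dropout_kappa dropout scale (CPM); 0 disables dropout.
#' @param dropout_post apply dropout to both phases instead of pre only.
#' @param exclude_top_expressed fraction of top-expressed genes ineligible
#'   for targeting.
#' @param n_replicates replicates per phase.
#' @param spike_frac fraction of library mass from spike-ins.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `capture_sim_params`.
#' @export
capture_sim_params <- function(n_genes = 2000, targeted_fraction = 0.05,
                               expr_sdlog = 1.2, depth_pre = 1e6,
                               depth_post = 1e6, capture_efficiency = 100,
                               capture_spread = 0, carryover = 1,
                               dropout_kappa = 0, dropout_post = FALSE,
                               exclude_top_expressed = 0.1,
                               n_replicates = 4, spike_frac = 0.03,
                               seed = 1) {
  stopifnot(targeted_fraction > 0, targeted_fraction < 1,
            depth_pre > 0, depth_post > 0, capture_efficiency > 0,
            spike_frac >= 0, spike_frac < 1, n_replicates >= 1)
  structure(
    list(n_genes = n_genes, targeted_fraction = targeted_fraction,
         expr_sdlog = expr_sdlog, depth_pre = depth_pre,
         depth_post = depth_post, capture_efficiency = capture_efficiency,
         capture_spread = capture_spread, carryover = carryover,
         dropout_kappa = dropout_kappa, dropout_post = dropout_post,
         exclude_top_expressed = exclude_top_expressed,
         n_replicates = n_replicates, spike_frac = spike_frac,
         seed = as.integer(seed)),
    class = "capture_sim_params"
  )
}

#' Draw the ground truth of a capture simulation
#'
#' Draws expression levels, the targeted gene set, per-gene capture
#' efficiencies, dropout flags and the spike-in ladder, and records the
#' expected on-target shares and the closed-form expected sample enrichment
#' factor EF = q/p, where p and q are the expected on-target mass shares of
#' the pre- and post-capture sampling weights (for constant efficiency C
#' and no dropout this reduces to C / (C p + 1 - p)).
#'
#' @param params `capture_sim_params`.
#' @param ladder optional `spikein_ladder`; generated from the seed when
#'   `NULL`.
#' @return list of class `capture_sim_truth`.
#' @export
simulate_capture_truth <- function(params, ladder = NULL) {
  set.seed(params$seed)
  n <- params$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  lambda <- stats::rlnorm(n, meanlog = 0, sdlog = params$expr_sdlog)
  lambda_cpm <- lambda / sum(lambda) * 1e6
  names(lambda_cpm) <- gene_ids
  eligible <- if (params$exclude_top_expressed > 0) {
    cut <- stats::quantile(lambda_cpm, 1 - params$exclude_top_expressed,
                           names = FALSE)
    gene_ids[lambda_cpm <= cut]
  } else {
    gene_ids
  }
  n_target <- max(1, round(n * params$targeted_fraction))
  targeted_genes <- sort(sample(eligible, min(n_target, length(eligible))))
  targeted <- gene_ids %in% targeted_genes
  C <- rep(1, n)
  if (params$capture_spread > 0) {
    C[targeted] <- stats::rlnorm(
      sum(targeted),
      meanlog = log(params$capture_efficiency) -
        params$capture_spread^2 / 2,
      sdlog = params$capture_spread)
  } else {
    C[targeted] <- params$capture_efficiency
  }
  names(C) <- gene_ids
  # dropout is a per-gene, per-replicate event: each low-input library
  # loses gene g independently with probability exp(-lambda_g / kappa)
  dropout <- matrix(FALSE, n, params$n_replicates,
                    dimnames = list(gene_ids, NULL))
  if (params$dropout_kappa > 0) {
    p_drop <- exp(-lambda_cpm / params$dropout_kappa)
    dropout[] <- stats::runif(n * params$n_replicates) <
      rep(p_drop, params$n_replicates)
  }
  dropout_all <- rowSums(!dropout) == 0
  if (is.null(ladder)) {
    ladder <- generate_spikein_ladder(seed = NULL)  # uses current stream
  }
  # spike sampling weights: reads scale with molar concentration x length
  spike_w <- ladder$concentration * ladder$length_nt / 1000
  if (params$spike_frac > 0) {
    spike_w <- spike_w / sum(spike_w) *
      params$spike_frac / (1 - params$spike_frac) * 1e6
  } else {
    spike_w <- rep(0, nrow(ladder))
  }
  names(spike_w) <- ladder$spike_id
  spike_C <- ifelse(ladder$targeted,
                    params$capture_efficiency, params$carryover)
  # expected on-target shares (targeted genes + targeted spike-ins); the
  # pre-capture share averages the per-replicate shares (equal depths)
  on <- c(targeted, ladder$targeted)
  p_pre_r <- vapply(seq_len(params$n_replicates), function(r) {
    w <- c(ifelse(dropout[, r], 0, lambda_cpm), spike_w)
    sum(w[on]) / sum(w)
  }, numeric(1))
  p_pre <- mean(p_pre_r)
  post_mask <- lambda_cpm
  if (params$dropout_post) {
    # library-construction loss: capture cannot rescue; expectation uses
    # the per-replicate masks
    p_post_r <- vapply(seq_len(params$n_replicates), function(r) {
      w <- c(ifelse(dropout[, r], 0, lambda_cpm) *
               ifelse(targeted, C, params$carryover), spike_w * spike_C)
      sum(w[on]) / sum(w)
    }, numeric(1))
    p_post <- mean(p_post_r)
  } else {
    w_post <- c(post_mask * ifelse(targeted, C, params$carryover),
                spike_w * spike_C)
    p_post <- sum(w_post[on]) / sum(w_post)
  }
  structure(
    list(params = params, gene_ids = gene_ids, lambda_cpm = lambda_cpm,
         targeted = targeted, capture_efficiency = C, dropout = dropout,
         dropout_all = dropout_all,
         ladder = ladder, spike_weights = spike_w, spike_C = spike_C,
         target_ids = c(gene_ids[targeted],
                        ladder$spike_id[ladder$targeted]),
         p_pre = p_pre, p_post = p_post,
         expected_ef = p_post / p_pre),
    class = "capture_sim_truth"
  )
}

.sample_counts <- function(weights, depth, n_replicates, ids, phase,
                           capture) {
  # weights: vector (shared across replicates) or matrix with one column
  # per replicate
  if (is.matrix(weights)) {
    m <- vapply(seq_len(n_replicates), function(r) {
      stats::rmultinom(1, size = depth,
                       prob = weights[, r] / sum(weights[, r]))[, 1]
    }, numeric(nrow(weights)))
  } else {
    m <- stats::rmultinom(n_replicates, size = depth,
                          prob = weights / sum(weights))
  }
  rownames(m) <- ids
  meta <- data.frame(
    sample_id = sprintf("%s_%s_r%d", capture, phase,
                        seq_len(n_replicates)),
    phase = phase, capture = capture,
    replicate = sprintf("r%d", seq_len(n_replicates)),
    stringsAsFactors = FALSE
  )
  count_matrix(m, meta)
}

#' Simulate pre-capture libraries
#'
#' Per replicate, counts are drawn Multinomial(depth_pre, w) where w is the
#' expression vector with that replicate's dropped-out genes masked to
#' zero, plus spike-in weights, so column totals equal the depth exactly.
#'
#' @param truth `capture_sim_truth`.
#' @param capture capture label recorded in the sample metadata.
#' @return `count_matrix` (genes then spike-ins in rows).
#' @export
simulate_pre_capture <- function(truth, capture = "sim") {
  p <- truth$params
  w <- vapply(seq_len(p$n_replicates), function(r) {
    c(ifelse(truth$dropout[, r], 0, truth$lambda_cpm),
      truth$spike_weights)
  }, numeric(p$n_genes + nrow(truth$ladder)))
  .sample_counts(w, p$depth_pre, p$n_replicates,
                 c(truth$gene_ids, truth$ladder$spike_id), "pre", capture)
}

#' Simulate post-capture libraries
#'
#' Sampling weights are expression times capture efficiency for targeted
#' species and expression times the carry-over weight for non-targeted
#' species; counts are Multinomial(depth_post, w). Genes dropped out of the
#' pre-capture library re-enter here (capture rescues them) unless
#' `dropout_post` was set.
#'
#' @inheritParams simulate_pre_capture
#' @return `count_matrix`.
#' @export
simulate_post_capture <- function(truth, capture = "sim") {
  p <- truth$params
  gene_mult <- ifelse(truth$targeted, truth$capture_efficiency, p$carryover)
  if (p$dropout_post) {
    w <- vapply(seq_len(p$n_replicates), function(r) {
      c(ifelse(truth$dropout[, r], 0, truth$lambda_cpm) * gene_mult,
        truth$spike_weights * truth$spike_C)
    }, numeric(p$n_genes + nrow(truth$ladder)))
  } else {
    w <- c(truth$lambda_cpm * gene_mult,
           truth$spike_weights * truth$spike_C)
  }
  .sample_counts(w, p$depth_post, p$n_replicates,
                 c(truth$gene_ids, truth$ladder$spike_id), "post", capture)
}

#' Simulate a complete pre/post capture experiment
#'
#' @param params `capture_sim_params`.
#' @param capture capture label.
#' @param ladder optional `spikein_ladder`.
#' @return list: `pre` and `post` (`count_matrix`), `combined`
#'   (`count_matrix` with both phases), `truth` (`capture_sim_truth`).
#' @export
simulate_capture_experiment <- function(params, capture = "sim",
                                        ladder = NULL) {
  truth <- simulate_capture_truth(params, ladder = ladder)
  pre <- simulate_pre_capture(truth, capture)
  post <- simulate_post_capture(truth, capture)
  combined <- count_matrix(cbind(pre$counts, post$counts),
                           rbind(pre$meta, post$meta))
  list(pre = pre, post = post, combined = combined, truth = truth)
}

#' Generate a 2-fold dilution spike-in ladder
#'
#' One spike-in per dilution rung: concentrations top_conc / dilution^k for
#' k = 0 .. n_spikes - 1, random sequence lengths between 250 and 2000 nt,
#' and targeted flags drawn at the given fraction (56/92 by default, the
#' classic partial-ERCC capture design) with at least one targeted and one
#' non-targeted spike-in.
#'
#' @param n_spikes number of spike-ins (>= 4).
#' @param top_conc highest concentration (attomoles/ul).
#' @param dilution fold dilution between rungs.
#' @param targeted_fraction fraction of spike-ins on the panel.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return `spikein_ladder`.
#' @export
generate_spikein_ladder <- function(n_spikes = 16, top_conc = 30000,
                                    dilution = 2,
                                    targeted_fraction = 56 / 92,
                                    seed = NULL) {
  if (n_spikes < 4) stop("need at least 4 spike-ins")
  if (!is.null(seed)) set.seed(seed)
  conc <- top_conc / dilution^(seq_len(n_spikes) - 1)
  len <- round(stats::runif(n_spikes, 250, 2000))
  targeted <- stats::runif(n_spikes) < targeted_fraction
  if (!any(targeted)) targeted[1] <- TRUE
  if (all(targeted)) targeted[n_spikes] <- FALSE
  spikein_ladder(sprintf("SPK%03d", seq_len(n_spikes)), len, conc, targeted)
}

#' Generate a toy genome annotation with auxiliary tracks
#'
#' Places non-overlapping genes (1-10 exons each; coding genes carry a CDS
#' inside the exon union) along one chromosome and generates repeat, EST,
#' SNP and tiered LD-block tracks. Deterministic under the seed.
#'
#' @param n_genes number of genes.
#' @param chrom_len chromosome length (nt).
#' @param chrom chromosome name.
#' @param biotype_mix named fractions for coding/lncRNA/other.
#' @param repeat_density,est_density expected features per 10 kb.
#' @param n_snps SNP count in the SNP table.
#' @param seed integer seed.
#' @return list: `annotation` (`annotation_set` with tracks `repeats`,
#'   `ests`, `ld_blocks` tiers), `snps` (data.frame), `seqlengths`.
#' @export
generate_annotation <- function(n_genes = 50, chrom_len = 1e6,
                                chrom = "chr1",
                                biotype_mix = c(coding = 0.5,
                                                lncRNA = 0.3, other = 0.2),
                                repeat_density = 1, est_density = 1,
                                n_snps = 40, seed = 1) {
  set.seed(seed)
  biotypes <- sample(names(biotype_mix), n_genes, replace = TRUE,
                     prob = biotype_mix)
  n_exons <- sample(1:10, n_genes, replace = TRUE)
  # draw structures first, then check packing feasibility
  exon_lens <- lapply(n_exons, function(k) round(stats::runif(k, 100, 500)))
  intron_lens <- lapply(n_exons, function(k) {
    if (k > 1) round(stats::runif(k - 1, 300, 2000)) else numeric(0)
  })
  spans <- mapply(function(e, i) sum(e) + sum(i), exon_lens, intron_lens)
  gap <- 2000
  if (sum(spans) + (n_genes + 1) * gap > chrom_len) {
    stop("infeasible packing: ", n_genes, " genes do not fit in ",
         chrom_len, " nt")
  }
  slack <- chrom_len - sum(spans) - (n_genes + 1) * gap
  extra <- diff(c(0, sort(stats::runif(n_genes, 0, 1)))) * slack
  starts <- gap + c(0, cumsum(spans[-n_genes] + gap)) + cumsum(extra)
  starts <- round(starts)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  tx_rows <- exon_rows <- cds_rows <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%04d", g)
    tid <- sprintf("T%04d", g)
    k <- n_exons[g]
    es <- starts[g] + cumsum(c(0, exon_lens[[g]][-k] + intron_lens[[g]]))
    ee <- es + exon_lens[[g]]
    tx_rows[[g]] <- data.frame(
      transcript_id = tid, gene_id = gid, biotype = biotypes[g],
      chrom = chrom, strand = strands[g], stringsAsFactors = FALSE)
    ex <- gintervals(chrom, es, ee, name = gid, strand = strands[g])
    ex$transcript_id <- tid
    ex$gene_id <- gid
    exon_rows[[g]] <- ex
    if (biotypes[g] == "coding") {
      # CDS: exon union shrunk by a UTR at each transcript end
      utr5 <- min(50, exon_lens[[g]][1] - 10)
      utr3 <- min(50, exon_lens[[g]][k] - 10)
      cs <- es; ce <- ee
      cs[1] <- cs[1] + utr5
      ce[k] <- ce[k] - utr3
      cd <- gintervals(chrom, cs, ce, name = gid, strand = strands[g])
      cd$transcript_id <- tid
      cd$gene_id <- gid
      cds_rows[[length(cds_rows) + 1]] <- cd
    }
  }
  transcripts <- do.call(rbind, tx_rows)
  exons <- do.call(rbind, exon_rows)
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else NULL
  rand_track <- function(n, min_len, max_len, names_pool) {
    if (n < 1) return(gintervals())
    s <- sort(round(stats::runif(n, 0, chrom_len - max_len)))
    l <- round(stats::runif(n, min_len, max_len))
    gintervals(chrom, s, s + l,
               name = sample(names_pool, n, replace = TRUE))
  }
  n_rep <- max(1, round(repeat_density * chrom_len / 1e4))
  n_est <- max(1, round(est_density * chrom_len / 1e4))
  repeats <- rand_track(n_rep, 80, 400,
                        c("rRNA", "tRNA", "7SK", "srpRNA", "LINE", "SINE"))
  ests <- rand_track(n_est, 200, 800, "EST")
  snp_pos <- sort(sample.int(chrom_len - 1, n_snps)) # 1-based positions
  snps <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chrom = chrom,
    pos = snp_pos,
    pvalue = 10^-stats::runif(n_snps, 4, 12),
    phenotype = sample(c("trait_a", "trait_b"), n_snps, replace = TRUE),
    stringsAsFactors = FALSE
  )
  # tiered LD blocks: most SNPs in tier 1 blocks, some only in tier 2/3
  tier_of <- sample(1:3, n_snps, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  mk_blocks <- function(tier) {
    idx <- which(tier_of == tier)
    if (!length(idx)) return(gintervals())
    half <- round(stats::runif(length(idx), 2000, 20000))
    merge_intervals(gintervals(
      chrom, pmax(0, snp_pos[idx] - 1 - half),
      pmin(chrom_len, snp_pos[idx] + half)))
  }
  ld_blocks <- lapply(1:3, mk_blocks)
  ann <- annotation_set(
    transcripts, exons, cds,
    tracks = list(repeats = repeats, ests = ests, ld_blocks = ld_blocks),
    seqlengths = stats::setNames(chrom_len, chrom))
  list(annotation = ann, snps = snps,
       seqlengths = stats::setNames(chrom_len, chrom))
}

#' Build a named simulation scenario
#'
#' One-command fixture bundles exercising every pipeline stage. Scenarios:
#' `"ng-like"` (small panel, ~0.5% of transcriptome mass, high capture
#' efficiency, mini-bulk dropout), `"tf-like"` (larger panel, ~2-3% of
#' mass, moderate efficiency, mini-bulk dropout),
#' `"low-complexity-minibulk"` (pronounced dropout). When `outdir` is given
#' all inputs are written as plain-text files (GTF, BED tracks, TSV tables,
#' truth JSON); re-running with the same seed reproduces them byte for
#' byte.
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param outdir optional output directory.
#' @return list: params, truth, pre, post, combined, annotation bundle,
#'   snps, ladder, and (when written) `files`.
#' @export
make_scenario <- function(name = c("ng-like", "tf-like",
                                   "low-complexity-minibulk"),
                          seed = 1, outdir = NULL) {
  name <- match.arg(name)
  params <- switch(
    name,
    "ng-like" = capture_sim_params(
      n_genes = 2000, targeted_fraction = 0.01, capture_efficiency = 400,
      capture_spread = 0.3, dropout_kappa = 200,
      exclude_top_expressed = 0.2, seed = seed),
    "tf-like" = capture_sim_params(
      n_genes = 2000, targeted_fraction = 0.05, capture_efficiency = 80,
      capture_spread = 0.3, dropout_kappa = 200,
      exclude_top_expressed = 0.1, seed = seed),
    "low-complexity-minibulk" = capture_sim_params(
      n_genes = 2000, targeted_fraction = 0.05, capture_efficiency = 80,
      capture_spread = 0.3, dropout_kappa = 500,
      exclude_top_expressed = 0.1, seed = seed)
  )
  sim <- simulate_capture_experiment(params, capture = name)
  gen <- generate_annotation(seed = seed + 1000L)
  bundle <- list(name = name, params = params, truth = sim$truth,
                 pre = sim$pre, post = sim$post, combined = sim$combined,
                 annotation = gen$annotation, snps = gen$snps,
                 ladder = sim$truth$ladder)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(outdir, x)
    write_gtf(gen$annotation, f("annotation.gtf"))
    write_bed(gen$annotation$tracks$repeats, f("repeats.bed"))
    write_bed(gen$annotation$tracks$ests, f("ests.bed"))
    for (i in seq_along(gen$annotation$tracks$ld_blocks)) {
      blk <- gen$annotation$tracks$ld_blocks[[i]]
      if (nrow(blk)) write_bed(blk, f(sprintf("ld_blocks_tier%d.bed", i)))
    }
    utils::write.table(gen$snps, f("snps.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_count_matrix(sim$combined, f("counts.tsv"), f("samples.tsv"))
    write_spikein_ladder(sim$truth$ladder, f("ladder.tsv"))
    truth_json <- list(
      scenario = name, seed = seed,
      targeted_genes = sim$truth$gene_ids[sim$truth$targeted],
      dropout_genes = sim$truth$gene_ids[sim$truth$dropout_all],
      p_pre = sim$truth$p_pre, p_post = sim$truth$p_post,
      expected_ef = sim$truth$expected_ef,
      lambda_cpm = as.list(sim$truth$lambda_cpm)
    )
    jsonlite::write_json(truth_json, f("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    bundle$files <- list(
      gtf = f("annotation.gtf"), counts = f("counts.tsv"),
      samples = f("samples.tsv"), ladder = f("ladder.tsv"),
      truth = f("truth.json"))
  }
  bundle
}
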