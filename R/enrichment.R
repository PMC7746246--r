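#' On-target read fraction of a library
#'
#' Fraction of usable reads assigned to the capture panel. In BED mode a
#' read interval is on-target when it overlaps any panel base by at least
#' 1 nt; in count mode the on-target reads are the counts of panel genes.
#'
#' @param reads interval table of aligned-read positions (BED mode), or
#'   `NULL` to use count mode.
#' @param panel `target_panel` (BED mode) or character vector of panel
#'   gene_ids (count mode).
#' @param gene_counts named per-gene counts for count mode.
#' @param total_reads total usable reads; in count mode defaults to
#'   `sum(gene_counts)`.
#' @return fraction in [0, 1].
#' @export
on_target_fraction <- function(reads = NULL, panel, gene_counts = NULL,
                               total_reads = NULL) {
  if (!is.null(reads)) {
    reads <- validate_intervals(reads, "reads")
    if (is.null(total_reads)) total_reads <- nrow(reads)
    if (total_reads <= 0) stop("total_reads must be positive")
    targets <- if (inherits(panel, "target_panel")) panel$targets else
      validate_intervals(panel, "panel")
    n_on <- sum(IRanges::overlapsAny(.as_granges(reads),
                                     .as_granges(targets),
                                     ignore.strand = TRUE))
    return(n_on / total_reads)
  }
  if (is.null(gene_counts)) stop("supply reads or gene_counts")
  panel_ids <- if (inherits(panel, "target_panel")) panel_genes(panel) else
    as.character(panel)
  if (is.null(total_reads)) total_reads <- sum(gene_counts)
  if (total_reads <= 0) stop("total_reads must be positive")
  sum(gene_counts[names(gene_counts) %in% panel_ids]) / total_reads
}

#' Sample-level capture enrichment factor
#'
#' Ratio of the post-capture on-target read proportion to the pre-capture
#' proportion, so successful captures give values above 1 (the study-scale
#' range is tens to hundreds-fold).
#'
#' @param pre_fraction,post_fraction on-target fractions in [0, 1];
#'   vectors are paired.
#' @return enrichment factor(s); `NA` where the pre fraction is 0.
#' @export
sample_enrichment_factor <- function(pre_fraction, post_fraction) {
  if (any(pre_fraction < 0 | pre_fraction > 1, na.rm = TRUE) ||
      any(post_fraction < 0 | post_fraction > 1, na.rm = TRUE)) {
    stop("fractions must lie in [0, 1]")
  }
  ef <- ifelse(pre_fraction > 0, post_fraction / pre_fraction, NA_real_)
  ef
}

#' Median sample enrichment factor of a capture
#' @param ef vector of per-sample enrichment factors.
#' @return median over defined values.
#' @export
median_sample_ef <- function(ef) {
  stats::median(ef[is.finite(ef)])
}

#' Gene-level capture enrichment
#'
#' For each targeted gene the enrichment factor is the ratio of its mean
#' post-capture CPM to its mean pre-capture CPM (means across replicates
#' within phase). For plotting, the log2 scale adds a pseudocount of 1
#' (`ef_log = log2(ef_raw + 1)`) so not-enriched genes fall in (0, 1).
#' Genes are categorized: `enriched` (detected pre, ef_raw > 1),
#' `not_enriched` (detected pre, ef_raw <= 1), `rescued` (undetected pre,
#' detected post), `undetected` (detected in neither phase). The enrichment
#' success rate is the percentage of genes detected pre-capture that are
#' enriched post-capture.
#'
#' @param pre_cpm,post_cpm CPM matrices (genes x replicates) for the two
#'   phases, or a `count_matrix` in `cm` with both phases.
#' @param cm optional `count_matrix`; overrides `pre_cpm`/`post_cpm`.
#' @param targeted_genes gene_ids on the capture panel.
#' @param pseudocount added inside the log2 transform.
#' @return data.frame gene_id, pre_mean, post_mean, ef_raw, ef_log,
#'   category, with attribute `success_rate` (percent).
#' @export
gene_enrichment <- function(pre_cpm = NULL, post_cpm = NULL,
                            targeted_genes, cm = NULL, pseudocount = 1) {
  if (!is.null(cm)) {
    cpm <- cpm_normalize(cm)
    pre_cpm <- cpm[, cm$meta$phase == "pre", drop = FALSE]
    post_cpm <- cpm[, cm$meta$phase == "post", drop = FALSE]
  }
  missing_genes <- setdiff(targeted_genes, rownames(pre_cpm))
  if (length(missing_genes)) {
    stop("targeted gene absent from matrix: ", missing_genes[1])
  }
  pre_mean <- rowMeans(pre_cpm[targeted_genes, , drop = FALSE])
  post_mean <- rowMeans(post_cpm[targeted_genes, , drop = FALSE])
  ef_raw <- ifelse(pre_mean > 0, post_mean / pre_mean, NA_real_)
  category <- rep("undetected", length(targeted_genes))
  category[pre_mean == 0 & post_mean > 0] <- "rescued"
  category[pre_mean > 0 & ef_raw > 1] <- "enriched"
  category[pre_mean > 0 & ef_raw <= 1] <- "not_enriched"
  detected_pre <- sum(pre_mean > 0)
  success_rate <- if (detected_pre > 0) {
    100 * sum(category == "enriched") / detected_pre
  } else {
    NA_real_
  }
  out <- data.frame(
    gene_id = targeted_genes,
    pre_mean = pre_mean,
    post_mean = post_mean,
    ef_raw = ef_raw,
    ef_log = log2(ifelse(is.na(ef_raw), NA_real_, ef_raw) + pseudocount),
    category = category,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "success_rate") <- success_rate
  out
}

#' Per-gene coefficient of variation across replicates
#'
#' CV = sd / mean (sample sd, n - 1 denominator) per gene over the given
#' sample columns, defined for genes whose group mean is positive.
#'
#' @param cpm CPM matrix.
#' @param samples column names or indices of the replicate group.
#' @return named vector of CVs (genes with zero mean are `NA`).
#' @export
replicate_cv <- function(cpm, samples = colnames(cpm)) {
  m <- cpm[, samples, drop = FALSE]
  if (ncol(m) < 2) stop("replicate_cv requires at least 2 replicates")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  names(cv) <- rownames(m)
  cv
}

#' Paired comparison of replicate variability pre vs post capture
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test on per-gene CVs,
#' pairing genes defined in both groups. The exact distribution is used for
#' 25 or fewer informative pairs, the normal approximation with continuity
#' correction above. Zero differences are dropped by default.
#'
#' @param pre_cv,post_cv named CV vectors from [replicate_cv()].
#' @param drop_zeros drop genes with identical CVs before ranking.
#' @return list: n_pairs, statistic (V), p_value, median_pre, median_post,
#'   direction (`post_lower`, `post_higher`, `none`).
#' @export
compare_cv <- function(pre_cv, post_cv, drop_zeros = TRUE) {
  shared <- intersect(names(pre_cv)[is.finite(pre_cv)],
                      names(post_cv)[is.finite(post_cv)])
  if (length(shared) < 2) stop("fewer than 2 genes with defined CV in both")
  x <- pre_cv[shared]
  y <- post_cv[shared]
  d <- x - y
  if (drop_zeros) {
    keep <- d != 0
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 1) {
    return(list(n_pairs = 0L, statistic = NA_real_, p_value = 1,
                median_pre = stats::median(pre_cv[shared]),
                median_post = stats::median(post_cv[shared]),
                direction = "none"))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, alternative = "two.sided",
    exact = n <= 25, correct = TRUE))
  med_pre <- stats::median(x)
  med_post <- stats::median(y)
  list(
    n_pairs = n,
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    median_pre = med_pre,
    median_post = med_post,
    direction = if (med_post < med_pre) "post_lower" else
      if (med_post > med_pre) "post_higher" else "none"
  )
}

#' Between-gene enrichment variability above and below a threshold
#'
#' Splits genes at a pre-capture expression cut-off (strictly above vs at or
#' below) and reports the coefficient of variation of the raw enrichment
#' factor within each stratum.
#'
#' @param ef vector of per-gene raw enrichment factors.
#' @param pre_means matching pre-capture mean CPMs.
#' @param threshold expression cut-off in CPM (positive).
#' @return list: cv_above, cv_below, n_above, n_below (CV is `NA` for a
#'   stratum with fewer than 2 genes).
#' @export
group_cv <- function(ef, pre_means, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  ok <- is.finite(ef) & is.finite(pre_means)
  ef <- ef[ok]; pre_means <- pre_means[ok]
  above <- ef[pre_means > threshold]
  below <- ef[pre_means <= threshold]
  cv <- function(v) if (length(v) >= 2 && mean(v) != 0)
    stats::sd(v) / mean(v) else NA_real_
  list(cv_above = cv(above), cv_below = cv(below),
       n_above = length(above), n_below = length(below))
}

#' Validate pre/post read balance for paired libraries
#'
#' A pre/post pair is usable for enrichment scoring only when the
#' pre-capture library has at least as many usable reads as the matched
#' post-capture library has on-target reads (downsampling pre-capture
#' libraries would bias read selection, so failing pairs are excluded
#' rather than downsampled).
#'
#' @param pre_usable named vector of usable pre-capture read counts.
#' @param post_on_target named vector of post-capture on-target read
#'   counts; names must pair with `pre_usable`.
#' @return data.frame pair, pre_usable, post_on_target, pass.
#' @export
validate_read_balance <- function(pre_usable, post_on_target) {
  if (is.null(names(pre_usable)) || is.null(names(post_on_target))) {
    stop("pre and post vectors must be named to pair libraries")
  }
  unpaired <- union(setdiff(names(pre_usable), names(post_on_target)),
                    setdiff(names(post_on_target), names(pre_usable)))
  if (length(unpaired)) {
    stop("unpaired library: ", unpaired[1])
  }
  nm <- names(pre_usable)
  data.frame(
    pair = nm,
    pre_usable = unname(pre_usable[nm]),
    post_on_target = unname(post_on_target[nm]),
    pass = unname(pre_usable[nm] >= post_on_target[nm]),
    stringsAsFactors = FALSE
  )
}

#' Correlate samples with reference stage expression profiles
#'
#' Reference replicate profiles are first averaged per timepoint/stage, then
#' each sample is correlated (Pearson, on log2(x + 1) expression) with each
#' averaged stage profile over the shared genes. Each sample is assigned the
#' stage of maximum correlation; exact ties go to the earliest stage and are
#' flagged.
#'
#' @param sample_profiles genes x samples expression matrix (linear scale).
#' @param reference genes x reference-column expression matrix.
#' @param stages character vector mapping reference columns to stage labels
#'   (replicate columns share a label); defaults to the column names.
#' @return list: `correlations` (samples x stages matrix) and `assignment`
#'   (data.frame sample, stage, correlation, tie).
#' @export
stage_correlation <- function(sample_profiles, reference,
                              stages = colnames(reference)) {
  sample_profiles <- as.matrix(sample_profiles)
  reference <- as.matrix(reference)
  if (length(stages) != ncol(reference)) {
    stop("stages must label every reference column")
  }
  shared <- intersect(rownames(sample_profiles), rownames(reference))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  s <- log2(sample_profiles[shared, , drop = FALSE] + 1)
  r <- log2(reference[shared, , drop = FALSE] + 1)
  stage_levels <- unique(stages)
  ravg <- vapply(stage_levels, function(st) {
    rowMeans(r[, stages == st, drop = FALSE])
  }, numeric(length(shared)))
  const <- apply(s, 2, stats::sd) == 0
  if (any(const)) {
    stop("constant sample profile: ", colnames(s)[which(const)[1]])
  }
  if (any(apply(ravg, 2, stats::sd) == 0)) {
    stop("constant reference stage profile")
  }
  cors <- stats::cor(s, ravg, method = "pearson")
  best <- apply(cors, 1, which.max)  # ties resolved to earliest stage
  tie <- apply(cors, 1, function(v) sum(v == max(v)) > 1)
  assignment <- data.frame(
    sample = rownames(cors),
    stage = stage_levels[best],
    correlation = cors[cbind(seq_len(nrow(cors)), best)],
    tie = tie,
    stringsAsFactors = FALSE
  )
  rownames(assignment) <- NULL
  list(correlations = cors, assignment = assignment)
}
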