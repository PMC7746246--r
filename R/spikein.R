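#' Construct a spike-in ladder
#'
#' Describes a set of synthetic RNA controls of known input concentration
#' (a 2-fold dilution series in the classic design), each with a sequence
#' length and a flag saying whether it is targeted by the capture panel.
#' Non-targeted spike-ins serve as a within-experiment depletion control.
#'
#' @param spike_id character identifiers.
#' @param length_nt sequence lengths (nt), positive.
#' @param concentration known concentrations (attomoles/ul), positive.
#' @param targeted logical: on the capture panel.
#' @return data.frame of class `spikein_ladder`.
#' @export
spikein_ladder <- function(spike_id, length_nt, concentration, targeted) {
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (any(length_nt <= 0)) stop("lengths must be positive")
  if (anyDuplicated(spike_id)) stop("duplicate spike_id")
  df <- data.frame(
    spike_id = as.character(spike_id),
    length_nt = as.numeric(length_nt),
    concentration = as.numeric(concentration),
    targeted = as.logical(targeted),
    stringsAsFactors = FALSE
  )
  class(df) <- unique(c("spikein_ladder", class(df)))
  df
}

#' Read / write a spike-in ladder TSV
#'
#' Columns: spike_id, length_nt, concentration_attomol_ul, targeted (0/1).
#'
#' @param path file path.
#' @return `spikein_ladder`.
#' @export
read_spikein_ladder <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spike_id", "length_nt", "concentration_attomol_ul", "targeted")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("ladder file missing column(s): ", paste(miss, collapse = ", "))
  }
  spikein_ladder(tab$spike_id, tab$length_nt, tab$concentration_attomol_ul,
                 tab$targeted != 0)
}

#' @rdname read_spikein_ladder
#' @param ladder `spikein_ladder` to write.
#' @export
write_spikein_ladder <- function(ladder, path) {
  utils::write.table(
    data.frame(spike_id = ladder$spike_id,
               length_nt = ladder$length_nt,
               concentration_attomol_ul = ladder$concentration,
               targeted = as.integer(ladder$targeted)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Counts per kilobase per million (CPKM)
#'
#' cpkm = count / (length/1000) / (total_reads/1e6). The denominator is the
#' total usable reads of the library (configurable by passing a different
#' total, e.g. total spike-in reads).
#'
#' @param counts per-spike-in read counts.
#' @param length_nt matching sequence lengths (nt).
#' @param total_reads library total (> 0).
#' @return numeric CPKM vector.
#' @export
cpkm <- function(counts, length_nt, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (any(length_nt <= 0)) stop("lengths must be positive")
  counts / (length_nt / 1000) / (total_reads / 1e6)
}

#' Spike-in detection threshold of a library set
#'
#' A spike-in is detected when it has at least `min_reads` reads in at least
#' one replicate. The detection threshold is the lowest known concentration
#' among detected, targeted spike-ins.
#'
#' @param ladder `spikein_ladder`.
#' @param counts matrix spike-ins x replicates (rownames = spike_id), or a
#'   named vector for a single library.
#' @param min_reads detection rule.
#' @param targeted_only restrict to targeted spike-ins (default).
#' @return threshold concentration, or `NA` when nothing is detected.
#' @export
detection_threshold <- function(ladder, counts, min_reads = 1,
                                targeted_only = TRUE) {
  m <- if (is.matrix(counts)) counts else
    matrix(counts, ncol = 1, dimnames = list(names(counts), NULL))
  ids <- ladder$spike_id
  if (targeted_only) ids <- ids[ladder$targeted]
  ids <- intersect(ids, rownames(m))
  detected <- ids[apply(m[ids, , drop = FALSE] >= min_reads, 1, any)]
  if (!length(detected)) return(NA_real_)
  min(ladder$concentration[ladder$spike_id %in% detected])
}

#' Fold improvement of the detection threshold after capture
#' @param pre_threshold,post_threshold thresholds from
#'   [detection_threshold()].
#' @return pre/post ratio; `NA` if either is undefined.
#' @export
threshold_improvement <- function(pre_threshold, post_threshold) {
  if (is.na(pre_threshold) || is.na(post_threshold)) return(NA_real_)
  pre_threshold / post_threshold
}

#' Spearman correlation of measured expression with known concentration
#'
#' @param cpkm_values per-spike-in CPKM.
#' @param ladder `spikein_ladder` (same order as `cpkm_values`, or
#'   `cpkm_values` named by spike_id).
#' @param detected_only drop undetected spike-ins (cpkm == 0).
#' @return list: rho, p_value (two-tailed), n.
#' @export
concentration_correlation <- function(cpkm_values, ladder,
                                      detected_only = TRUE) {
  conc <- .match_ladder(cpkm_values, ladder)
  keep <- if (detected_only) cpkm_values > 0 else rep(TRUE,
                                                      length(cpkm_values))
  x <- conc[keep]; y <- cpkm_values[keep]
  if (length(x) < 5) stop("fewer than 5 detected spike-ins")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Log10-log10 dose-response slope
#'
#' Ordinary least-squares straight line of log10 CPKM on log10 known
#' concentration, over detected spike-ins. A slope of 1 indicates perfectly
#' proportional quantitation.
#'
#' @inheritParams concentration_correlation
#' @return list: slope, intercept, n.
#' @export
loglog_slope <- function(cpkm_values, ladder) {
  conc <- .match_ladder(cpkm_values, ladder)
  keep <- cpkm_values > 0
  x <- log10(conc[keep]); y <- log10(cpkm_values[keep])
  if (length(x) < 3) stop("fewer than 3 detected spike-ins")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n = length(x))
}

#' Depletion of non-targeted spike-ins by capture
#'
#' Fold depletion = mean pre-capture CPKM / mean post-capture CPKM over the
#' spike-ins not targeted by the panel.
#'
#' @param pre_cpkm,post_cpkm named CPKM vectors (names = spike_id).
#' @param ladder `spikein_ladder`.
#' @return fold depletion (Inf when the post mean is 0).
#' @export
depletion_factor <- function(pre_cpkm, post_cpkm, ladder) {
  ids <- ladder$spike_id[!ladder$targeted]
  if (!length(ids)) stop("no non-targeted spike-ins in ladder")
  ids <- intersect(ids, intersect(names(pre_cpkm), names(post_cpkm)))
  pre_m <- mean(pre_cpkm[ids])
  post_m <- mean(post_cpkm[ids])
  if (post_m == 0) return(Inf)
  pre_m / post_m
}

#' Flag low-complexity libraries
#'
#' Libraries whose complexity (number of detected genes) falls below a
#' percentile of the cohort are flagged for exclusion from spike-in
#' quantitation, mirroring the removal of poor-quality pre-capture
#' libraries. The flag is explicit, never silent.
#'
#' @param counts genes x samples count matrix.
#' @param percentile complexity percentile below which to flag.
#' @param min_reads detection rule per gene.
#' @return data.frame sample, n_detected, flagged.
#' @export
flag_low_complexity <- function(counts, percentile = 0.1, min_reads = 1) {
  n_det <- colSums(counts >= min_reads)
  cut <- stats::quantile(n_det, percentile, names = FALSE)
  data.frame(sample = colnames(counts), n_detected = unname(n_det),
             flagged = unname(n_det < cut), stringsAsFactors = FALSE)
}

.match_ladder <- function(values, ladder) {
  if (!is.null(names(values))) {
    i <- match(names(values), ladder$spike_id)
    if (any(is.na(i))) {
      stop("value named after unknown spike_id: ",
           names(values)[which(is.na(i))[1]])
    }
    ladder$concentration[i]
  } else {
    if (length(values) != nrow(ladder)) {
      stop("unnamed values must match ladder length")
    }
    ladder$concentration
  }
}
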