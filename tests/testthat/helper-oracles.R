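# Per-base boolean-mask oracles for interval arithmetic on toy chromosomes.
# These are deliberately naive O(L) implementations, independent of the
# GRanges-backed code paths they check.

mask_from_intervals <- function(iv, L) {
  m <- logical(L)
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      s <- max(0, iv$start[i]) + 1
      e <- min(L, iv$end[i])
      if (s <= e) m[s:e] <- TRUE
    }
  }
  m
}

intervals_from_mask <- function(m, chrom = "c1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(gintervals())
  gintervals(chrom, starts[keep], ends[keep])
}

oracle_merge <- function(iv, L) {
  intervals_from_mask(mask_from_intervals(iv, L), iv$chrom[1])
}

# mark every base within `margin` nt (gap < margin) of a TRUE base;
# windowed-OR via cumulative sums: base i is marked iff any TRUE base lies
# in [i - margin, i + margin]
dilate_mask <- function(m, margin) {
  if (margin == 0 || !any(m)) return(m)
  L <- length(m)
  cs <- c(0, cumsum(m))
  hi <- pmin(L, seq_len(L) + margin)
  lo <- pmax(0, seq_len(L) - margin - 1)
  (cs[hi + 1] - cs[lo + 1]) > 0
}

oracle_subtract <- function(targets, exclusions, margin, L) {
  mt <- mask_from_intervals(targets, L)
  me <- dilate_mask(mask_from_intervals(exclusions, L), margin)
  keep <- mt & !me
  if (!any(keep)) return(gintervals())
  intervals_from_mask(keep, targets$chrom[1])
}

# brute-force min gap between two 0-based half-open intervals
interval_gap <- function(qs, qe, rs, re) {
  if (qs < re && rs < qe) return(0)       # overlap
  if (qs >= re) qs - re else rs - qe
}

oracle_within <- function(query, reference, max_dist) {
  keep <- vapply(seq_len(nrow(query)), function(i) {
    same <- reference[reference$chrom == query$chrom[i], , drop = FALSE]
    if (!nrow(same)) return(FALSE)
    gaps <- vapply(seq_len(nrow(same)), function(j) {
      interval_gap(query$start[i], query$end[i],
                   same$start[j], same$end[j])
    }, numeric(1))
    min(gaps) <= max_dist
  }, logical(1))
  out <- query[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, L, chrom = "c1", max_len = 500) {
  s <- sample.int(L - 2, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  gintervals(chrom, s, pmin(s + len, L))
}

# mirror a genome of length L: coordinates reflect, strands flip
mirror_intervals <- function(iv, L) {
  out <- iv
  out$start <- L - iv$end
  out$end <- L - iv$start
  out$strand <- ifelse(iv$strand == "+", "-",
                       ifelse(iv$strand == "-", "+", "*"))
  validate_intervals(out)
}

mirror_annotation <- function(ann, L) {
  tx <- ann$transcripts
  tx$strand <- ifelse(tx$strand == "+", "-", "+")
  flip_tab <- function(tab) {
    if (is.null(tab) || !nrow(tab)) return(tab)
    s <- L - tab$end
    tab$end <- L - tab$start
    tab$start <- s
    tab$strand <- ifelse(tab$strand == "+", "-",
                         ifelse(tab$strand == "-", "+", "*"))
    tab[order(tab$transcript_id, tab$start), , drop = FALSE]
  }
  annotation_set(tx, flip_tab(ann$exons), flip_tab(ann$cds),
                 tracks = lapply(ann$tracks, function(t) {
                   if (is.data.frame(t)) mirror_intervals(t, L) else t
                 }))
}
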