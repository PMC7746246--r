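#' Construct a genomic interval table
#'
#' The unit of all panel-design arithmetic is a plain data.frame of genomic
#' intervals in 0-based half-open coordinates (BED convention): a base at
#' position p is covered by an interval iff start <= p < end.
#'
#' @param chrom character vector of sequence names.
#' @param start 0-based inclusive start positions (nt).
#' @param end 0-based exclusive end positions (nt); must satisfy start < end.
#' @param name optional labels (recycled); `NA` allowed.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @return data.frame with columns chrom, start, end, name, strand and class
#'   `genomic_intervals`.
#' @examples
#' gintervals("chr1", 0, 100)
#' @export
gintervals <- function(chrom = character(), start = integer(),
                       end = integer(), name = NA_character_,
                       strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0) n <- 0
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = rep_len(as.character(name), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
}

#' Validate an interval table
#'
#' @param x data.frame with at least chrom/start/end columns.
#' @param what label used in error messages.
#' @return `x`, with class `genomic_intervals` and name/strand columns filled.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) {
    stop(what, " must be a data.frame of genomic intervals")
  }
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(x$name)) x$name <- NA_character_
  if (is.null(x$strand)) x$strand <- "*"
  x$strand[is.na(x$strand) | x$strand == "."] <- "*"
  bad_strand <- !x$strand %in% c("+", "-", "*")
  if (any(bad_strand)) {
    stop(what, ": invalid strand '", x$strand[which(bad_strand)[1]], "'")
  }
  if (nrow(x)) {
    if (any(is.na(x$start)) || any(is.na(x$end)) || any(is.na(x$chrom))) {
      stop(what, ": NA coordinates in record ",
           which(is.na(x$start) | is.na(x$end) | is.na(x$chrom))[1])
    }
    bad <- x$start < 0 | x$start >= x$end
    if (any(bad)) {
      i <- which(bad)[1]
      stop(what, ": invalid interval at record ", i, " (",
           x$chrom[i], ":", x$start[i], "-", x$end[i],
           "); require 0 <= start < end")
    }
  }
  rownames(x) <- NULL
  class(x) <- unique(c("genomic_intervals", class(x)))
  x
}

#' Interval lengths in nucleotides
#' @param x interval table.
#' @return numeric vector `end - start`.
#' @export
interval_length <- function(x) {
  x <- validate_intervals(x)
  x$end - x$start
}

## GRanges conversion helpers. Internal coordinates are 0-based half-open;
## GRanges is 1-based closed, so start shifts by +1 and end is unchanged.
.as_granges <- function(x, keep_strand = FALSE) {
  x <- validate_intervals(x)
  if (!nrow(x)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = if (keep_strand) x$strand else "*",
    name = x$name
  )
}

.from_granges <- function(gr) {
  if (!length(gr)) {
    return(gintervals())
  }
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  gintervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = nm,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Sort intervals by (chrom, start, end), ties broken by name
#'
#' Lexicographic on chromosome name, then numerically on start and end;
#' residual ties are broken by name and finally input order, so sorting is
#' deterministic.
#'
#' @param x interval table.
#' @return sorted interval table.
#' @export
sort_intervals <- function(x) {
  x <- validate_intervals(x)
  if (!nrow(x)) return(x)
  o <- order(x$chrom, x$start, x$end, x$name, seq_len(nrow(x)),
             method = "radix")
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## sorted-scan union of one chromosome's intervals (starts already ordered)
.merge_chr <- function(start, end) {
  if (length(start) == 1) return(list(start = start, end = end))
  hi <- cummax(end)
  new_run <- c(TRUE, start[-1] > hi[-length(hi)])
  grp <- cumsum(new_run)
  list(start = start[new_run],
       end = as.numeric(tapply(end, grp, max)))
}

#' Merge overlapping and book-ended intervals
#'
#' Returns the disjoint union of the input: overlapping intervals and
#' adjacent intervals (one's end equals the next's start) are fused. Strand
#' is ignored; hybridization capture is strand-agnostic.
#'
#' @param intervals interval table.
#' @return sorted, pairwise-disjoint interval table covering exactly the
#'   same bases as the input.
#' @examples
#' merge_intervals(gintervals("c1", c(100, 150), c(200, 300)))
#' @export
merge_intervals <- function(intervals) {
  intervals <- validate_intervals(intervals)
  if (!nrow(intervals)) return(gintervals())
  o <- order(intervals$chrom, intervals$start, intervals$end,
             method = "radix")
  s <- intervals$start[o]
  e <- intervals$end[o]
  ch <- intervals$chrom[o]
  parts <- lapply(split(seq_along(s), factor(ch, levels = unique(ch))),
                  function(i) .merge_chr(s[i], e[i]))
  gintervals(
    chrom = rep(names(parts), vapply(parts, function(p) length(p$start), 0L)),
    start = unlist(lapply(parts, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(parts, `[[`, "end"), use.names = FALSE)
  )
}

#' Subtract exclusion regions plus a safety margin from target regions
#'
#' Removes from `targets` every base whose gap to any base of `exclusions`
#' is smaller than `margin` (gap = number of intervening bases; overlap is
#' gap < 0 and always removed). Bases at gap >= margin are kept, so with
#' margin 0 only overlapping bases are removed. Equivalent to widening each
#' exclusion by `margin` on both sides and taking the set difference. The
#' operation is idempotent and zero-length results are dropped.
#'
#' @param targets interval table to be trimmed.
#' @param exclusions interval table to subtract.
#' @param margin non-negative margin in nt.
#' @return merged interval table of surviving target bases.
#' @examples
#' subtract_with_margin(gintervals("c1", 0, 1000),
#'                      gintervals("c1", 500, 600), margin = 50)
#' @export
subtract_with_margin <- function(targets, exclusions, margin = 0) {
  if (!is.numeric(margin) || length(margin) != 1 || is.na(margin) ||
      margin < 0) {
    stop("margin must be a single non-negative number")
  }
  targets <- validate_intervals(targets, "targets")
  exclusions <- validate_intervals(exclusions, "exclusions")
  if (!nrow(targets)) return(gintervals())
  tgt <- merge_intervals(targets)
  if (!nrow(exclusions)) return(tgt)
  exc <- merge_intervals(gintervals(exclusions$chrom,
                                    pmax(0, exclusions$start - margin),
                                    exclusions$end + margin))
  parts <- lapply(unique(tgt$chrom), function(ch) {
    ti <- tgt[tgt$chrom == ch, , drop = FALSE]
    ei <- exc[exc$chrom == ch, , drop = FALSE]
    d <- .diff_sorted(ti$start, ti$end, ei$start, ei$end)
    if (!length(d$start)) return(NULL)
    gintervals(ch, d$start, d$end)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(gintervals())
  sort_intervals(do.call(rbind, parts))
}

#' Select query intervals within a distance of a reference set
#'
#' Keeps the query intervals whose minimum gap to any reference interval on
#' the same chromosome is at most `max_dist` nt. Overlapping or book-ended
#' intervals are at gap 0; distance is never computed across chromosomes.
#'
#' @param query interval table to filter.
#' @param reference interval table to measure against.
#' @param max_dist non-negative distance in nt.
#' @return the retained subset of `query`, original order and columns.
#' @export
within_distance <- function(query, reference, max_dist = 0) {
  if (!is.numeric(max_dist) || length(max_dist) != 1 || is.na(max_dist) ||
      max_dist < 0) {
    stop("max_dist must be a single non-negative number")
  }
  query <- validate_intervals(query, "query")
  reference <- validate_intervals(reference, "reference")
  if (!nrow(query) || !nrow(reference)) {
    return(query[integer(0), , drop = FALSE])
  }
  # gap <= max_dist is equivalent to touching (book-ended or overlapping)
  # the reference widened by max_dist on both sides
  ref <- merge_intervals(gintervals(reference$chrom,
                                    pmax(0, reference$start - max_dist),
                                    reference$end + max_dist))
  keep <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ri <- ref[ref$chrom == ch, , drop = FALSE]
    if (!nrow(ri)) next
    # candidate: last reference starting at or before the query end; since
    # merged references have increasing ends, only it can touch the query
    idx <- findInterval(query$end[qi], ri$start)
    keep[qi] <- idx >= 1 & ri$end[pmax(idx, 1)] >= query$start[qi]
  }
  out <- query[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Fast difference of sorted, disjoint interval vectors on one chromosome.
## Used in per-gene/per-transcript inner loops where the S4 overhead of a
## ranges object per call would dominate; semantics match
## subtract_with_margin(margin = 0) and are cross-checked in the tests.
.diff_sorted <- function(a_start, a_end, b_start, b_end) {
  out_s <- numeric(0)
  out_e <- numeric(0)
  j <- 1L
  nb <- length(b_start)
  for (i in seq_along(a_start)) {
    s <- a_start[i]
    e <- a_end[i]
    while (j <= nb && b_end[j] <= s) j <- j + 1L
    k <- j
    while (k <= nb && b_start[k] < e) {
      if (b_start[k] > s) {
        out_s <- c(out_s, s)
        out_e <- c(out_e, b_start[k])
      }
      s <- max(s, b_end[k])
      k <- k + 1L
      if (s >= e) break
    }
    if (s < e) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, e)
    }
  }
  list(start = out_s, end = out_e)
}

#' Read a BED3+ file
#'
#' Reads BED in its native 0-based half-open coordinates, which are also the
#' package's internal convention, so no shift is applied. Columns beyond
#' chrom/start/end/name/score/strand are ignored.
#'
#' @param path file path.
#' @return interval table.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) return(gintervals())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", idx[which(nf < 3)[1]], " in ", path,
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    stop("malformed BED line ", idx[which(bad)[1]], " in ", path,
         ": require numeric 0 <= start < end")
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                 NA_character_)
  name[name == "."] <- NA_character_
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))], ""),
                   "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gintervals(chrom, start, end, name, strand)
}

#' Write intervals as BED6
#'
#' @param intervals interval table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  df <- data.frame(
    chrom = intervals$chrom,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE),
    name = ifelse(is.na(intervals$name), ".", intervals$name),
    score = 0L,
    strand = ifelse(intervals$strand == "*", ".", intervals$strand)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
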