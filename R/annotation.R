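#' Construct an annotation set
#'
#' Container for transcript models plus auxiliary interval tracks (repeats,
#' ESTs, SNP tables, LD blocks, gene deserts). All coordinates are 0-based
#' half-open.
#'
#' @param transcripts data.frame with one row per transcript: transcript_id,
#'   gene_id, biotype (`coding`, `lncRNA`, or `other`), chrom, strand.
#' @param exons data.frame of exon intervals with transcript_id and gene_id
#'   columns; exons of one transcript must be non-overlapping.
#' @param cds optional data.frame like `exons` for coding sequence; every
#'   CDS base must fall inside the exon union of its transcript.
#' @param tracks named list of auxiliary interval tables or data.frames.
#' @param seqlengths optional named vector declaring the sequence universe.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(transcripts, exons, cds = NULL, tracks = list(),
                           seqlengths = NULL) {
  need <- c("transcript_id", "gene_id", "biotype", "chrom", "strand")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) {
    stop("transcripts table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript_id in transcripts table")
  }
  exons <- validate_intervals(exons, "exons")
  if (is.null(exons$transcript_id) || is.null(exons$gene_id)) {
    stop("exons table requires transcript_id and gene_id columns")
  }
  # sort exons within transcript and check non-overlap
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tx in names(by_tx)) {
    i <- by_tx[[tx]]
    if (length(i) > 1) {
      s <- exons$start[i]; e <- exons$end[i]
      if (any(s[-1] < e[-length(e)])) {
        stop("overlapping exons in transcript ", tx)
      }
    }
  }
  orphan <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan)) {
    stop("exons reference unknown transcript_id: ", orphan[1])
  }
  if (!is.null(cds) && nrow(cds)) {
    cds <- validate_intervals(cds, "cds")
    if (is.null(cds$transcript_id)) {
      stop("cds table requires a transcript_id column")
    }
    cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
    for (tx in unique(cds$transcript_id)) {
      ce <- cds[cds$transcript_id == tx, , drop = FALSE]
      ex <- exons[exons$transcript_id == tx, , drop = FALSE]
      left <- .diff_sorted(ce$start, ce$end, ex$start, ex$end)
      if (length(left$start)) {
        stop("CDS outside exon union for transcript ", tx)
      }
    }
  } else {
    cds <- NULL
  }
  if (!is.null(seqlengths)) {
    missing_chr <- setdiff(unique(transcripts$chrom), names(seqlengths))
    if (length(missing_chr)) {
      stop("transcript chromosome not in declared sequence universe: ",
           missing_chr[1])
    }
  }
  structure(
    list(transcripts = transcripts, exons = exons, cds = cds,
         tracks = tracks, seqlengths = seqlengths),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$exons), "exons")
  if (length(x$tracks)) {
    cat("; tracks:", paste(names(x$tracks), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Genomic extent of each gene (first to last exon)
#'
#' @param annotation `annotation_set`.
#' @param biotype optional biotype filter.
#' @return interval table with one row per gene, name = gene_id.
#' @export
gene_extents <- function(annotation, biotype = NULL) {
  tx <- annotation$transcripts
  if (!is.null(biotype)) tx <- tx[tx$biotype %in% biotype, , drop = FALSE]
  ex <- annotation$exons[annotation$exons$transcript_id %in%
                           tx$transcript_id, , drop = FALSE]
  if (!nrow(ex)) return(gintervals())
  agg_start <- tapply(ex$start, ex$gene_id, min)
  agg_end <- tapply(ex$end, ex$gene_id, max)
  chrom <- tapply(ex$chrom, ex$gene_id, `[`, 1)
  g <- names(agg_start)
  sort_intervals(gintervals(as.character(chrom[g]), as.numeric(agg_start),
                            as.numeric(agg_end[g]), name = g))
}

#' Exons of genes of a given biotype
#'
#' @inheritParams gene_extents
#' @return exon interval table (name = gene_id).
#' @export
biotype_exons <- function(annotation, biotype) {
  tx <- annotation$transcripts
  keep_tx <- tx$transcript_id[tx$biotype %in% biotype]
  ex <- annotation$exons[annotation$exons$transcript_id %in% keep_tx, ,
                         drop = FALSE]
  if (!nrow(ex)) return(gintervals())
  gintervals(ex$chrom, ex$start, ex$end, name = ex$gene_id,
             strand = ex$strand)
}

#' Exons of one transcript in transcript (5'->3') orientation
#'
#' For a minus-strand transcript the first exon is the one with the highest
#' genomic coordinates.
#'
#' @param annotation `annotation_set`.
#' @param transcript_id transcript identifier.
#' @return exon interval table ordered 5' to 3'.
#' @export
transcript_exons <- function(annotation, transcript_id) {
  ex <- annotation$exons[annotation$exons$transcript_id == transcript_id, ,
                         drop = FALSE]
  if (!nrow(ex)) stop("unknown transcript: ", transcript_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  strand <- annotation$transcripts$strand[
    annotation$transcripts$transcript_id == transcript_id]
  if (identical(strand, "-")) ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

#' Read a GTF annotation file
#'
#' Parses GTF (1-based inclusive coordinates) and converts to the internal
#' 0-based half-open convention: a GTF feature `start..end` becomes the
#' interval `(start - 1, end)`, preserving length. Exon and CDS features are
#' assembled into transcript models; exons out of file order are sorted.
#'
#' @param path GTF file path.
#' @param biotype_attr attribute key carrying the biotype (tried in order;
#'   default looks for `gene_biotype` then `gene_type`).
#' @return `annotation_set`.
#' @export
read_gtf <- function(path, biotype_attr = c("gene_biotype", "gene_type")) {
  gr <- rtracklayer::import(path, format = "gtf")
  feat <- as.character(gr$type)
  keep <- feat %in% c("exon", "CDS")
  gr <- gr[keep]
  feat <- feat[keep]
  if (!length(gr)) stop("no exon or CDS features in ", path)
  tx_id <- as.character(gr$transcript_id)
  if (any(is.na(tx_id) | tx_id == "")) {
    stop("exon/CDS feature without transcript_id in ", path)
  }
  gene_id <- as.character(gr$gene_id)
  bio_raw <- rep(NA_character_, length(gr))
  for (key in biotype_attr) {
    if (!is.null(S4Vectors::mcols(gr)[[key]])) {
      v <- as.character(S4Vectors::mcols(gr)[[key]])
      bio_raw[is.na(bio_raw)] <- v[is.na(bio_raw)]
    }
  }
  biotype <- normalize_biotype(bio_raw)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = feat,
    transcript_id = tx_id,
    gene_id = gene_id,
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  exf <- df[df$feature == "exon", , drop = FALSE]
  cdf <- df[df$feature == "CDS", , drop = FALSE]
  first <- !duplicated(exf$transcript_id)
  transcripts <- data.frame(
    transcript_id = exf$transcript_id[first],
    gene_id = exf$gene_id[first],
    biotype = exf$biotype[first],
    chrom = exf$chrom[first],
    strand = exf$strand[first],
    stringsAsFactors = FALSE
  )
  exons <- gintervals(exf$chrom, exf$start, exf$end, name = exf$gene_id,
                      strand = exf$strand)
  exons$transcript_id <- exf$transcript_id
  exons$gene_id <- exf$gene_id
  cds <- NULL
  if (nrow(cdf)) {
    cds <- gintervals(cdf$chrom, cdf$start, cdf$end, name = cdf$gene_id,
                      strand = cdf$strand)
    cds$transcript_id <- cdf$transcript_id
    cds$gene_id <- cdf$gene_id
  }
  annotation_set(transcripts, exons, cds)
}

#' Map annotation biotype strings to the package's three classes
#' @param x character vector of raw biotype labels.
#' @return factor-free character vector in {coding, lncRNA, other}.
#' @export
normalize_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x %in% c("protein_coding", "coding")] <- "coding"
  out[x %in% c("lncRNA", "lincRNA", "antisense", "lnc_RNA")] <- "lncRNA"
  out
}

#' Write an annotation set to GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open intervals are written
#' as 1-based inclusive GTF features with gene_id/transcript_id/gene_biotype
#' attributes.
#'
#' @param annotation `annotation_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  tx <- annotation$transcripts
  fmt_rows <- function(tab, feature) {
    bio <- tx$biotype[match(tab$transcript_id, tx$transcript_id)]
    sprintf(
      "%s\tcaptureseq\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_biotype \"%s\";",
      tab$chrom, feature, as.integer(tab$start + 1), as.integer(tab$end),
      tab$strand, tab$gene_id, tab$transcript_id, bio
    )
  }
  lines <- fmt_rows(annotation$exons, "exon")
  if (!is.null(annotation$cds) && nrow(annotation$cds)) {
    lines <- c(lines, fmt_rows(annotation$cds, "CDS"))
  }
  writeLines(lines, path)
  invisible(path)
}
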