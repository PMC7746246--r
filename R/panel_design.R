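#' Filter a GWAS SNP table at a genome-wide significance threshold
#'
#' Retains associations with p value strictly below the threshold and
#' collapses duplicated (snp_id, phenotype) pairs to a single row, so the
#' result counts unique SNP-phenotype associations.
#'
#' @param snps data.frame with columns snp_id, chrom, pos (1-based SNP
#'   position), pvalue and optionally phenotype.
#' @param p_threshold significance threshold; default genome-wide 5e-8.
#' @return filtered, deduplicated SNP table.
#' @export
filter_gwas_snps <- function(snps, p_threshold = 5e-8) {
  need <- c("snp_id", "pvalue")
  miss <- setdiff(need, names(snps))
  if (length(miss)) {
    stop("SNP table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(is.na(snps$pvalue)) || any(snps$pvalue <= 0 | snps$pvalue > 1)) {
    stop("pvalue column must contain values in (0, 1]")
  }
  out <- snps[snps$pvalue < p_threshold, , drop = FALSE]
  pheno <- if (!is.null(out$phenotype)) out$phenotype else ""
  out <- out[!duplicated(paste(out$snp_id, pheno, sep = "\r")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign SNPs to LD blocks with tiered preference
#'
#' Block sets are consulted in order of preference: a SNP is assigned to the
#' first set containing a block overlapping its position and later sets are
#' not consulted for it. Within the matching set a SNP overlapping several
#' blocks is assigned to all of them.
#'
#' @param snps SNP table with snp_id, chrom, pos (1-based position).
#' @param block_sets non-empty list of interval tables, ordered by
#'   preference.
#' @param chroms optional declared chromosome universe; SNPs on other
#'   chromosomes raise a warning and count as unassigned. Defaults to the
#'   chromosomes seen across the block sets.
#' @return list with `assignments` (data.frame snp_id, tier, block
#'   chrom/start/end) and `unassigned` (character snp_ids).
#' @export
assign_snps_to_blocks <- function(snps, block_sets, chroms = NULL) {
  if (!length(block_sets)) stop("block_sets must be a non-empty list")
  block_sets <- lapply(block_sets, validate_intervals, what = "LD blocks")
  if (is.null(chroms)) {
    chroms <- unique(unlist(lapply(block_sets, function(b) b$chrom)))
  }
  off <- !snps$chrom %in% chroms
  if (any(off)) {
    warning(sum(off), " SNP(s) on chromosomes outside the declared universe")
  }
  snp_iv <- gintervals(snps$chrom[!off], snps$pos[!off] - 1, snps$pos[!off],
                       name = snps$snp_id[!off])
  assigned <- rep(FALSE, nrow(snp_iv))
  rows <- list()
  for (tier in seq_along(block_sets)) {
    blocks <- block_sets[[tier]]
    if (!nrow(blocks) || all(assigned)) next
    pending <- which(!assigned)
    if (length(pending) * nrow(blocks) <= 1e6) {
      # dense point-in-interval test; cheap at design-table sizes
      pos <- snp_iv$start[pending]
      inb <- outer(pos, blocks$start, ">=") & outer(pos, blocks$end, "<") &
        outer(snp_iv$chrom[pending], blocks$chrom, "==")
      w <- which(inb, arr.ind = TRUE)
      if (!nrow(w)) next
      w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
      qi <- pending[w[, 1]]
      bi <- w[, 2]
    } else {
      hits <- GenomicRanges::findOverlaps(
        .as_granges(snp_iv[pending, , drop = FALSE]),
        .as_granges(blocks), ignore.strand = TRUE)
      if (!length(hits)) next
      qi <- pending[S4Vectors::queryHits(hits)]
      bi <- S4Vectors::subjectHits(hits)
    }
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = snp_iv$name[qi],
      tier = tier,
      block_chrom = blocks$chrom[bi],
      block_start = blocks$start[bi],
      block_end = blocks$end[bi],
      stringsAsFactors = FALSE
    )
    assigned[unique(qi)] <- TRUE
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), tier = integer(),
               block_chrom = character(), block_start = numeric(),
               block_end = numeric(), stringsAsFactors = FALSE)
  unassigned <- c(snp_iv$name[!assigned], snps$snp_id[off])
  list(assignments = assignments, unassigned = unassigned)
}

#' Retain LD blocks free of protein-coding transcripts
#'
#' A block is removed if it overlaps (by 1 nt or more) the genomic extent of
#' any coding transcript. By default the full transcript span (first to last
#' exon) anchors the test, since capture probes within introns still pull
#' down pre-mRNA; `anchor = "exon"` restricts to exon overlap.
#'
#' @param blocks interval table of LD blocks.
#' @param annotation `annotation_set` with biotypes assigned.
#' @param anchor `"transcript"` (default) or `"exon"`.
#' @return the retained subset of `blocks`.
#' @export
coding_free_blocks <- function(blocks, annotation,
                               anchor = c("transcript", "exon")) {
  anchor <- match.arg(anchor)
  blocks <- validate_intervals(blocks, "blocks")
  coding <- if (anchor == "transcript") {
    gene_extents(annotation, biotype = "coding")
  } else {
    biotype_exons(annotation, "coding")
  }
  if (!nrow(blocks) || !nrow(coding)) return(blocks)
  hits <- GenomicRanges::findOverlaps(.as_granges(blocks),
                                      .as_granges(coding),
                                      ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- blocks[setdiff(seq_len(nrow(blocks)), drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exons of lncRNA genes near LD blocks
#'
#' A lncRNA gene qualifies when it overlaps a block or has at least one exon
#' within `window` nt of a block; one qualifying exon pulls in all exons of
#' all the gene's transcripts (gene-level trigger).
#'
#' @param blocks interval table of LD blocks.
#' @param annotation `annotation_set`.
#' @param window proximity window in nt (default 50 kb).
#' @return exon interval table of qualifying lncRNA genes (name = gene_id).
#' @export
proximal_lncrna_exons <- function(blocks, annotation, window = 50000) {
  if (window < 0) stop("window must be non-negative")
  ex <- biotype_exons(annotation, "lncRNA")
  if (!nrow(ex) || !nrow(blocks)) return(gintervals())
  near <- within_distance(ex, blocks, max_dist = window)
  genes <- unique(near$name)
  out <- ex[ex$name %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim target regions near coding transcripts
#'
#' Removes every target base closer than `margin` nt to a coding transcript
#' (full genomic extent by default), so no synthesized probe can pull down
#' coding RNA.
#'
#' @param targets interval table.
#' @param annotation `annotation_set`.
#' @param margin safety margin in nt (default 50).
#' @param anchor `"transcript"` extent (default) or `"exon"` only.
#' @return trimmed, merged interval table.
#' @export
trim_near_coding <- function(targets, annotation, margin = 50,
                             anchor = c("transcript", "exon")) {
  anchor <- match.arg(anchor)
  excl <- if (anchor == "transcript") {
    gene_extents(annotation, biotype = "coding")
  } else {
    biotype_exons(annotation, "coding")
  }
  subtract_with_margin(targets, excl, margin = margin)
}

#' Trim target regions near RNA repeats
#'
#' Subtracts, with a safety margin, repeats of the requested classes
#' (e.g. rRNA, tRNA, 7SK, srpRNA/7SL for panel-level filtering at 50 nt, or
#' all RNA-class RepeatMasker repeats at 120 nt for probe filtering).
#'
#' @param targets interval table.
#' @param repeats interval table whose `name` column carries the repeat
#'   class.
#' @param margin safety margin in nt.
#' @param classes repeat classes to subtract; `NULL` uses all repeats.
#' @return trimmed, merged interval table.
#' @export
rna_repeat_filter <- function(targets, repeats, margin, classes = NULL) {
  repeats <- validate_intervals(repeats, "repeats")
  if (!is.null(classes)) {
    unknown <- setdiff(classes, unique(repeats$name))
    if (length(unknown)) {
      stop("unknown repeat class requested: ",
           paste(unknown, collapse = ", "))
    }
    repeats <- repeats[repeats$name %in% classes, , drop = FALSE]
  }
  subtract_with_margin(targets, repeats, margin = margin)
}

#' Classify genes for full or partial probing by predicted read share
#'
#' Genes predicted to dominate the captured library are probed only in part.
#' A gene is classed `partial` when its predicted share of captured reads in
#' neuronal cells is at least `neuronal_thresh` (0.5% or more) or its
#' maximum predicted share across reference (ENCODE-like) contexts strictly
#' exceeds `encode_thresh` (over 5%); all other genes are `full`.
#'
#' @param expression_shares data.frame with gene_id, a `neuronal` column,
#'   and one or more further numeric columns treated as reference contexts.
#' @param neuronal_thresh inclusive threshold on the neuronal share.
#' @param encode_thresh exclusive threshold on the max reference share.
#' @return data.frame gene_id, class, share_neuronal, share_encode_max.
#' @export
classify_tf_probing <- function(expression_shares, neuronal_thresh = 0.005,
                                encode_thresh = 0.05) {
  if (is.null(expression_shares$gene_id) ||
      is.null(expression_shares$neuronal)) {
    stop("expression_shares requires gene_id and neuronal columns")
  }
  ctx_cols <- setdiff(names(expression_shares), c("gene_id", "neuronal"))
  vals <- as.matrix(expression_shares[, c("neuronal", ctx_cols),
                                      drop = FALSE])
  if (any(is.na(vals)) || any(vals < 0 | vals > 1)) {
    stop("expression shares must lie in [0, 1]")
  }
  encode_max <- if (length(ctx_cols)) {
    apply(expression_shares[, ctx_cols, drop = FALSE], 1, max)
  } else {
    rep(0, nrow(expression_shares))
  }
  partial <- expression_shares$neuronal >= neuronal_thresh |
    encode_max > encode_thresh
  data.frame(
    gene_id = expression_shares$gene_id,
    class = ifelse(partial, "partial", "full"),
    share_neuronal = expression_shares$neuronal,
    share_encode_max = encode_max,
    stringsAsFactors = FALSE
  )
}

#' Partial-probing target regions of one transcript
#'
#' For mono-exonic transcripts the last `cds_tail` nt of the CDS are
#' targeted (the whole CDS when shorter). For multi-exonic transcripts two
#' regions are targeted: the last `penult_len` nt of the penultimate exon
#' and the first `final_head` nt of the final exon, each clipped to the exon
#' when it is shorter. "First" and "last" follow transcript orientation: on
#' the minus strand the last N nt of a feature occupy its lowest genomic
#' coordinates.
#'
#' @param annotation `annotation_set`.
#' @param transcript_id transcript to probe.
#' @param cds_tail,penult_len,final_head region sizes in nt.
#' @return interval table of one (mono-exonic) or two regions.
#' @export
partial_probe_targets <- function(annotation, transcript_id, cds_tail = 200,
                                  penult_len = 100, final_head = 150) {
  ex <- transcript_exons(annotation, transcript_id)  # 5' -> 3' order
  strand <- ex$strand[1]
  take_last <- function(iv, n) {
    len <- iv$end - iv$start
    n <- min(n, len)
    if (strand == "-") {
      gintervals(iv$chrom, iv$start, iv$start + n, name = iv$name,
                 strand = strand)
    } else {
      gintervals(iv$chrom, iv$end - n, iv$end, name = iv$name,
                 strand = strand)
    }
  }
  take_first <- function(iv, n) {
    len <- iv$end - iv$start
    n <- min(n, len)
    if (strand == "-") {
      gintervals(iv$chrom, iv$end - n, iv$end, name = iv$name,
                 strand = strand)
    } else {
      gintervals(iv$chrom, iv$start, iv$start + n, name = iv$name,
                 strand = strand)
    }
  }
  if (nrow(ex) == 1) {
    cds <- annotation$cds
    cds <- if (!is.null(cds)) {
      cds[cds$transcript_id == transcript_id, , drop = FALSE]
    } else {
      NULL
    }
    if (is.null(cds) || !nrow(cds)) {
      stop("mono-exonic transcript without CDS: ", transcript_id)
    }
    cds_iv <- merge_intervals(cds)
    cds_iv$name <- ex$name[1]
    return(take_last(cds_iv[1, , drop = FALSE], cds_tail))
  }
  penult <- ex[nrow(ex) - 1, , drop = FALSE]
  final <- ex[nrow(ex), , drop = FALSE]
  out <- rbind(take_last(penult, penult_len), take_first(final, final_head))
  sort_intervals(validate_intervals(out))
}

#' Design one repeat-free intronic control region per gene
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' unioned per gene. Candidate pieces are the introns after trimming
#' `ann_margin` nt around annotation anchors, `repeat_margin` nt around
#' repeats, and `est_margin` nt around ESTs. Pieces longer than `min_piece`
#' (strictly) survive; the longest per gene (ties to the leftmost) supplies
#' the control: its centered `control_len` window, offset
#' `floor((len - control_len) / 2)` from the piece start. Genes with no
#' surviving piece are omitted.
#'
#' By default the annotation trim is anchored on exons of all genes
#' (including the host gene); `ann_anchor = "transcript"` trims around full
#' transcript extents of all other genes instead.
#'
#' @param genes character vector of gene_ids to design controls for.
#' @param annotation `annotation_set`.
#' @param repeats,ests interval tables (may be empty).
#' @param ann_margin,repeat_margin,est_margin trim margins in nt.
#' @param min_piece minimum surviving piece length in nt (strict).
#' @param control_len emitted control region length in nt.
#' @param ann_anchor `"exon"` (default) or `"transcript"`.
#' @return interval table, one region per surviving gene (name = gene_id).
#' @export
design_intronic_controls <- function(genes, annotation, repeats, ests,
                                     ann_margin = 500, repeat_margin = 100,
                                     est_margin = 50, min_piece = 200,
                                     control_len = 200,
                                     ann_anchor = c("exon", "transcript")) {
  ann_anchor <- match.arg(ann_anchor)
  if (control_len > min_piece) {
    stop("control_len must not exceed min_piece")
  }
  repeats <- validate_intervals(repeats, "repeats")
  ests <- validate_intervals(ests, "ests")
  all_exons <- gintervals(annotation$exons$chrom, annotation$exons$start,
                          annotation$exons$end)
  # dilate each exclusion track by its margin once, then take the union;
  # subtracting the union equals the three sequential margin-trims
  pad_iv <- function(iv, margin) {
    if (!nrow(iv)) return(gintervals())
    gintervals(iv$chrom, pmax(0, iv$start - margin), iv$end + margin)
  }
  excl_shared <- if (ann_anchor == "exon") {
    merge_intervals(rbind(pad_iv(all_exons, ann_margin),
                          pad_iv(repeats, repeat_margin),
                          pad_iv(ests, est_margin)))
  } else {
    merge_intervals(rbind(pad_iv(repeats, repeat_margin),
                          pad_iv(ests, est_margin)))
  }
  out <- list()
  for (g in genes) {
    tx_ids <- annotation$transcripts$transcript_id[
      annotation$transcripts$gene_id == g]
    introns <- list()
    for (tx in tx_ids) {
      ex <- annotation$exons[annotation$exons$transcript_id == tx, ,
                             drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) < 2) next
      s <- ex$end[-nrow(ex)]
      e <- ex$start[-1]
      keep <- s < e
      if (any(keep)) {
        introns[[length(introns) + 1]] <-
          gintervals(ex$chrom[1], s[keep], e[keep])
      }
    }
    if (!length(introns)) next
    pieces <- merge_intervals(do.call(rbind, introns))
    excl <- if (ann_anchor == "exon") {
      excl_shared
    } else {
      ge <- gene_extents(annotation)
      merge_intervals(rbind(excl_shared,
                            pad_iv(ge[ge$name != g, , drop = FALSE],
                                   ann_margin)))
    }
    chr <- pieces$chrom[1]
    ec <- excl[excl$chrom == chr, , drop = FALSE]
    dd <- .diff_sorted(pieces$start, pieces$end, ec$start, ec$end)
    if (!length(dd$start)) next
    pieces <- gintervals(chr, dd$start, dd$end)
    lens <- interval_length(pieces)
    pieces <- pieces[lens > min_piece, , drop = FALSE]
    if (!nrow(pieces)) next
    lens <- interval_length(pieces)
    pieces <- sort_intervals(pieces)
    lens <- interval_length(pieces)
    best <- pieces[which.max(lens), , drop = FALSE]  # which.max ties leftmost
    off <- floor((interval_length(best) - control_len) / 2)
    out[[length(out) + 1]] <- gintervals(
      best$chrom, best$start + off, best$start + off + control_len, name = g)
  }
  if (!length(out)) return(gintervals())
  sort_intervals(do.call(rbind, out))
}

#' Prepare spike-in target regions for probe design
#'
#' Regions on spike-in sequences are dropped when shorter than `min_len` nt
#' and short regions (between `min_len` and `pad_to - 1` nt) are padded out
#' symmetrically. A region whose padding deficit is even, or that must be
#' padded against a sequence boundary, is padded to exactly `pad_to` nt; an
#' interior region with an odd deficit is padded one nt further (to
#' `pad_to + 1`) so the two flanks stay equal. Padding never crosses
#' sequence bounds: any deficit is shifted to the other side. Regions at
#' least `pad_to` nt long pass unchanged.
#'
#' @param regions interval table on spike-in sequences.
#' @param seq_lengths named vector of spike-in sequence lengths (nt).
#' @param min_len minimum region length retained.
#' @param pad_to target padded length.
#' @return interval table of retained, padded regions.
#' @export
prepare_spikein_targets <- function(regions, seq_lengths, min_len = 30,
                                    pad_to = 50) {
  regions <- validate_intervals(regions, "spike-in regions")
  if (!nrow(regions)) return(regions)
  unknown <- setdiff(unique(regions$chrom), names(seq_lengths))
  if (length(unknown)) {
    stop("region on unknown spike-in sequence: ", unknown[1])
  }
  L <- as.numeric(seq_lengths[regions$chrom])
  if (any(regions$end > L)) {
    stop("region outside spike-in sequence bounds: record ",
         which(regions$end > L)[1])
  }
  len <- regions$end - regions$start
  keep <- len >= min_len
  regions <- regions[keep, , drop = FALSE]
  L <- L[keep]
  len <- len[keep]
  if (!nrow(regions)) return(validate_intervals(regions))
  for (i in seq_len(nrow(regions))) {
    if (len[i] >= pad_to) next
    deficit <- pad_to - len[i]
    at_boundary <- regions$start[i] - ceiling(deficit / 2) < 0 ||
      regions$end[i] + ceiling(deficit / 2) > L[i]
    if (deficit %% 2 == 1 && !at_boundary) deficit <- deficit + 1
    left <- floor(deficit / 2)
    right <- deficit - left
    s <- regions$start[i] - left
    e <- regions$end[i] + right
    if (s < 0) { e <- e - s; s <- 0 }
    if (e > L[i]) { s <- s - (e - L[i]); e <- L[i] }
    if (s < 0) s <- 0  # sequence shorter than pad_to: keep whole sequence
    regions$start[i] <- s
    regions$end[i] <- e
  }
  validate_intervals(regions)
}

#' Assemble a named target panel from region groups
#'
#' Merges all region groups into a disjoint panel, attributes each panel
#' region to overlapping genes, and accounts for bases contributed per rule.
#'
#' @param name panel name.
#' @param region_groups named list of interval tables (one per design rule).
#' @param annotation `annotation_set` used for gene attribution.
#' @param extra_log optional named list merged into the design log.
#' @return object of class `target_panel`: list with name, targets (merged
#'   interval table), gene_attribution (data.frame region/gene_id),
#'   design_log and total_bases.
#' @export
assemble_panel <- function(name, region_groups, annotation = NULL,
                           extra_log = list()) {
  if (!length(region_groups)) stop("no region groups supplied")
  if (is.null(names(region_groups)) || any(!nzchar(names(region_groups)))) {
    stop("region_groups must be a named list")
  }
  region_groups <- lapply(region_groups, validate_intervals)
  nonempty <- region_groups[vapply(region_groups, nrow, 0L) > 0]
  if (!length(nonempty)) stop("empty final panel for design '", name, "'")
  # drop group-specific extra columns before row-binding
  core <- lapply(nonempty, function(g) {
    g[, c("chrom", "start", "end", "name", "strand"), drop = FALSE]
  })
  targets <- merge_intervals(do.call(rbind, core))
  if (!nrow(targets)) stop("empty final panel for design '", name, "'")
  total_bases <- sum(interval_length(targets))
  design_log <- c(
    lapply(region_groups, function(g) {
      list(n_regions = nrow(g),
           n_bases = if (nrow(g)) sum(interval_length(merge_intervals(g)))
                     else 0)
    }),
    extra_log
  )
  gene_attribution <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    gene_id = character(), stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    ge <- gene_extents(annotation)
    if (nrow(ge)) {
      hits <- GenomicRanges::findOverlaps(.as_granges(targets),
                                          .as_granges(ge),
                                          ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(hits)
      gene_attribution <- data.frame(
        chrom = targets$chrom[qi],
        start = targets$start[qi],
        end = targets$end[qi],
        gene_id = ge$name[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(name = name, targets = targets,
         gene_attribution = gene_attribution,
         design_log = design_log, total_bases = total_bases),
    class = "target_panel"
  )
}

#' @export
print.target_panel <- function(x, ...) {
  cat("target_panel '", x$name, "': ", nrow(x$targets), " regions, ",
      format(x$total_bases, big.mark = ","), " nt, ",
      length(unique(x$gene_attribution$gene_id)), " attributed genes\n",
      sep = "")
  invisible(x)
}

#' Genes attributed to a panel
#' @param panel `target_panel`.
#' @return character vector of gene_ids overlapping the panel.
#' @export
panel_genes <- function(panel) {
  sort(unique(panel$gene_attribution$gene_id))
}

#' End-to-end GWAS/lncRNA (NG-style) panel design
#'
#' Runs the complete intergenic-GWAS design: filter SNPs at genome-wide
#' significance, assign them to LD blocks by tiered preference, keep blocks
#' free of protein-coding transcripts, add all exons of lncRNA genes
#' overlapping or within `lncrna_window` of a retained block, trim every
#' target within `coding_margin` nt of a coding transcript, and remove
#' regions within `repeat_margin` nt of highly expressed RNA repeats.
#' Optional intronic control regions are added per gene.
#'
#' @param snps GWAS SNP table.
#' @param block_sets list of LD-block interval tables in preference order.
#' @param annotation `annotation_set`.
#' @param repeats repeat interval table (name = class).
#' @param ests EST interval table (used only for intronic controls).
#' @param p_threshold GWAS significance threshold.
#' @param lncrna_window lncRNA proximity window (nt).
#' @param coding_margin coding-transcript trim margin (nt).
#' @param repeat_classes repeat classes treated as highly expressed RNA.
#' @param repeat_margin repeat trim margin (nt).
#' @param control_genes genes receiving an intronic control region.
#' @param control_len,control_min_piece intronic control sizing (nt).
#' @return `target_panel`.
#' @export
design_ng_panel <- function(snps, block_sets, annotation, repeats,
                            ests = gintervals(),
                            p_threshold = 5e-8, lncrna_window = 50000,
                            coding_margin = 50,
                            repeat_classes = c("rRNA", "tRNA", "7SK",
                                               "srpRNA"),
                            repeat_margin = 50,
                            control_genes = character(),
                            control_len = 500, control_min_piece = 500) {
  snps <- filter_gwas_snps(snps, p_threshold)
  asg <- assign_snps_to_blocks(snps, block_sets)
  blk <- unique(asg$assignments[, c("block_chrom", "block_start",
                                    "block_end")])
  blocks <- gintervals(blk$block_chrom, blk$block_start, blk$block_end)
  blocks <- coding_free_blocks(blocks, annotation)
  lnc <- proximal_lncrna_exons(blocks, annotation, window = lncrna_window)
  raw <- list(ld_blocks = blocks, lncrna_exons = lnc)
  raw <- lapply(raw, function(g) {
    g <- trim_near_coding(g, annotation, margin = coding_margin)
    repeat_present <- intersect(repeat_classes, unique(repeats$name))
    if (length(repeat_present)) {
      g <- rna_repeat_filter(g, repeats, margin = repeat_margin,
                             classes = repeat_present)
    }
    g
  })
  groups <- raw
  if (length(control_genes)) {
    groups$intronic_controls <- design_intronic_controls(
      control_genes, annotation, repeats, ests,
      min_piece = control_min_piece, control_len = control_len)
  }
  assemble_panel("NG", groups, annotation,
                 extra_log = list(
                   snps_retained = nrow(snps),
                   snps_unassigned = length(asg$unassigned),
                   blocks_coding_free = nrow(blocks)))
}

#' End-to-end transcription-factor (TF-style) panel design
#'
#' Targets all exons of genes classed for full probing, partial-probing
#' regions (terminal-exon windows or CDS tails) of highly expressed genes,
#' and one intronic control per target gene. All probe regions are trimmed
#' against non-targeted loci (`nontarget_margin`) and RNA-class repeats
#' (`repeat_margin`). Spike-in regions are filtered and padded for probe
#' design compatibility.
#'
#' @param target_genes gene_ids to probe.
#' @param annotation `annotation_set`.
#' @param expression_shares table for [classify_tf_probing()], or `NULL` to
#'   probe every gene in full.
#' @param repeats repeat interval table (name = class).
#' @param ests EST interval table.
#' @param spike_regions,spike_seq_lengths optional spike-in regions and
#'   sequence lengths for [prepare_spikein_targets()].
#' @param nontarget_margin trim margin around non-targeted loci (nt).
#' @param repeat_margin trim margin around RNA repeats (nt).
#' @param intronic_controls logical; design intronic controls.
#' @return `target_panel`.
#' @export
design_tf_panel <- function(target_genes, annotation,
                            expression_shares = NULL,
                            repeats = gintervals(), ests = gintervals(),
                            spike_regions = NULL, spike_seq_lengths = NULL,
                            nontarget_margin = 150, repeat_margin = 120,
                            intronic_controls = TRUE) {
  tx <- annotation$transcripts
  classes <- if (!is.null(expression_shares)) {
    classify_tf_probing(expression_shares)
  } else {
    data.frame(gene_id = target_genes, class = "full",
               stringsAsFactors = FALSE)
  }
  cls <- classes$class[match(target_genes, classes$gene_id)]
  cls[is.na(cls)] <- "full"
  full_genes <- target_genes[cls == "full"]
  partial_genes <- target_genes[cls == "partial"]
  full_ex <- annotation$exons[annotation$exons$gene_id %in% full_genes, ,
                              drop = FALSE]
  full_regions <- if (nrow(full_ex)) {
    gintervals(full_ex$chrom, full_ex$start, full_ex$end,
               name = full_ex$gene_id, strand = full_ex$strand)
  } else {
    gintervals()
  }
  partial_regions <- list()
  for (g in partial_genes) {
    tx_ids <- tx$transcript_id[tx$gene_id == g & tx$biotype == "coding"]
    for (t in tx_ids) {
      partial_regions[[length(partial_regions) + 1]] <-
        partial_probe_targets(annotation, t)
    }
  }
  partial_regions <- if (length(partial_regions)) {
    do.call(rbind, partial_regions)
  } else {
    gintervals()
  }
  # non-targeted loci: full extents of genes not on the panel
  ge <- gene_extents(annotation)
  nontarget <- ge[!ge$name %in% target_genes, , drop = FALSE]
  trim <- function(g) {
    g <- subtract_with_margin(g, nontarget, margin = nontarget_margin)
    if (nrow(repeats)) {
      g <- rna_repeat_filter(g, repeats, margin = repeat_margin)
    }
    g
  }
  groups <- list(full_probing = trim(full_regions),
                 partial_probing = trim(partial_regions))
  if (intronic_controls) {
    groups$intronic_controls <- design_intronic_controls(
      target_genes, annotation, repeats, ests)
  }
  if (!is.null(spike_regions)) {
    groups$spikein_targets <- prepare_spikein_targets(spike_regions,
                                                      spike_seq_lengths)
  }
  assemble_panel("TF", groups, annotation,
                 extra_log = list(
                   n_full = length(full_genes),
                   n_partial = length(partial_genes)))
}
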