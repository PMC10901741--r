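# Interval algebra: validation, merging, gene flattening and priority
# fragmentation. All coordinates live in GRanges (1-based closed); BED-style
# 0-based half-open coordinates are converted at the I/O boundary only.

#' Build a GRanges from BED-style coordinates
#'
#' Convenience constructor used throughout the package and its tests:
#' coordinates are 0-based half-open (BED convention) and converted to the
#' internal 1-based closed representation.
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand strand vector ("+", "-" or "*").
#' @param ... further metadata columns.
#' @return a `GRanges`.
#' @examples
#' gi("chr1", 10, 20)  # covers bases 10..19 (0-based)
#' @export
gi <- function(chrom, start, end, strand = "*", ...) {
  if (any(start < 0)) stop_input("negative start coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop_input("empty or inverted interval at record %d (start %s >= end %s)",
               bad[1], start[bad[1]], end[bad[1]])
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand, ...)
}

#' Validate a set of genomic intervals
#'
#' Rejects zero-width or inverted intervals, naming the first offending
#' record.
#'
#' @param gr a `GRanges`.
#' @param stranded if TRUE, additionally require every strand to be "+" or
#'   "-".
#' @return `gr`, invisibly.
#' @export
validate_intervals <- function(gr, stranded = FALSE) {
  if (!is(gr, "GRanges")) stop_input("expected a GRanges")
  bad <- which(GenomicRanges::width(gr) < 1L)
  if (length(bad))
    stop_input("empty interval at record %d (%s:%d-%d)", bad[1],
               as.character(GenomicRanges::seqnames(gr)[bad[1]]),
               GenomicRanges::start(gr)[bad[1]], GenomicRanges::end(gr)[bad[1]])
  if (stranded) {
    s <- as.character(GenomicRanges::strand(gr))
    bad <- which(!s %in% c("+", "-"))
    if (length(bad)) stop_input("unstranded interval at record %d", bad[1])
  }
  invisible(gr)
}

#' Merge overlapping or touching intervals
#'
#' Union of the input bases: returned intervals are sorted, pairwise
#' disjoint, and touching intervals are merged (zero minimum gap).
#'
#' @param gr a `GRanges`.
#' @param strand_aware merge only within identical strand (default TRUE).
#' @return a reduced `GRanges`.
#' @export
reduce_intervals <- function(gr, strand_aware = TRUE) {
  validate_intervals(gr)
  out <- GenomicRanges::reduce(gr, ignore.strand = !strand_aware)
  sort(out, ignore.strand = TRUE)
}

#' Genomic footprint of a gene
#'
#' The span from the first to the last exon base, used as the search space
#' for within-gene queries.
#'
#' @param exons `GRanges` of the gene's exons (same chrom and strand).
#' @return a length-1 `GRanges`.
#' @export
flatten_gene <- function(exons) {
  if (length(exons) == 0) stop_input("gene has no exons")
  validate_intervals(exons)
  if (length(unique(as.character(GenomicRanges::seqnames(exons)))) != 1 ||
      length(unique(as.character(GenomicRanges::strand(exons)))) != 1)
    stop_input("exons of one gene must share chromosome and strand")
  range(exons)
}

#' Footprints of all genes in an annotated genome
#'
#' @param genome an [AnnotatedGenome].
#' @return `GRanges` with a `gene_id` metadata column, one range per gene.
#' @export
flatten_genes <- function(genome) {
  genome$genes
}

#' Fragment a gene footprint by feature priority
#'
#' Every base of the gene footprint is labeled by the highest-priority
#' feature covering it; uncovered bases become `intron` fragments. Within a
#' label, features earlier in genomic order win overlapping bases. This is
#' the counting-reference construction used for fragment-level binding
#' quantification (exons prioritized over repeats and peaks, repeats over
#' introns).
#'
#' @param gene_id gene identifier (used for intron fragments' source).
#' @param footprint length-1 `GRanges`, the gene footprint.
#' @param features named list of `GRanges`, e.g.
#'   `list(exon = ..., repeat. = ..., peak = ...)`; each element may carry a
#'   `source_id` metadata column (defaults to `label_i`).
#' @param priority character vector, highest priority first; labels not in
#'   `names(features)` (other than "intron") are rejected. "intron" need not
#'   be listed; it always has the lowest priority.
#' @return `GRanges` of disjoint fragments covering the footprint, with
#'   metadata columns `label`, `source_id`, `host_gene`.
#' @export
fragment_by_priority <- function(gene_id, footprint, features,
                                 priority = c("exon", "repeat", "peak")) {
  stopifnot(length(footprint) == 1)
  known <- union(c("exon", "repeat", "peak", "intron"), names(features))
  bad <- setdiff(priority, known)
  if (length(bad)) stop_input("unknown label in priority: %s", bad[1])
  missing_ <- setdiff(names(features), c(priority, "intron"))
  if (length(missing_))
    stop_input("feature label '%s' absent from the priority order", missing_[1])
  priority <- setdiff(priority, "intron")

  # plain integer sweep: collect every candidate segment with its rank
  # ((priority level, genomic order) pairs), then label each elementary
  # segment between breakpoints by the lowest-ranked feature covering it
  fp_s <- GenomicRanges::start(footprint); fp_e <- GenomicRanges::end(footprint)
  seg_s <- integer(0); seg_e <- integer(0); seg_rank <- integer(0)
  seg_lab <- character(0); seg_id <- character(0)
  rank <- 0L
  for (lab in priority) {
    fs <- features[[lab]]
    if (is.null(fs) || length(fs) == 0) next
    ids <- if (!is.null(mcols(fs)$source_id)) as.character(mcols(fs)$source_id)
           else paste0(lab, "_", seq_along(fs))
    o <- order(GenomicRanges::start(fs), GenomicRanges::end(fs))
    s <- pmax(GenomicRanges::start(fs)[o], fp_s)
    e <- pmin(GenomicRanges::end(fs)[o], fp_e)
    keep <- s <= e
    n <- sum(keep)
    seg_s <- c(seg_s, s[keep]); seg_e <- c(seg_e, e[keep])
    seg_rank <- c(seg_rank, rank + seq_len(n))
    seg_lab <- c(seg_lab, rep(lab, n)); seg_id <- c(seg_id, ids[o][keep])
    rank <- rank + n
  }
  bp <- sort(unique(c(fp_s, fp_e + 1L, seg_s, seg_e + 1L)))
  bp <- bp[bp >= fp_s & bp <= fp_e + 1L]
  el_s <- bp[-length(bp)]; el_e <- bp[-1] - 1L
  el_lab <- rep("intron", length(el_s)); el_id <- rep(gene_id, length(el_s))
  if (length(seg_s)) {
    best <- rep(NA_integer_, length(el_s))
    for (k in order(seg_rank, decreasing = TRUE)) {
      cov <- el_s >= seg_s[k] & el_e <= seg_e[k]
      best[cov] <- k
    }
    hit <- !is.na(best)
    el_lab[hit] <- seg_lab[best[hit]]
    el_id[hit] <- seg_id[best[hit]]
  }
  # merge adjacent elementary segments with the same label and source
  grp <- cumsum(c(TRUE, el_lab[-1] != el_lab[-length(el_lab)] |
                    el_id[-1] != el_id[-length(el_id)]))
  out_s <- tapply(el_s, grp, min); out_e <- tapply(el_e, grp, max)
  first <- !duplicated(grp)
  out <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(footprint)),
    IRanges::IRanges(as.integer(out_s), as.integer(out_e)),
    strand = as.character(GenomicRanges::strand(footprint)),
    label = el_lab[first], source_id = el_id[first], host_gene = gene_id)
  out
}

#' Fragment every gene of a genome by feature priority
#'
#' @param genome an [AnnotatedGenome].
#' @param peaks optional `GRanges` of peaks (with `peak_id` in mcols).
#' @param priority label order, highest first; allowed labels are "exon",
#'   "repeat", "peak".
#' @return `GRanges` of labeled fragments over all genes.
#' @export
fragment_genome <- function(genome, peaks = NULL,
                            priority = c("exon", "repeat", "peak")) {
  res <- lapply(seq_along(genome$genes), function(i) {
    g <- genome$genes[i]
    gid <- mcols(g)$gene_id
    ex <- genome$exons[mcols(genome$exons)$gene_id == gid]
    mcols(ex)$source_id <- if (!is.null(mcols(ex)$exon_id))
      mcols(ex)$exon_id else paste0(gid, ".E", seq_along(ex))
    feats <- list(exon = ex)
    if ("repeat" %in% priority &&
        !is.null(genome$repeats) && length(genome$repeats)) {
      rp <- IRanges::subsetByOverlaps(genome$repeats, g, ignore.strand = TRUE)
      mcols(rp)$source_id <- mcols(rp)$family
      feats[["repeat"]] <- rp
    }
    if ("peak" %in% priority && !is.null(peaks) && length(peaks)) {
      pk <- IRanges::subsetByOverlaps(peaks, g, ignore.strand = TRUE)
      mcols(pk)$source_id <- mcols(pk)$peak_id %||% paste0("peak_", seq_along(pk))
      feats[["peak"]] <- pk
    }
    fragment_by_priority(gid, g, feats, intersect(priority, c(names(feats))))
  })
  do.call(c, res)
}
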