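# Long-read 3'-end alternative polyadenylation: collapse single-base read
# ends into putative polyadenylation regions and call differential polyA
# isoform usage per gene.

#' Read 3'-end coordinates from BED6 or TSV
#'
#' BED6 with the sample in the name field, or TSV with columns chrom, pos
#' (1-based), strand, sample.
#'
#' @param path input file.
#' @param format "bed" or "tsv" (default: by extension).
#' @return data.frame (chrom, pos, strand, sample), pos 1-based.
#' @export
read_read_ends <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.bed$", path)) "bed" else "tsv")
  if (format == "bed") {
    gr <- read_bed6(path)
    if (any(GenomicRanges::width(gr) != 1))
      stop_input("read ends must be single-base intervals")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               sample = mcols(gr)$name)
  } else {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "integer", "character",
                                    "character"))
    stopifnot(all(c("chrom", "pos", "strand", "sample") %in% colnames(df)))
    df
  }
}

ends_to_granges <- function(ends) {
  if (any(ends$pos < 1)) stop_input("read-end position below 1")
  GenomicRanges::GRanges(ends$chrom, IRanges::IRanges(ends$pos, ends$pos),
                         strand = ends$strand, sample = ends$sample)
}

#' Collapse read ends into putative polyadenylation regions
#'
#' Every end is padded by `pad` nt on both sides; overlapping or touching
#' padded intervals are merged per chromosome and strand. Every input end
#' lies inside exactly one region.
#'
#' @param ends data.frame (chrom, pos, strand, sample) or single-base
#'   `GRanges`.
#' @param pad padding in nt (default 50).
#' @return `GRanges` of disjoint regions with `region_id`.
#' @export
collapse_read_ends <- function(ends, pad = 50L) {
  stopifnot(pad >= 0)
  gr <- if (is(ends, "GRanges")) ends else ends_to_granges(ends)
  pos <- GenomicRanges::start(gr)
  padded <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(pmax(1L, pos - as.integer(pad)), pos + as.integer(pad)),
    strand = GenomicRanges::strand(gr))
  regions <- GenomicRanges::reduce(padded)
  regions <- sort(regions, ignore.strand = TRUE)
  mcols(regions)$region_id <- sprintf("pa_%06d", seq_along(regions))
  regions
}

#' Count read ends per region and condition
#'
#' @param regions `GRanges` from [collapse_read_ends()].
#' @param ends data.frame (chrom, pos, strand, sample).
#' @param design a [make_design()] object mapping sample -> condition.
#' @return `regions` with `n_control` and `n_treatment` metadata; errors if
#'   any end falls outside all regions (cannot happen for regions collapsed
#'   from the same ends).
#' @export
count_ends <- function(regions, ends, design) {
  gr <- ends_to_granges(ends)
  cond <- setNames(design$condition, design$sample)
  unknown <- setdiff(ends$sample, design$sample)
  if (length(unknown)) stop_input("sample '%s' missing from design", unknown[1])
  hits <- GenomicRanges::findOverlaps(gr, regions, ignore.strand = FALSE)
  if (length(unique(queryHits(hits))) != length(gr))
    stop_input("internal consistency error: read end outside all regions")
  cc <- cond[ends$sample[queryHits(hits)]]
  idx <- subjectHits(hits)
  mcols(regions)$n_control <-
    tabulate(idx[cc == "control"], nbins = length(regions))
  mcols(regions)$n_treatment <-
    tabulate(idx[cc == "treatment"], nbins = length(regions))
  regions
}

#' Assign polyA regions to host genes
#'
#' Region midpoint containment in a gene footprint on the same strand;
#' unassigned regions are dropped.
#'
#' @param regions counted region `GRanges`.
#' @param genome an [AnnotatedGenome].
#' @return regions with a `host_gene` column, restricted to assigned ones.
#' @export
assign_polya_regions <- function(regions, genome) {
  mid <- GenomicRanges::resize(regions, width = 1L, fix = "center")
  hits <- GenomicRanges::findOverlaps(mid, genome$genes, type = "within",
                                      ignore.strand = FALSE, select = "first")
  keep <- !is.na(hits)
  out <- regions[keep]
  mcols(out)$host_gene <- mcols(genome$genes)$gene_id[hits[keep]]
  out
}

#' Differential polyadenylation calls
#'
#' Per gene and condition, each region's fraction of the gene's reads; a
#' gene is called differentially polyadenylated iff its total reads (both
#' conditions) reach `min_reads` and at least one region's fraction shifts
#' by at least `min_shift` between conditions. Genes with zero reads in
#' one condition are not callable (reported with reason).
#'
#' @param regions gene-assigned, counted region `GRanges`.
#' @param min_reads minimum reads per gene, both conditions summed
#'   (default 20).
#' @param min_shift minimum isoform-fraction shift (default 0.20).
#' @return list(calls = per-gene data.frame (gene_id, n_reads, max_shift,
#'   called, reason), fractions = per-region data.frame).
#' @export
differential_polya <- function(regions, min_reads = 20, min_shift = 0.20) {
  df <- data.frame(gene_id = mcols(regions)$host_gene,
                   region_id = mcols(regions)$region_id,
                   n_control = mcols(regions)$n_control,
                   n_treatment = mcols(regions)$n_treatment)
  genes <- unique(df$gene_id)
  fr <- do.call(rbind, lapply(genes, function(g) {
    d <- df[df$gene_id == g, , drop = FALSE]
    tc <- sum(d$n_control); tt <- sum(d$n_treatment)
    d$frac_control <- if (tc > 0) d$n_control / tc else NA_real_
    d$frac_treatment <- if (tt > 0) d$n_treatment / tt else NA_real_
    d$shift <- abs(d$frac_treatment - d$frac_control)
    d
  }))
  calls <- do.call(rbind, lapply(genes, function(g) {
    d <- fr[fr$gene_id == g, , drop = FALSE]
    n <- sum(d$n_control) + sum(d$n_treatment)
    if (sum(d$n_control) == 0 || sum(d$n_treatment) == 0)
      return(data.frame(gene_id = g, n_reads = n, max_shift = NA_real_,
                        called = FALSE, reason = "zero reads in a condition"))
    ms <- max(d$shift)
    ok_n <- n >= min_reads
    ok_s <- ms >= min_shift
    data.frame(gene_id = g, n_reads = n, max_shift = ms,
               called = ok_n && ok_s,
               reason = if (ok_n && ok_s) "called"
                        else if (!ok_n) "below read support" else "below shift")
  }))
  list(calls = calls, fractions = fr)
}

#' End-to-end APA call from read ends
#'
#' @param ends data.frame (chrom, pos, strand, sample).
#' @param genome an [AnnotatedGenome].
#' @param design a [make_design()] object.
#' @param pad,min_reads,min_shift see the stage functions.
#' @return list(regions, calls, fractions).
#' @export
apa_call <- function(ends, genome, design, pad = 50L, min_reads = 20,
                     min_shift = 0.20) {
  regions <- collapse_read_ends(ends, pad)
  regions <- count_ends(regions, ends, design)
  regions <- assign_polya_regions(regions, genome)
  res <- differential_polya(regions, min_reads, min_shift)
  c(list(regions = regions), res)
}
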