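# The exonization / early-termination pipeline: differential usage of
# intronic peaks within their host genes, reference-peak selection, gene
# splitting into pre-/post-peak exon sets, aggregated differential
# expression of the two sides, and classification into
# upregulated-peak vs control genes.

#' Differential usage scan over intronic peaks
#'
#' Each intronic peak is tested for a change in its share of the host
#' gene's total signal (exonic + intronic-peak counts) between conditions.
#'
#' @param peak_counts intronic-peak x sample count matrix (rownames =
#'   peak ids).
#' @param exon_counts exon x sample count matrix (rownames = exon ids).
#' @param peak_gene named vector peak id -> host gene.
#' @param exon_gene named vector exon id -> gene.
#' @param design a [make_design()] object.
#' @param sf size factors (default from combined counts).
#' @return data.frame from [relative_usage_test()] plus a `gene_id` column;
#'   peaks without a host gene are skipped with a warning.
#' @export
peak_usage_scan <- function(peak_counts, exon_counts, peak_gene, exon_gene,
                            design, sf = NULL) {
  peak_counts <- as.matrix(peak_counts); exon_counts <- as.matrix(exon_counts)
  hosted <- rownames(peak_counts)[!is.na(peak_gene[rownames(peak_counts)])]
  skipped <- setdiff(rownames(peak_counts), hosted)
  if (length(skipped))
    warning(sprintf("%d peak(s) without host gene skipped", length(skipped)))
  peak_counts <- peak_counts[hosted, , drop = FALSE]
  genes <- unique(peak_gene[hosted])
  samples <- design$sample
  gene_tot <- matrix(0, nrow = length(genes), ncol = length(samples),
                     dimnames = list(genes, samples))
  for (g in genes) {
    ex <- names(exon_gene)[exon_gene == g]
    ex <- intersect(ex, rownames(exon_counts))
    pk <- hosted[peak_gene[hosted] == g]
    gene_tot[g, ] <-
      colSums(exon_counts[ex, samples, drop = FALSE]) +
      colSums(peak_counts[pk, samples, drop = FALSE])
  }
  if (is.null(sf))
    sf <- size_factors(rbind(exon_counts[, samples, drop = FALSE],
                             peak_counts[, samples, drop = FALSE]))
  tot <- gene_tot[peak_gene[hosted], , drop = FALSE]
  rownames(tot) <- hosted
  res <- relative_usage_test(peak_counts[, samples, drop = FALSE], tot,
                             design, sf = sf)
  res$gene_id <- unname(peak_gene[res$feature_id])
  res
}

#' Select the reference peak of each gene
#'
#' The peak with the lowest raw usage p-value; ties broken by smaller
#' genomic start, then peak id.
#'
#' @param peak_results data.frame from [peak_usage_scan()] (needs
#'   feature_id, gene_id, p).
#' @param peaks intronic peak `GRanges` with `peak_id` (for tie-breaking
#'   and coordinates); optional.
#' @return data.frame, one row per gene: the reference peak's result.
#' @export
select_reference_peak <- function(peak_results, peaks = NULL) {
  pr <- peak_results[!is.na(peak_results$p), , drop = FALSE]
  if (nrow(pr) == 0) return(pr)
  starts <- rep(NA_integer_, nrow(pr))
  if (!is.null(peaks)) {
    idx <- match(pr$feature_id, mcols(peaks)$peak_id)
    starts <- GenomicRanges::start(peaks)[idx]
  }
  starts[is.na(starts)] <- .Machine$integer.max
  o <- order(pr$gene_id, pr$p, starts, pr$feature_id)
  pr <- pr[o, , drop = FALSE]
  pr[!duplicated(pr$gene_id), , drop = FALSE]
}

#' Split a gene's exons into pre- and post-peak sets
#'
#' In transcription direction: `pre` exons end strictly 5' of the peak,
#' `post` exons start strictly 3' of it; exons overlapping the peak span
#' belong to neither. On the minus strand 5'/3' are reflected.
#'
#' @param gene_id gene identifier.
#' @param exons the gene's exon `GRanges`.
#' @param peak length-1 `GRanges`, the reference peak (must lie inside the
#'   gene footprint).
#' @param footprint optional length-1 `GRanges` gene footprint; defaults to
#'   the exon span. A gene record extending beyond the terminal exons
#'   admits peaks in its UTR-flanking introns (empty pre or post side).
#' @return list(gene_id, peak, pre, post, empty_pre, empty_post).
#' @export
fragment_gene_at_peak <- function(gene_id, exons, peak, footprint = NULL) {
  stopifnot(length(peak) == 1)
  fp <- if (is.null(footprint)) range(GenomicRanges::granges(exons))
        else GenomicRanges::granges(footprint)
  if (GenomicRanges::start(peak) < GenomicRanges::start(fp) ||
      GenomicRanges::end(peak) > GenomicRanges::end(fp))
    stop_input("reference peak lies outside gene '%s'", gene_id)
  left <- exons[GenomicRanges::end(exons) < GenomicRanges::start(peak)]
  right <- exons[GenomicRanges::start(exons) > GenomicRanges::end(peak)]
  minus <- as.character(GenomicRanges::strand(exons)[1]) == "-"
  pre <- if (minus) right else left
  post <- if (minus) left else right
  list(gene_id = gene_id, peak = peak, pre = pre, post = post,
       empty_pre = length(pre) == 0, empty_post = length(post) == 0)
}

#' Aggregated pre/post-peak differential expression
#'
#' Per gene, exonic counts are summed separately over the pre- and
#' post-peak exon sets and both aggregates are tested for differential
#' expression (point null). Genes with an empty side get NA on that side.
#'
#' @param fragmentations list of [fragment_gene_at_peak()] results.
#' @param exon_counts exon x sample count matrix.
#' @param exon_ranges `GRanges` of the exons in `exon_counts` (rownames
#'   matched against `exon_id` mcol or names).
#' @param design a [make_design()] object.
#' @param sf size factors (default from `exon_counts`).
#' @return data.frame (gene_id, pre_log2fc, pre_p, post_log2fc, post_p).
#' @export
prepost_differential <- function(fragmentations, exon_counts, exon_ranges,
                                 design, sf = NULL) {
  exon_counts <- as.matrix(exon_counts)
  if (is.null(sf)) sf <- size_factors(exon_counts)
  eid <- mcols(exon_ranges)$exon_id %||% names(exon_ranges)
  stopifnot(!is.null(eid))
  side_counts <- function(side_gr) {
    if (length(side_gr) == 0) return(NULL)
    hits <- GenomicRanges::findOverlaps(exon_ranges, side_gr, type = "equal")
    ids <- intersect(eid[queryHits(hits)], rownames(exon_counts))
    if (!length(ids)) return(NULL)
    colSums(exon_counts[ids, design$sample, drop = FALSE])
  }
  rows <- list(); labels <- character()
  for (fr in fragmentations) {
    pre <- side_counts(fr$pre); post <- side_counts(fr$post)
    if (!is.null(pre)) { rows[[length(rows) + 1]] <- pre
                         labels <- c(labels, paste0(fr$gene_id, "|pre")) }
    if (!is.null(post)) { rows[[length(rows) + 1]] <- post
                          labels <- c(labels, paste0(fr$gene_id, "|post")) }
  }
  genes <- vapply(fragmentations, `[[`, "", "gene_id")
  out <- data.frame(gene_id = genes, pre_log2fc = NA_real_, pre_p = NA_real_,
                    post_log2fc = NA_real_, post_p = NA_real_)
  if (!length(rows)) return(out)
  m <- do.call(rbind, rows)
  rownames(m) <- labels
  res <- nb_wald_test(m, design, sf = sf[design$sample], lfc_threshold = 0)
  side <- sub(".*\\|", "", res$feature_id)
  gene <- sub("\\|(pre|post)$", "", res$feature_id)
  for (i in seq_len(nrow(res))) {
    j <- match(gene[i], out$gene_id)
    if (side[i] == "pre") {
      out$pre_log2fc[j] <- res$log2fc[i]; out$pre_p[j] <- res$p[i]
    } else {
      out$post_log2fc[j] <- res$log2fc[i]; out$post_p[j] <- res$p[i]
    }
  }
  out
}

#' Classify genes by reference-peak behaviour
#'
#' `upregulated`: reference peak padj < `padj_cut` and usage log2 fold
#' change > `up_lfc`. `control`: padj > `padj_cut` and effect within
#' `(-control_band, control_band)`. Everything else (including filtered
#' peaks with undefined padj) is `other`.
#'
#' @param reference_results data.frame from [select_reference_peak()].
#' @param prepost data.frame from [prepost_differential()].
#' @param padj_cut adjusted-p threshold (default 0.05).
#' @param up_lfc minimum usage log2 fold change for "upregulated"
#'   (default 2).
#' @param control_band half-width of the control effect band (default 0.5).
#' @return data.frame (gene_id, label, peak_id, peak_log2fc, peak_padj,
#'   pre_log2fc, post_log2fc).
#' @export
classify_genes <- function(reference_results, prepost, padj_cut = 0.05,
                           up_lfc = 2, control_band = 0.5) {
  df <- merge(reference_results, prepost, by = "gene_id", all.x = TRUE)
  lab <- rep("other", nrow(df))
  ok <- !is.na(df$padj) & !is.na(df$log2fc)
  lab[ok & df$padj < padj_cut & df$log2fc > up_lfc] <- "upregulated"
  lab[ok & df$padj > padj_cut & df$log2fc > -control_band &
        df$log2fc < control_band] <- "control"
  data.frame(gene_id = df$gene_id, label = lab, peak_id = df$feature_id,
             peak_log2fc = df$log2fc, peak_padj = df$padj,
             pre_log2fc = df$pre_log2fc, post_log2fc = df$post_log2fc)
}

#' End-to-end exonization scan
#'
#' Composition of [peak_usage_scan()], [select_reference_peak()],
#' [fragment_gene_at_peak()], [prepost_differential()] and
#' [classify_genes()].
#'
#' @param genome an [AnnotatedGenome].
#' @param intronic intronic peak `GRanges` (from [intronic_peaks()]).
#' @param exon_counts,peak_counts count matrices.
#' @param design a [make_design()] object.
#' @param padj_cut,up_lfc,control_band classification thresholds.
#' @return list(peak_results, reference, fragmentations, prepost,
#'   classification).
#' @export
exonization_scan <- function(genome, intronic, exon_counts, peak_counts,
                             design, padj_cut = 0.05, up_lfc = 2,
                             control_band = 0.5) {
  peak_gene <- setNames(mcols(intronic)$host_gene, mcols(intronic)$peak_id)
  eid <- mcols(genome$exons)$exon_id
  exon_gene <- setNames(mcols(genome$exons)$gene_id, eid)
  res <- peak_usage_scan(peak_counts, exon_counts, peak_gene, exon_gene,
                         design)
  ref <- select_reference_peak(res, intronic)
  frs <- lapply(seq_len(nrow(ref)), function(i) {
    g <- ref$gene_id[i]
    ex <- genome$exons[mcols(genome$exons)$gene_id == g]
    pk <- intronic[mcols(intronic)$peak_id == ref$feature_id[i]]
    fp <- genome$genes[mcols(genome$genes)$gene_id == g]
    fragment_gene_at_peak(g, ex, pk, footprint = fp)
  })
  pp <- prepost_differential(frs, exon_counts, genome$exons, design)
  cls <- classify_genes(ref, pp, padj_cut, up_lfc, control_band)
  list(peak_results = res, reference = ref, fragmentations = frs,
       prepost = pp, classification = cls)
}
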