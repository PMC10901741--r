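# Peak universe construction: strand-aware merging of per-profile peak
# sets, host-gene assignment, exon masking to an intronic peak set, and the
# unified peak x profile count matrix.

#' Merge per-profile peak sets into a unified peak universe
#'
#' Overlapping or touching peaks from different RBP profiles are merged
#' strand-aware; each merged peak records the set of contributing profiles.
#'
#' @param peak_sets named list of `GRanges`, one per profile; every interval
#'   must be stranded.
#' @return `GRanges` with `peak_id` and `sources` (a `CharacterList`)
#'   metadata columns, sorted.
#' @export
merge_peak_sets <- function(peak_sets) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  for (p in names(peak_sets)) validate_intervals(peak_sets[[p]], stranded = TRUE)
  all <- do.call(c, lapply(names(peak_sets), function(p) {
    g <- GenomicRanges::granges(peak_sets[[p]])
    mcols(g)$profile <- p
    g
  }))
  merged <- GenomicRanges::reduce(all, with.revmap = TRUE)
  merged <- sort(merged, ignore.strand = TRUE)
  src <- lapply(mcols(merged)$revmap, function(i)
    sort(unique(mcols(all)$profile[i])))
  mcols(merged)$revmap <- NULL
  mcols(merged)$peak_id <- sprintf("peak_%05d", seq_along(merged))
  mcols(merged)$sources <- IRanges::CharacterList(src)
  merged
}

#' Assign merged peaks to host genes
#'
#' A peak is within-gene iff (by default) it is fully contained in a gene
#' footprint on the same strand. Peaks contained in multiple genes go to
#' the gene with the longest overlap, ties broken by lexicographically
#' smallest gene_id; such peaks are flagged ambiguous.
#'
#' @param peaks merged peak `GRanges`.
#' @param genome an [AnnotatedGenome] (or a gene-footprint `GRanges` with
#'   `gene_id`).
#' @param mode "containment" (default, strictest reading of "located
#'   inside") or "any" for any-overlap assignment.
#' @return `peaks` with `host_gene` (NA when intergenic/straddling) and
#'   `ambiguous_host` metadata columns.
#' @export
assign_host_genes <- function(peaks, genome, mode = c("containment", "any")) {
  mode <- match.arg(mode)
  genes <- if (is(genome, "AnnotatedGenome")) genome$genes else genome
  hits <- GenomicRanges::findOverlaps(
    peaks, genes, type = if (mode == "containment") "within" else "any",
    ignore.strand = FALSE)
  host <- rep(NA_character_, length(peaks))
  ambig <- rep(FALSE, length(peaks))
  if (length(hits)) {
    qh <- queryHits(hits); sh <- subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(peaks[qh], genes[sh]))
    gid <- mcols(genes)$gene_id[sh]
    for (q in unique(qh)) {
      sel <- which(qh == q)
      if (length(sel) > 1) {
        ambig[q] <- TRUE
        sel <- sel[order(-ov[sel], gid[sel])][1]
      }
      host[q] <- gid[sel]
    }
  }
  mcols(peaks)$host_gene <- host
  mcols(peaks)$ambiguous_host <- ambig
  peaks
}

#' Reduce within-gene peaks to their intronic parts
#'
#' Peak portions overlapping annotated exons are masked; surviving
#' sub-peaks at least `min_length` long are returned flagged intronic.
#' A peak fully inside exons vanishes; a peak split by an exon yields
#' several intronic fragments (ids suffixed `.1`, `.2`, ...).
#'
#' @param peaks host-assigned peak `GRanges` (only peaks with a host gene
#'   are considered).
#' @param genome an [AnnotatedGenome].
#' @param min_length minimum surviving fragment length (default 1).
#' @param ignore_exon_strand mask exons regardless of strand (default FALSE:
#'   only same-strand exons mask).
#' @return `GRanges` of intronic peak fragments with `peak_id`, `sources`,
#'   `host_gene`, `intronic = TRUE`.
#' @export
intronic_peaks <- function(peaks, genome, min_length = 1L,
                           ignore_exon_strand = FALSE) {
  if (is.null(mcols(peaks)$host_gene))
    stop_input("peaks must be host-assigned first (assign_host_genes)")
  within <- peaks[!is.na(mcols(peaks)$host_gene)]
  if (length(within) == 0) return(within)
  exons <- GenomicRanges::reduce(genome$exons,
                                 ignore.strand = ignore_exon_strand)
  pieces <- GenomicRanges::subtract(within, exons,
                                    ignore.strand = ignore_exon_strand)
  flat <- unlist(pieces, use.names = FALSE)
  origin <- rep(seq_along(pieces), lengths(pieces))
  ok <- GenomicRanges::width(flat) >= min_length
  flat <- flat[ok]; origin <- origin[ok]
  if (length(flat) == 0) {
    out <- within[0]
    mcols(out)$intronic <- logical(0)
    return(out)
  }
  n_frag <- as.integer(table(factor(origin, levels = unique(origin))))
  base_id <- mcols(within)$peak_id[origin]
  sub <- sequence(n_frag)
  multi <- origin %in% origin[duplicated(origin)]
  mcols(flat)$peak_id <- ifelse(multi, paste0(base_id, ".", sub), base_id)
  mcols(flat)$sources <- mcols(within)$sources[origin]
  mcols(flat)$host_gene <- mcols(within)$host_gene[origin]
  mcols(flat)$intronic <- TRUE
  sort(flat, ignore.strand = TRUE)
}

#' Assemble the unified peak x profile count matrix
#'
#' @param merged_peaks peak `GRanges` with `peak_id`.
#' @param per_profile_counts named list (one element per profile) of named
#'   numeric vectors `peak_id -> count`; peaks a profile omits count 0.
#' @return integer matrix peaks x profiles with dimnames.
#' @export
build_peak_count_matrix <- function(merged_peaks, per_profile_counts) {
  ids <- mcols(merged_peaks)$peak_id
  stopifnot(!is.null(ids), !is.null(names(per_profile_counts)))
  profs <- names(per_profile_counts)
  m <- matrix(0L, nrow = length(ids), ncol = length(profs),
              dimnames = list(ids, profs))
  for (p in profs) {
    v <- per_profile_counts[[p]]
    if (any(v < 0)) stop_input("negative count for profile '%s'", p)
    unknown <- setdiff(names(v), ids)
    if (length(unknown)) stop_input("profile '%s' counts unknown peak '%s'",
                                    p, unknown[1])
    m[names(v), p] <- as.integer(v)
  }
  m
}

#' Write a count matrix as TSV (feature_id first column)
#' @param m integer matrix with rownames.
#' @param path output TSV.
#' @param id_col name of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV (feature_id first column)
#' @param path TSV written by [write_count_matrix()] or equivalent.
#' @return integer matrix with rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
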