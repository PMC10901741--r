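# Splice-junction analyses: SJ-dialect IO, gene-assignment filter,
# differential junction usage, the intron-centric splicing index, the
# stringent tissue-panel filter chain, splice-site-to-TE distances, and the
# window-based splice-site strength survey with a pluggable scorer.

#' Read splice junctions in the SJ.out.tab dialect
#'
#' Columns: chrom, intron start (1-based, first intronic base), intron end
#' (1-based, last intronic base), strand code (0 undefined, 1 "+", 2 "-"),
#' motif, annotated flag, unique reads, multimapping reads, max overhang.
#' Unique-read counts are used.
#'
#' @param path SJ.out.tab-style file.
#' @return `GRanges` of introns with a `reads` metadata column.
#' @export
read_sj_tab <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE)
  if (ncol(df) < 7) stop_input("'%s' is not an SJ.out.tab-dialect file", path)
  strand <- c("*", "+", "-")[df[[4]] + 1L]
  bad <- which(df[[2]] > df[[3]])
  if (length(bad)) stop_input("coordinate inversion at line %d of '%s'",
                              bad[1], path)
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]], df[[3]]),
                         strand = strand, reads = as.integer(df[[7]]))
}

#' Assemble a junction panel from per-sample SJ files
#'
#' @param paths named character vector (sample -> file).
#' @return list(junctions = `GRanges` with `junction_id`, counts = junction
#'   x sample matrix).
#' @export
read_sj_panel <- function(paths) {
  stopifnot(!is.null(names(paths)))
  per <- lapply(paths, read_sj_tab)
  all <- unique(do.call(c, unname(lapply(per, GenomicRanges::granges))))
  all <- sort(all, ignore.strand = TRUE)
  mcols(all)$junction_id <- sprintf("jx_%05d", seq_along(all))
  counts <- matrix(0L, nrow = length(all), ncol = length(paths),
                   dimnames = list(mcols(all)$junction_id, names(paths)))
  for (s in names(paths)) {
    hits <- GenomicRanges::findOverlaps(per[[s]], all, type = "equal")
    counts[subjectHits(hits), s] <- mcols(per[[s]])$reads[queryHits(hits)]
  }
  list(junctions = all, counts = counts)
}

#' Write a junction count vector in the SJ.out.tab dialect
#' @param junctions intron `GRanges`.
#' @param reads integer read counts, one per junction.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sj_tab <- function(junctions, reads, path) {
  code <- c("*" = 0L, "+" = 1L, "-" = 2L)[
    as.character(GenomicRanges::strand(junctions))]
  df <- data.frame(as.character(GenomicRanges::seqnames(junctions)),
                   GenomicRanges::start(junctions),
                   GenomicRanges::end(junctions),
                   code, 0L, 0L, as.integer(reads), 0L, 20L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Strand-oriented donor and acceptor positions of junctions
#'
#' The donor is the first intronic base in transcription direction, the
#' acceptor the last (reflected on the minus strand).
#'
#' @param junctions intron `GRanges`.
#' @return data.frame (chrom, strand, donor_pos, acceptor_pos), 1-based.
#' @export
junction_sites <- function(junctions) {
  minus <- as.character(GenomicRanges::strand(junctions)) == "-"
  data.frame(chrom = as.character(GenomicRanges::seqnames(junctions)),
             strand = as.character(GenomicRanges::strand(junctions)),
             donor_pos = ifelse(minus, GenomicRanges::end(junctions),
                                GenomicRanges::start(junctions)),
             acceptor_pos = ifelse(minus, GenomicRanges::start(junctions),
                                   GenomicRanges::end(junctions)))
}

#' Filter junctions by host gene and read support
#'
#' A junction survives iff it is contained in exactly one gene footprint on
#' the same strand (unambiguous host) and its total reads across all
#' samples reach `min_total_reads`.
#'
#' @param junctions intron `GRanges`.
#' @param counts junction x sample matrix (rows parallel to `junctions`).
#' @param genome an [AnnotatedGenome].
#' @param min_total_reads default 10.
#' @return list(junctions with `host_gene`, counts) restricted to
#'   survivors.
#' @export
filter_junctions <- function(junctions, counts, genome, min_total_reads = 10) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(junctions))
  hits <- GenomicRanges::findOverlaps(junctions, genome$genes, type = "within",
                                      ignore.strand = FALSE)
  nhit <- tabulate(queryHits(hits), nbins = length(junctions))
  host <- rep(NA_character_, length(junctions))
  uq <- queryHits(hits)[nhit[queryHits(hits)] == 1]
  host[uq] <- mcols(genome$genes)$gene_id[
    subjectHits(hits)[nhit[queryHits(hits)] == 1]]
  keep <- nhit == 1 & rowSums(counts) >= min_total_reads
  out <- junctions[keep]
  mcols(out)$host_gene <- host[keep]
  list(junctions = out, counts = counts[keep, , drop = FALSE])
}

#' Differential junction usage
#'
#' Junctions as features, host genes as groups: each junction's share of
#' its gene's total junction reads is tested between conditions.
#'
#' @param junctions filtered junction `GRanges` with `host_gene` and
#'   `junction_id`.
#' @param counts junction x sample matrix.
#' @param design a [make_design()] object.
#' @return data.frame from [relative_usage_test()] plus `gene_id`.
#' @export
differential_junction_usage <- function(junctions, counts, design) {
  counts <- as.matrix(counts)
  gene <- mcols(junctions)$host_gene
  rownames(counts) <- mcols(junctions)$junction_id
  tot <- rowsum(counts, gene)[gene, , drop = FALSE]
  rownames(tot) <- rownames(counts)
  res <- relative_usage_test(counts, tot, design)
  res$gene_id <- gene[match(res$feature_id, rownames(counts))]
  res
}

#' Intron-centric splicing index
#'
#' For every donor (or acceptor) site, each junction's share of the total
#' reads of all junctions using that site. Shares sum to 1 per site
#' wherever the site total is positive; sites with zero total get NA.
#'
#' @param junctions intron `GRanges`.
#' @param counts junction x sample (or x tissue) matrix.
#' @param site "donor" or "acceptor".
#' @return matrix of splicing indices, same shape as `counts`, plus a
#'   `site_key` attribute (the site each junction belongs to).
#' @export
splicing_index <- function(junctions, counts, site = c("donor", "acceptor")) {
  site <- match.arg(site)
  counts <- as.matrix(counts)
  js <- junction_sites(junctions)
  pos <- if (site == "donor") js$donor_pos else js$acceptor_pos
  key <- paste(js$chrom, js$strand, pos)
  tot <- rowsum(counts, key)[key, , drop = FALSE]
  si <- counts / tot
  si[tot == 0] <- NA
  dimnames(si) <- dimnames(counts)
  attr(si, "site_key") <- key
  si
}

#' Stringent tissue-panel filter chain for novel acceptors in peaks
#'
#' Applies, in order: tissue inclusion (per-tissue spliced-read total >=
#' `tissue_min`); junction inside exactly one annotated gene; donor in the
#' annotated donor set; acceptor within a fully intronic peak; donor used
#' by >= 2 junctions; splicing index > `si_min` in at least one included
#' tissue; donor support >= `read_min` in every included tissue. Donor
#' sharing, splicing index and donor support are computed on the full
#' tissue-included panel, and each junction is attributed to the first
#' rule it fails.
#'
#' @param junctions intron `GRanges`.
#' @param tissue_counts junction x tissue matrix.
#' @param genome an [AnnotatedGenome].
#' @param intronic intronic peak `GRanges`.
#' @param annotated_donors data.frame (chrom, strand, donor_pos) of
#'   annotated donor sites, e.g. from [annotated_donor_sites()].
#' @param tissue_min minimum spliced reads per tissue (default 1e9).
#' @param si_min splicing-index threshold (default 0.01).
#' @param read_min donor read support required in every tissue (default
#'   500).
#' @param support "donor" (default: the donor's total junction reads per
#'   tissue) or "junction" (the junction's own reads).
#' @return list(junctions = survivors, status = per-junction first failed
#'   rule ("pass" for survivors), attrition = data.frame(filter, n_in,
#'   n_out), tissues = included tissues).
#' @export
stringent_panel_filter <- function(junctions, tissue_counts, genome, intronic,
                                   annotated_donors, tissue_min = 1e9,
                                   si_min = 0.01, read_min = 500,
                                   support = c("donor", "junction")) {
  support <- match.arg(support)
  tissue_counts <- as.matrix(tissue_counts)
  if (ncol(tissue_counts) == 0 || length(junctions) == 0)
    stop_input("empty junction panel")
  tissues <- colnames(tissue_counts)[colSums(tissue_counts) >= tissue_min]
  if (!length(tissues)) stop_input("no tissue passes the inclusion threshold")
  tc <- tissue_counts[, tissues, drop = FALSE]

  js <- junction_sites(junctions)
  # rule 1: unambiguous host gene
  hits <- GenomicRanges::findOverlaps(junctions, genome$genes, type = "within",
                                      ignore.strand = FALSE)
  nhit <- tabulate(queryHits(hits), nbins = length(junctions))
  in_gene <- nhit == 1
  # rule 2: donor annotated
  dkey <- paste(js$chrom, js$strand, js$donor_pos)
  akey_annot <- paste(annotated_donors$chrom, annotated_donors$strand,
                      annotated_donors$donor_pos)
  donor_annot <- dkey %in% akey_annot
  # rule 3: acceptor within a fully intronic peak
  acc <- GenomicRanges::GRanges(js$chrom,
                                IRanges::IRanges(js$acceptor_pos,
                                                 js$acceptor_pos),
                                strand = js$strand)
  acc_in_peak <- IRanges::overlapsAny(acc, intronic, type = "within",
                                      ignore.strand = FALSE)
  # rule 4: donor participates in multiple events
  donor_multi <- unname(table(dkey)[dkey]) >= 2
  # rule 5: SI above threshold in >= 1 tissue
  si <- splicing_index(junctions, tc, "donor")
  si_ok <- apply(si, 1, function(r) any(!is.na(r) & r > si_min))
  # rule 6: support in every tissue
  supp <- if (support == "donor") rowsum(tc, dkey)[dkey, , drop = FALSE]
          else tc
  supp_ok <- apply(supp, 1, function(r) all(r >= read_min))

  rules <- cbind(host_gene = in_gene, donor_annotated = donor_annot,
                 acceptor_in_peak = acc_in_peak, donor_multi = donor_multi,
                 si = si_ok, support = supp_ok)
  first_fail <- unname(apply(rules, 1, function(r)
    if (all(r)) "pass" else colnames(rules)[which(!r)[1]]))
  n_in <- length(junctions)
  attrition <- data.frame(filter = colnames(rules),
                          n_in = NA_integer_, n_out = NA_integer_)
  surviving <- rep(TRUE, n_in)
  for (i in seq_len(ncol(rules))) {
    attrition$n_in[i] <- sum(surviving)
    surviving <- surviving & rules[, i]
    attrition$n_out[i] <- sum(surviving)
  }
  out <- junctions[surviving]
  mcols(out)$host_gene <- mcols(genome$genes)$gene_id[
    subjectHits(hits)[match(which(surviving), queryHits(hits))]]
  list(junctions = out, status = first_fail, attrition = attrition,
       tissues = tissues)
}

#' Annotated donor sites of a genome
#'
#' Donor positions implied by the flattened exon structure: the first
#' intronic base after each non-terminal exon in transcription direction.
#'
#' @param genome an [AnnotatedGenome].
#' @return data.frame (chrom, strand, donor_pos).
#' @export
annotated_donor_sites <- function(genome) {
  res <- lapply(split(genome$exons, mcols(genome$exons)$gene_id), function(ex) {
    ex <- sort(GenomicRanges::granges(ex), ignore.strand = TRUE)
    if (length(ex) < 2) return(NULL)
    minus <- as.character(GenomicRanges::strand(ex)[1]) == "-"
    pos <- if (minus) GenomicRanges::start(ex)[-1] - 1L
           else GenomicRanges::end(ex)[-length(ex)] + 1L
    data.frame(chrom = as.character(GenomicRanges::seqnames(ex))[1],
               strand = as.character(GenomicRanges::strand(ex))[1],
               donor_pos = pos)
  })
  unique(do.call(rbind, res))
}

#' Distance from splice sites to the nearest TE of each family
#'
#' For each site, family and orientation (sense/antisense relative to the
#' site's gene strand), the gap in bases to the nearest family member
#' within the same flattened gene; 0 when the site lies inside one; NA when
#' the gene contains no such element. Repeats outside annotated genes are
#' dropped; sites outside any flattened gene are skipped.
#'
#' @param sites `GRanges` of single-base splice sites (stranded; strand =
#'   gene strand).
#' @param genome an [AnnotatedGenome].
#' @param families repeat families to measure (default: the ten surveyed
#'   families).
#' @return data.frame (site, chrom, pos, strand, gene_id, family,
#'   orientation, distance).
#' @export
nearest_te_distance <- function(sites, genome,
                                families = c("L1", "L2", "Alu", "SVA", "ERVL",
                                             "ERV1", "TcMar-Tigger", "MIR",
                                             "Simple_repeat", "hAT_Charlie")) {
  genes <- genome$genes
  reps <- genome$repeats
  reps <- reps[IRanges::overlapsAny(reps, genes, ignore.strand = TRUE)]
  site_hits <- GenomicRanges::findOverlaps(sites, genes, type = "within",
                                           ignore.strand = FALSE)
  if (length(site_hits) == 0) return(data.frame())
  rep_hits <- GenomicRanges::findOverlaps(reps, genes, ignore.strand = TRUE)
  rep_df <- data.frame(
    gene = mcols(genes)$gene_id[subjectHits(rep_hits)],
    start = GenomicRanges::start(reps)[queryHits(rep_hits)],
    end = GenomicRanges::end(reps)[queryHits(rep_hits)],
    family = mcols(reps)$family[queryHits(rep_hits)],
    strand = as.character(GenomicRanges::strand(reps))[queryHits(rep_hits)])
  si <- queryHits(site_hits)
  site_df <- data.frame(
    site = si, chrom = as.character(GenomicRanges::seqnames(sites))[si],
    pos = GenomicRanges::start(sites)[si],
    strand = as.character(GenomicRanges::strand(sites))[si],
    gene_id = mcols(genes)$gene_id[subjectHits(site_hits)],
    gene_strand = as.character(
      GenomicRanges::strand(genes))[subjectHits(site_hits)])
  grid <- merge(site_df,
                expand.grid(family = families,
                            orientation = c("sense", "antisense"),
                            stringsAsFactors = FALSE))
  pairs <- merge(grid, rep_df, by.x = "gene_id", by.y = "gene",
                 suffixes = c("", "_rep"), all.x = TRUE)
  want <- ifelse(pairs$orientation == "sense", pairs$gene_strand,
                 ifelse(pairs$gene_strand == "+", "-", "+"))
  ok <- !is.na(pairs$family_rep) & pairs$family == pairs$family_rep &
    pairs$strand_rep == want
  gap <- rep(NA_real_, nrow(pairs))
  inside <- ok & pairs$pos >= pairs$start & pairs$pos <= pairs$end
  gap[inside] <- 0
  flank <- ok & !inside
  gap[flank] <- pmin(abs(pairs$pos[flank] - pairs$end[flank]),
                     abs(pairs$start[flank] - pairs$pos[flank])) - 1
  key <- paste(pairs$site, pairs$gene_id, pairs$family, pairs$orientation)
  mins <- tapply(gap, key, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  first <- !duplicated(key)
  out <- pairs[first, c("site", "chrom", "pos", "strand", "gene_id",
                        "family", "orientation")]
  out$distance <- as.numeric(mins[key[first]])
  out <- out[order(out$site, out$family, out$orientation), ]
  rownames(out) <- NULL
  out
}

#' Window survey of splice-site strength
#'
#' Compares a novel site's score against every candidate dinucleotide
#' (AG for acceptors, GT for donors, on the site's strand) in a window
#' centered on it, and against a seeded random sample of those candidates.
#' The scorer is pluggable: any function `(position) -> score in [0, 1]`,
#' e.g. a neural splice model adapter or the package's toy hexamer scorer.
#'
#' @param scorer function(pos) -> numeric score.
#' @param novel_pos 1-based position of the novel site (position of the
#'   first base of the dinucleotide).
#' @param site_type "acceptor" (AG) or "donor" (GT).
#' @param sequence chromosome sequence (character or `DNAString`), plus
#'   strand context via `strand`.
#' @param strand "+" or "-" (on "-" the dinucleotide is matched as its
#'   reverse complement on the given sequence).
#' @param window window size in nt centered on the site (default 500).
#' @param n_random number of random candidate positions (default 100,
#'   sampled with replacement if fewer candidates exist).
#' @param seed RNG seed for the random sample.
#' @return list(novel_score, best_score, best_pos, random_scores,
#'   novel_is_best, n_candidates); NULL scores when no candidate
#'   dinucleotide exists in the window.
#' @export
window_site_survey <- function(scorer, novel_pos, site_type = c("acceptor",
                                                                "donor"),
                               sequence, strand = "+", window = 500,
                               n_random = 100, seed = 1) {
  site_type <- match.arg(site_type)
  s <- toupper(as.character(sequence))
  din <- if (site_type == "acceptor") "AG" else "GT"
  if (strand == "-")
    din <- chartr("ACGT", "TGCA", paste(rev(strsplit(din, "")[[1]]),
                                        collapse = ""))
  lo <- max(1, novel_pos - window %/% 2)
  hi <- min(nchar(s) - 1, novel_pos + window %/% 2)
  if (hi < lo) stop_input("window empty")
  sub <- substring(s, lo, hi + 1)
  starts <- gregexpr(din, sub, fixed = TRUE)[[1]]
  cand <- if (starts[1] == -1) integer(0) else as.integer(starts) + lo - 1L
  if (!length(cand))
    return(list(novel_score = NULL, best_score = NULL, best_pos = NULL,
                random_scores = NULL, novel_is_best = NA, n_candidates = 0))
  scores <- vapply(cand, scorer, 0)
  novel_score <- scorer(novel_pos)
  rnd <- with_seed(seed, sample(scores, n_random, replace = TRUE))
  best <- which.max(scores)
  list(novel_score = novel_score, best_score = scores[best],
       best_pos = cand[best], random_scores = rnd,
       novel_is_best = novel_score >= scores[best], n_candidates = length(cand))
}

#' Toy hexamer log-odds splice scorer
#'
#' A stand-in scorer for tests and demonstrations: scores position `p` by
#' the log-odds of the hexamer starting at `p` under foreground hexamer
#' frequencies (estimated from supplied training sequences) against a
#' uniform background, squashed to \[0, 1\] with a logistic.
#'
#' @param training_seqs character vector of foreground sequences.
#' @param sequence the chromosome sequence the scorer will be applied to.
#' @return function(pos) -> score in \[0, 1\].
#' @export
make_hexamer_scorer <- function(training_seqs, sequence) {
  s <- toupper(as.character(sequence))
  hex <- unlist(lapply(toupper(training_seqs), function(x) {
    n <- nchar(x)
    if (n < 6) return(character(0))
    substring(x, 1:(n - 5), 6:n)
  }))
  freq <- table(hex) / length(hex)
  bg <- 1 / 4^6
  function(pos) {
    h <- substring(s, pos, pos + 5)
    if (nchar(h) < 6) return(0)
    f <- freq[h]
    lo <- log((if (is.na(f)) bg / 10 else as.numeric(f)) / bg)
    1 / (1 + exp(-lo))
  }
}
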