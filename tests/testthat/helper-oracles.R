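# Independent brute-force oracles. All deliberately work base-by-base on
# plain integer vectors (1-based closed coordinates), never through the
# interval machinery they are used to check.

# maximal runs of covered bases per (chrom, strand) group
oracle_reduce <- function(chrom, start, end, strand, strand_aware = TRUE) {
  key <- if (strand_aware) paste(chrom, strand) else chrom
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    lo <- min(start[sel]); hi <- max(end[sel])
    occ <- rep(FALSE, hi - lo + 1)
    for (i in which(sel)) occ[(start[i]:end[i]) - lo + 1] <- TRUE
    r <- rle(occ)
    ends_ <- cumsum(r$lengths); starts_ <- ends_ - r$lengths + 1
    runs <- which(r$values)
    out[[k]] <- data.frame(chrom = chrom[sel][1],
                           start = starts_[runs] + lo - 1,
                           end = ends_[runs] + lo - 1,
                           strand = if (strand_aware) strand[sel][1] else "*")
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

# per-base labeling for priority fragmentation over one gene footprint
oracle_fragment_labels <- function(fp_start, fp_end, features, priority) {
  lab <- rep("intron", fp_end - fp_start + 1)
  for (lev in rev(priority)) {       # lowest first; higher overwrites
    fs <- features[[lev]]
    if (is.null(fs)) next
    for (i in seq_len(nrow(fs))) {
      s <- max(fs$start[i], fp_start); e <- min(fs$end[i], fp_end)
      if (s <= e) lab[(s:e) - fp_start + 1] <- lev
    }
  }
  lab
}

# per-base subtraction: bases of x not covered by any y
oracle_subtract <- function(x_start, x_end, y_start, y_end) {
  occ <- rep(TRUE, x_end - x_start + 1)
  for (i in seq_along(y_start)) {
    s <- max(y_start[i], x_start); e <- min(y_end[i], x_end)
    if (s <= e) occ[(s:e) - x_start + 1] <- FALSE
  }
  r <- rle(occ)
  ends_ <- cumsum(r$lengths); starts_ <- ends_ - r$lengths + 1
  runs <- which(r$values)
  data.frame(start = starts_[runs] + x_start - 1,
             end = ends_[runs] + x_start - 1)
}

# exhaustive nearest-distance scan (gap in bases; 0 when overlapping)
oracle_min_gap <- function(pos, starts, ends) {
  if (!length(starts)) return(NA_real_)
  gaps <- ifelse(pos >= starts & pos <= ends, 0,
                 pmin(abs(pos - ends), abs(starts - pos)) - 1)
  min(gaps)
}

# random interval set on a toy chromosome (1-based closed)
random_intervals <- function(n, chrom_len = 10000, max_len = 400,
                             strands = c("+", "-")) {
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  start <- sample.int(chrom_len - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = "chrT", start = start, end = start + len - 1,
             strand = sample(strands, n, replace = TRUE))
}

granges_of <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand)
}

grange_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}
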