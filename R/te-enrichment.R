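# Strand-separated TE family composition of interval sets, the log2
# observed/expected enrichment statistic, and sequence composition
# statistics (adenosine content, purine-rich k-mer enrichment).

#' Strand-separated TE family fractions of an interval set
#'
#' For each repeat family and orientation (sense = repeat strand equals
#' region strand), the fraction of the total region length covered by that
#' family. Overlapping same-family repeats count once per base; the
#' denominator is the total (reduced, per-strand) region length including
#' repeat-free bases.
#'
#' @param regions stranded `GRanges` (peaks or flattened genes).
#' @param repeats repeat `GRanges` with `family`.
#' @param families families to tabulate (default: all present).
#' @return data.frame (family, orientation, covered, total, fraction).
#' @export
te_fractions <- function(regions, repeats, families = NULL) {
  if (length(regions) == 0) stop_input("empty region set: fraction undefined")
  validate_intervals(regions, stranded = TRUE)
  if (is.null(families)) families <- sort(unique(mcols(repeats)$family))
  reg <- GenomicRanges::reduce(GenomicRanges::granges(regions))  # per strand
  total <- sum(GenomicRanges::width(reg))
  reg_s <- split(reg, as.character(GenomicRanges::strand(reg)))
  cover <- function(fam, orientation) {
    r <- repeats[mcols(repeats)$family == fam]
    covered <- 0
    for (s in names(reg_s)) {
      want <- if (orientation == "sense") s else setdiff(c("+", "-"), s)
      rs <- GenomicRanges::reduce(GenomicRanges::granges(
        r[as.character(GenomicRanges::strand(r)) == want]))
      covered <- covered + sum(GenomicRanges::width(
        GenomicRanges::intersect(reg_s[[s]], rs, ignore.strand = TRUE)))
    }
    covered
  }
  grid <- expand.grid(family = families, orientation = c("sense", "antisense"),
                      stringsAsFactors = FALSE)
  grid$covered <- mapply(cover, grid$family, grid$orientation)
  grid$total <- total
  grid$fraction <- grid$covered / total
  grid[order(grid$family, grid$orientation), ]
}

#' Log2 observed/expected TE enrichment
#'
#' `log2(observed fraction / expected fraction)` per family and
#' orientation. Degenerate fractions yield flagged sentinels: `-Inf`
#' (observed 0), `+Inf` (expected 0), `NaN` (both 0).
#'
#' @param observed,expected data.frames from [te_fractions()] over the same
#'   families.
#' @return data.frame (family, orientation, obs_fraction, exp_fraction,
#'   log2_enrichment, degenerate flag).
#' @export
log2_enrichment <- function(observed, expected) {
  key <- function(d) paste(d$family, d$orientation)
  if (!setequal(key(observed), key(expected)))
    stop_input("observed and expected tables cover different families")
  m <- merge(observed[c("family", "orientation", "fraction")],
             expected[c("family", "orientation", "fraction")],
             by = c("family", "orientation"), suffixes = c("_obs", "_exp"))
  le <- suppressWarnings(log2(m$fraction_obs / m$fraction_exp))
  data.frame(family = m$family, orientation = m$orientation,
             obs_fraction = m$fraction_obs, exp_fraction = m$fraction_exp,
             log2_enrichment = le,
             degenerate = !is.finite(le))
}

#' Nucleotide composition of a sequence
#'
#' Fractions of A, C, G and T (U counted as T); IUPAC ambiguity codes are
#' excluded from the denominator by default.
#'
#' @param seq character string or `Biostrings::DNAString`.
#' @param include_ambiguous count ambiguity codes in the denominator.
#' @return named numeric vector (A, C, G, T) summing to 1 over counted
#'   bases.
#' @export
nucleotide_composition <- function(seq, include_ambiguous = FALSE) {
  s <- toupper(as.character(seq))
  if (!nzchar(s)) stop_input("empty sequence")
  chars <- strsplit(chartr("U", "T", s), "")[[1]]
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  denom <- if (include_ambiguous) length(chars) else sum(counts)
  if (denom == 0) stop_input("sequence has no unambiguous bases")
  counts / denom
}

#' Purine-rich k-mer enrichment against a mononucleotide-shuffled background
#'
#' A k-mer is purine-rich iff its A+G fraction is at least
#' `purine_threshold`. The observed density (fraction of k-windows that are
#' purine-rich) is compared with densities from `n_shuffles` random
#' permutations of the sequence (mononucleotide shuffle preserves base
#' composition); the empirical p-value uses the add-one rule.
#'
#' @param seq character string or `DNAString`.
#' @param k k-mer length (>= 3).
#' @param purine_threshold minimum A+G fraction in (0, 1].
#' @param n_shuffles number of shuffles.
#' @param seed RNG seed.
#' @return list(observed_density, shuffled_mean, ratio, p_value,
#'   n_shuffles).
#' @export
purine_kmer_enrichment <- function(seq, k = 6L, purine_threshold = 1,
                                   n_shuffles = 100L, seed = 1L) {
  s <- toupper(as.character(seq))
  if (k < 3) stop_input("k must be >= 3")
  if (k > nchar(s)) stop_input("k longer than the sequence")
  stopifnot(purine_threshold > 0, purine_threshold <= 1)
  chars <- strsplit(s, "")[[1]]
  density <- function(ch) {
    pur <- as.integer(ch %in% c("A", "G"))
    win <- cumsum(pur)
    win <- (win[k:length(pur)] - c(0, head(win, length(pur) - k)))
    mean(win / k >= purine_threshold)
  }
  obs <- density(chars)
  shuf <- with_seed(seed, vapply(seq_len(n_shuffles),
                                 function(i) density(sample(chars)), 0))
  list(observed_density = obs, shuffled_mean = mean(shuf),
       ratio = if (mean(shuf) > 0) obs / mean(shuf) else Inf,
       p_value = (1 + sum(shuf >= obs)) / (n_shuffles + 1),
       n_shuffles = n_shuffles)
}
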