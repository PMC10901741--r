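# Seed-deterministic generators: annotated toy genomes with intronic TE
# insertions, RBP peaks, NB count tables with planted exonization /
# early-termination effects, junction panels, long-read 3' ends with
# planted polyA switches, and peak x profile matrices with planted
# clusters. Defaults define the study conditions every downstream module
# is validated against.

#' Simulation specification
#'
#' Bundles every tunable of the generators with its default. Defaults are
#' chosen once to emulate the statistical structure of the real analyses:
#' TE-rich introns (about half the intronic space), adenosine-biased
#' sense-TE bodies, NB counts at moderate depth and dispersion, 3 vs 3
#' replicates, and planted effect sizes large enough to be unambiguous at
#' that depth.
#'
#' @param seed master seed; every generator derives its stream from it.
#' @param n_genes number of genes (default 500).
#' @param chrom toy chromosome name.
#' @param n_exons_range inclusive range of exons per gene.
#' @param exon_len_meanlog,exon_len_sdlog lognormal exon lengths (median
#'   ~150 nt).
#' @param intron_len_meanlog,intron_len_sdlog lognormal intron lengths
#'   (median ~1,600 nt).
#' @param intergenic_gap gap between consecutive genes (nt).
#' @param te_families,te_family_probs repeat families and their sampling
#'   weights.
#' @param te_prob probability an intron carries a TE insertion (default
#'   0.8; with the default length distributions TEs occupy roughly half
#'   the intronic space).
#' @param te_sense_prob probability an inserted TE lies on the gene strand.
#' @param te_len_meanlog,te_len_sdlog lognormal TE lengths (median ~800
#'   nt, clipped to the intron).
#' @param te_A adenosine probability inside sense-TE bodies when sequences
#'   are generated (default 0.42, emulating A-rich L1 ORFs).
#' @param peak_width width of the one intronic peak planted per gene.
#' @param exonized_fraction fraction of genes with a planted exonization
#'   event (default 0.10).
#' @param peak_share_mult treatment multiplier of the planted peak's signal
#'   (default 8).
#' @param post_mult treatment multiplier of post-peak exon means in planted
#'   genes (default 0.5).
#' @param novel_junction_share share of gene depth given to the planted
#'   novel junction into the peak, treatment only (default 0.3).
#' @param apa_switch_fraction fraction of genes with a planted polyA switch
#'   (default 0.15).
#' @param apa_switch_pp planted isoform-fraction switch in percentage
#'   points / 100 (default 0.30).
#' @param apa_reads_per_gene 3'-end reads per gene per condition (default
#'   600: deep enough that isoform fractions are estimated to about +/- 3
#'   percentage points).
#' @param apa_jitter_sd positional jitter of read ends around the polyA
#'   site, nt (default 5; always within the +/-50 collapse radius).
#' @param mean_count mean NB count per exon per sample at depth 1 (default
#'   100).
#' @param mu_sdlog lognormal spread of per-gene expression (default 0.3).
#' @param dispersion NB dispersion (default 0.1).
#' @param peak_share baseline intronic-peak signal as a share of gene mean
#'   (default 0.05).
#' @param n_replicates replicates per condition (default 3).
#' @param with_seqs generate chromosome sequence (default FALSE; the
#'   coordinate-level pipelines do not need it).
#' @param n_clusters,peaks_per_cluster,n_profiles peak-profile matrix
#'   generator: planted clusters, peaks per cluster, profiles.
#' @param cluster_signal,cluster_background NB means of a cluster's
#'   dominant profile vs the rest.
#' @param shared_source_prob probability a simulated peak is attributed to
#'   two profiles instead of its dominant one.
#' @return a list with class `sim_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_genes = 500L, chrom = "chrS",
                            n_exons_range = c(4L, 8L),
                            exon_len_meanlog = log(150), exon_len_sdlog = 0.35,
                            intron_len_meanlog = log(1600),
                            intron_len_sdlog = 0.35,
                            intergenic_gap = 3000L,
                            te_families = c("L1", "Alu"),
                            te_family_probs = c(0.5, 0.5),
                            te_prob = 0.8, te_sense_prob = 0.5,
                            te_len_meanlog = log(800), te_len_sdlog = 0.3,
                            te_A = 0.42, peak_width = 300L,
                            exonized_fraction = 0.10, peak_share_mult = 8,
                            post_mult = 0.5, novel_junction_share = 0.3,
                            apa_switch_fraction = 0.15, apa_switch_pp = 0.30,
                            apa_reads_per_gene = 600L, apa_jitter_sd = 5,
                            mean_count = 100, mu_sdlog = 0.3,
                            dispersion = 0.1, peak_share = 0.05,
                            n_replicates = 3L, with_seqs = FALSE,
                            n_clusters = 3L, peaks_per_cluster = 300L,
                            n_profiles = 6L, cluster_signal = 200,
                            cluster_background = 5,
                            shared_source_prob = 0.1) {
  spec <- as.list(environment())
  stopifnot(spec$te_prob >= 0, spec$te_prob <= 1,
            spec$exonized_fraction >= 0, spec$exonized_fraction <= 1,
            spec$peak_share_mult > 0, spec$post_mult > 0,
            spec$n_replicates >= 2,
            length(spec$te_families) == length(spec$te_family_probs))
  class(spec) <- "sim_spec"
  spec
}

# fixed substream offsets keep the generators independently reproducible
.SIM_OFFSETS <- c(genome = 11L, counts = 23L, ends = 37L, profiles = 53L,
                  peaks = 71L)

#' Simulate an annotated toy genome with intronic TE insertions
#'
#' Genes are laid out sequentially on one chromosome; each intron carries a
#' TE insertion with probability `te_prob` (family, strand and length from
#' the spec), and one intronic peak per gene is planted (inside a TE when
#' the intron has one). When `with_seqs` is set the chromosome sequence is
#' generated with elevated adenosine content inside sense-TE bodies.
#'
#' @param spec a [simulation_spec()].
#' @return list(genome = [AnnotatedGenome], peaks = `GRanges` (planted
#'   intronic peaks with `peak_id`, `sources`, `host_gene`), truth =
#'   per-gene data.frame).
#' @export
simulate_genome <- function(spec = simulation_spec()) {
  with_seed(spec$seed + .SIM_OFFSETS[["genome"]], {
    n <- spec$n_genes
    exonized <- rep(FALSE, n)
    exonized[sample(n, round(spec$exonized_fraction * n))] <- TRUE
    apa <- rep(FALSE, n)
    apa[sample(n, round(spec$apa_switch_fraction * n))] <- TRUE

    cursor <- 1000L
    genes <- exons <- repeats <- peaks <- list()
    truth <- list()
    for (g in seq_len(n)) {
      gid <- sprintf("G%04d", g)
      strand <- sample(c("+", "-"), 1)
      k <- sample(seq(spec$n_exons_range[1], spec$n_exons_range[2]), 1)
      elen <- pmax(60L, round(rlnorm(k, spec$exon_len_meanlog,
                                     spec$exon_len_sdlog)))
      ilen <- pmax(400L, round(rlnorm(k - 1, spec$intron_len_meanlog,
                                      spec$intron_len_sdlog)))
      starts <- integer(k); ends <- integer(k)
      x <- cursor
      for (i in seq_len(k)) {
        starts[i] <- x; ends[i] <- x + elen[i] - 1L
        x <- ends[i] + 1L + if (i < k) ilen[i] else 0L
      }
      gene_start <- starts[1]; gene_end <- ends[k]
      exons[[g]] <- data.frame(start = starts, end = ends)

      # TE insertions per intron
      te_intron <- integer(0)
      for (i in seq_len(k - 1)) {
        if (runif(1) > spec$te_prob) next
        i_start <- ends[i] + 1L; i_end <- starts[i + 1] - 1L
        space <- i_end - i_start - 60L
        if (space < 100L) next
        tlen <- min(space, max(100L, round(rlnorm(1, spec$te_len_meanlog,
                                                  spec$te_len_sdlog))))
        t_start <- i_start + 30L +
          sample.int(max(1L, space - tlen + 1L), 1) - 1L
        fam <- sample(spec$te_families, 1, prob = spec$te_family_probs)
        sense <- runif(1) < spec$te_sense_prob
        t_strand <- if (sense) strand else setdiff(c("+", "-"), strand)
        repeats[[length(repeats) + 1L]] <- data.frame(
          start = t_start, end = t_start + tlen - 1L, strand = t_strand,
          family = fam, gene = gid)
        te_intron <- c(te_intron, i)
      }

      # one planted intronic peak per gene, preferentially inside a TE
      pi_ <- if (length(te_intron)) sample(rep(te_intron, 2), 1)
             else sample(seq_len(k - 1), 1)
      i_start <- ends[pi_] + 1L; i_end <- starts[pi_ + 1] - 1L
      pw <- min(spec$peak_width, i_end - i_start - 20L)
      in_te <- pi_ %in% te_intron
      if (in_te) {
        te <- repeats[[max(which(vapply(repeats, function(r)
          r$gene == gid & r$start > ends[pi_] & r$end < starts[pi_ + 1],
          TRUE)))]]
        lo <- te$start; hi <- te$end - pw
      } else {
        lo <- i_start + 10L; hi <- i_end - 10L - pw
      }
      if (hi < lo) { lo <- i_start + 5L; hi <- max(lo, i_end - 5L - pw) }
      p_start <- lo + sample.int(max(1L, hi - lo + 1L), 1) - 1L
      peaks[[g]] <- data.frame(start = p_start, end = p_start + pw - 1L,
                               strand = strand, gene = gid,
                               peak_intron = pi_)

      truth[[g]] <- data.frame(
        gene_id = gid, strand = strand, n_exons = k,
        gene_start = gene_start, gene_end = gene_end,
        exonized = exonized[g], apa_switched = apa[g],
        peak_id = sprintf("pk_%04d", g), peak_intron = pi_,
        peak_start = p_start, peak_end = p_start + pw - 1L)
      cursor <- gene_end + spec$intergenic_gap
    }

    truth <- do.call(rbind, truth)
    gene_gr <- GenomicRanges::GRanges(
      spec$chrom, IRanges::IRanges(truth$gene_start, truth$gene_end),
      strand = truth$strand, gene_id = truth$gene_id,
      biotype = "protein_coding")
    exon_gr <- do.call(c, lapply(seq_len(n), function(g) {
      e <- exons[[g]]
      GenomicRanges::GRanges(spec$chrom, IRanges::IRanges(e$start, e$end),
                             strand = truth$strand[g],
                             gene_id = truth$gene_id[g],
                             exon_id = sprintf("%s.E%d", truth$gene_id[g],
                                               seq_len(nrow(e))))
    }))
    rep_gr <- if (length(repeats)) {
      rp <- do.call(rbind, repeats)
      GenomicRanges::GRanges(spec$chrom, IRanges::IRanges(rp$start, rp$end),
                             strand = rp$strand, family = rp$family,
                             class_name = ifelse(rp$family == "Alu", "SINE",
                                                 "LINE"))
    } else GenomicRanges::GRanges()
    pk <- do.call(rbind, peaks)
    peak_gr <- GenomicRanges::GRanges(
      spec$chrom, IRanges::IRanges(pk$start, pk$end), strand = pk$strand,
      peak_id = truth$peak_id, host_gene = pk$gene,
      sources = IRanges::CharacterList(as.list(rep("RBP1", n))),
      intronic = TRUE)

    seqs <- NULL
    if (spec$with_seqs) {
      len <- max(truth$gene_end) + 1000L
      probA <- rep(0.25, len)
      # A-rich bodies for TEs on their host gene's strand
      host_strand <- truth$strand[match(
        vapply(repeats, `[[`, "", "gene"), truth$gene_id)]
      for (i in seq_along(repeats)) {
        r <- repeats[[i]]
        if (r$strand == host_strand[i])
          probA[r$start:r$end] <- spec$te_A
      }
      other <- (1 - probA) / 3
      chars <- vapply(seq_len(len), function(i)
        sample(c("A", "C", "G", "T"), 1,
               prob = c(probA[i], other[i], other[i], other[i])), "")
      seqs <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""),
                                                spec$chrom))
    }
    genome <- AnnotatedGenome(gene_gr, exon_gr, rep_gr, seqs)
    list(genome = genome, peaks = peak_gr, truth = truth)
  })
}

sim_samples <- function(spec) {
  data.frame(sample = c(paste0("control_", seq_len(spec$n_replicates)),
                        paste0("treatment_", seq_len(spec$n_replicates))),
             condition = rep(c("control", "treatment"),
                             each = spec$n_replicates))
}

#' Simulate exon, peak and junction count tables with planted effects
#'
#' NB counts per exon, intronic peak and junction per sample. In planted
#' exonized genes the treatment peak signal is multiplied by
#' `peak_share_mult`, post-peak exon means by `post_mult`, and a novel
#' junction from the upstream exon's donor into the peak appears in
#' treatment.
#'
#' @param sim output of [simulate_genome()].
#' @param spec the same [simulation_spec()].
#' @return list(exon_counts, peak_counts, junctions (`GRanges` with
#'   `junction_id`, `novel`), junction_counts, design, mu (per-gene means)).
#' @export
simulate_counts <- function(sim, spec = simulation_spec()) {
  with_seed(spec$seed + .SIM_OFFSETS[["counts"]], {
    genome <- sim$genome; truth <- sim$truth
    des <- sim_samples(spec)
    design <- make_design(des$sample, des$condition)
    samples <- design$sample
    treat <- design$condition == "treatment"
    size <- 1 / spec$dispersion

    mu_g <- setNames(rlnorm(nrow(truth), log(spec$mean_count), spec$mu_sdlog),
                     truth$gene_id)

    ex <- genome$exons
    eid <- mcols(ex)$exon_id
    e_gene <- mcols(ex)$gene_id
    # post-peak flag per exon (transcription direction, beyond the peak)
    exon_index <- as.integer(sub(".*\\.E", "", eid))
    post <- logical(length(ex))
    for (g in which(truth$exonized)) {
      gid <- truth$gene_id[g]
      sel <- e_gene == gid
      if (truth$strand[g] == "+")
        post[sel] <- exon_index[sel] > truth$peak_intron[g]
      else post[sel] <- exon_index[sel] <= truth$peak_intron[g]
    }
    exon_mu <- mu_g[e_gene]
    exon_counts <- sapply(seq_along(samples), function(s) {
      mu <- exon_mu
      if (treat[s]) mu <- ifelse(post, mu * spec$post_mult, mu)
      rnbinom(length(mu), mu = mu, size = size)
    })
    dimnames(exon_counts) <- list(eid, samples)

    peak_mu <- spec$peak_share * mu_g[truth$gene_id]
    peak_counts <- sapply(seq_along(samples), function(s) {
      mu <- peak_mu
      if (treat[s]) mu <- ifelse(truth$exonized, mu * spec$peak_share_mult, mu)
      rnbinom(length(mu), mu = mu, size = size)
    })
    dimnames(peak_counts) <- list(truth$peak_id, samples)

    # constitutive junctions between consecutive exons + planted novel
    # junctions into the peak of exonized genes (treatment only)
    jx <- list(); jmu <- list(); jnovel <- logical(0)
    for (g in seq_len(nrow(truth))) {
      gid <- truth$gene_id[g]
      e <- sort(GenomicRanges::granges(
        genome$exons[e_gene == gid]), ignore.strand = TRUE)
      k <- length(e)
      if (k < 2) next
      jx[[length(jx) + 1L]] <- GenomicRanges::GRanges(
        spec$chrom,
        IRanges::IRanges(GenomicRanges::end(e)[-k] + 1L,
                         GenomicRanges::start(e)[-1] - 1L),
        strand = truth$strand[g])
      jmu[[length(jmu) + 1L]] <- rep(mu_g[gid], k - 1)
      jnovel <- c(jnovel, rep(FALSE, k - 1))
      if (truth$exonized[g]) {
        pi_ <- truth$peak_intron[g]
        acc_in_peak <- truth$peak_start[g] +
          min(50L, truth$peak_end[g] - truth$peak_start[g])
        novel <- if (truth$strand[g] == "+")
          GenomicRanges::GRanges(spec$chrom,
                                 IRanges::IRanges(
                                   GenomicRanges::end(e)[pi_] + 1L,
                                   acc_in_peak - 1L),
                                 strand = "+")
        else
          GenomicRanges::GRanges(spec$chrom,
                                 IRanges::IRanges(
                                   acc_in_peak + 1L,
                                   GenomicRanges::start(e)[pi_ + 1] - 1L),
                                 strand = "-")
        jx[[length(jx) + 1L]] <- novel
        jmu[[length(jmu) + 1L]] <- spec$novel_junction_share * mu_g[gid]
        jnovel <- c(jnovel, TRUE)
      }
    }
    junctions <- do.call(c, jx)
    jmu <- unlist(jmu)
    mcols(junctions)$junction_id <- sprintf("jx_%05d", seq_along(junctions))
    mcols(junctions)$novel <- jnovel
    junction_counts <- sapply(seq_along(samples), function(s) {
      mu <- jmu
      mu[jnovel] <- if (treat[s]) mu[jnovel] else 0
      ifelse(mu == 0, 0L, rnbinom(length(mu), mu = mu, size = size))
    })
    dimnames(junction_counts) <- list(mcols(junctions)$junction_id, samples)

    list(exon_counts = exon_counts, peak_counts = peak_counts,
         junctions = junctions, junction_counts = junction_counts,
         design = design, mu = mu_g)
  })
}

#' Simulate long-read 3'-end coordinates with planted polyA switches
#'
#' Each gene has a distal polyA site at its 3' end and a proximal site
#' upstream; read ends are sampled multinomially over the two isoforms
#' (70/30 baseline) with Gaussian positional jitter. In planted switched
#' genes the treatment shifts `apa_switch_pp` of the isoform mass from the
#' distal to the proximal site.
#'
#' @param sim output of [simulate_genome()].
#' @param spec the same [simulation_spec()].
#' @return data.frame (chrom, pos, strand, sample), one row per read end.
#' @export
simulate_read_ends <- function(sim, spec = simulation_spec()) {
  with_seed(spec$seed + .SIM_OFFSETS[["ends"]], {
    truth <- sim$truth
    des <- sim_samples(spec)
    base_frac <- c(distal = 0.7, proximal = 0.3)
    out <- list()
    for (g in seq_len(nrow(truth))) {
      distal <- if (truth$strand[g] == "+") truth$gene_end[g]
                else truth$gene_start[g]
      span <- truth$gene_end[g] - truth$gene_start[g]
      offs <- min(1500L, max(300L, span %/% 3))
      proximal <- if (truth$strand[g] == "+") distal - offs else distal + offs
      for (s in seq_len(nrow(des))) {
        fr <- base_frac
        if (truth$apa_switched[g] && des$condition[s] == "treatment")
          fr <- c(distal = base_frac[["distal"]] - spec$apa_switch_pp,
                  proximal = base_frac[["proximal"]] + spec$apa_switch_pp)
        n_reads <- spec$apa_reads_per_gene %/% spec$n_replicates
        k <- rmultinom(1, n_reads, fr)[, 1]
        pos <- c(rep(distal, k[1]), rep(proximal, k[2]))
        if (spec$apa_jitter_sd > 0)
          pos <- pos + pmax(-10L, pmin(10L, round(rnorm(length(pos), 0,
                                                        spec$apa_jitter_sd))))
        out[[length(out) + 1L]] <- data.frame(
          chrom = spec$chrom, pos = pmax(1L, pos), strand = truth$strand[g],
          sample = des$sample[s])
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a peak x profile count matrix with planted clusters
#'
#' Each planted cluster has one dominant profile whose counts are NB
#' around `cluster_signal`, the other profiles around
#' `cluster_background`. Peak provenance is the dominant profile, or a
#' two-profile shared set with probability `shared_source_prob`.
#'
#' @param spec a [simulation_spec()].
#' @return list(counts matrix, peaks `GRanges` (with `sources`), truth =
#'   data.frame(peak_id, cluster, dominant_profile)).
#' @export
simulate_peak_profiles <- function(spec = simulation_spec()) {
  with_seed(spec$seed + .SIM_OFFSETS[["profiles"]], {
    stopifnot(spec$n_clusters >= 1, spec$n_profiles >= spec$n_clusters)
    profiles <- paste0("RBP", seq_len(spec$n_profiles))
    n_pk <- spec$n_clusters * spec$peaks_per_cluster
    cluster <- rep(seq_len(spec$n_clusters) - 1L, each = spec$peaks_per_cluster)
    dominant <- profiles[cluster + 1L]
    size <- 1 / spec$dispersion
    counts <- sapply(profiles, function(p) {
      mu <- ifelse(dominant == p, spec$cluster_signal, spec$cluster_background)
      rnbinom(n_pk, mu = mu, size = size)
    })
    peak_id <- sprintf("peak_%05d", seq_len(n_pk))
    rownames(counts) <- peak_id
    shared <- runif(n_pk) < spec$shared_source_prob
    src <- lapply(seq_len(n_pk), function(i) {
      if (!shared[i]) return(dominant[i])
      sort(c(dominant[i], sample(setdiff(profiles, dominant[i]), 1)))
    })
    peaks <- GenomicRanges::GRanges(
      spec$chrom,
      IRanges::IRanges(seq_len(n_pk) * 1000L, width = 200L), strand = "+",
      peak_id = peak_id, sources = IRanges::CharacterList(src))
    list(counts = counts, peaks = peaks,
         truth = data.frame(peak_id = peak_id, cluster = cluster,
                            dominant_profile = dominant))
  })
}

#' Sample peaks over gene bodies with a planted coverage preference
#'
#' Draws `n` peak midpoints uniformly per base over the flattened gene
#' bodies, except that bases inside the target (family, orientation) class
#' receive `multiplier` times the baseline per-base probability; with
#' multiplier 1 the placement is uniform. This is the generator behind the
#' enrichment null and planted-signal checks: the observed TE fraction of
#' the sampled peaks converges to `multiplier` times the genomic fraction.
#'
#' Wider peaks dilute the planted multiplier: overlapping samples merge
#' during fraction computation, so coverage in the preferred class
#' saturates. The single-base default keeps the sampler faithful to its
#' contract at any density.
#'
#' @param genome an [AnnotatedGenome].
#' @param n number of peaks.
#' @param width peak width (default 1).
#' @param family target repeat family (default "L1").
#' @param orientation "sense" or "antisense" relative to the gene strand.
#' @param multiplier coverage multiplier of the target class (default 1 =
#'   uniform null).
#' @param seed RNG seed.
#' @return stranded peak `GRanges` (strand = host gene strand).
#' @export
sample_peaks_preferential <- function(genome, n, width = 1L, family = "L1",
                                      orientation = "sense", multiplier = 1,
                                      seed = 1L) {
  with_seed(seed + .SIM_OFFSETS[["peaks"]], {
    genes <- genome$genes
    # target bases: family repeats in the requested orientation, clipped to
    # gene bodies (per gene strand)
    target <- GenomicRanges::GRanges()
    for (s in c("+", "-")) {
      gs <- genes[as.character(GenomicRanges::strand(genes)) == s]
      if (!length(gs)) next
      want <- if (orientation == "sense") s else setdiff(c("+", "-"), s)
      rr <- genome$repeats[mcols(genome$repeats)$family == family &
                             as.character(GenomicRanges::strand(
                               genome$repeats)) == want]
      tg <- GenomicRanges::intersect(
        GenomicRanges::reduce(GenomicRanges::granges(gs), ignore.strand = TRUE),
        GenomicRanges::reduce(GenomicRanges::granges(rr), ignore.strand = TRUE),
        ignore.strand = TRUE)
      target <- c(target, tg)
    }
    target <- GenomicRanges::reduce(target, ignore.strand = TRUE)
    universe <- GenomicRanges::reduce(GenomicRanges::granges(genes),
                                      ignore.strand = TRUE)
    complement <- GenomicRanges::setdiff(universe, target, ignore.strand = TRUE)
    f <- sum(GenomicRanges::width(target)) / sum(GenomicRanges::width(universe))
    p_target <- min(1, multiplier * f)
    pick_pos <- function(gr, m) {
      w <- GenomicRanges::width(gr)
      seg <- sample.int(length(gr), m, replace = TRUE, prob = w)
      GenomicRanges::start(gr)[seg] +
        floor(runif(m) * w[seg])
    }
    in_target <- runif(n) < p_target
    pos <- integer(n)
    if (any(in_target)) pos[in_target] <- pick_pos(target, sum(in_target))
    if (any(!in_target)) pos[!in_target] <- pick_pos(complement,
                                                     sum(!in_target))
    half <- width %/% 2
    pk <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(genes))[1],
      IRanges::IRanges(pmax(1L, pos - half), pos - half + width - 1L))
    # strand of the host gene (peaks fall inside genes by construction)
    hit <- GenomicRanges::findOverlaps(pk, genes, select = "first",
                                       ignore.strand = TRUE)
    GenomicRanges::strand(pk) <- ifelse(
      is.na(hit), "+", as.character(GenomicRanges::strand(genes))[hit])
    pk
  })
}

#' Greedy best-match agreement between two labelings
#'
#' Matches each recovered cluster to the ground-truth cluster it overlaps
#' most (greedily, largest overlaps first) and returns the fraction of
#' points whose matched labels agree.
#'
#' @param truth,labels equal-length label vectors.
#' @return agreement fraction in \[0, 1\].
#' @export
label_agreement <- function(truth, labels) {
  stopifnot(length(truth) == length(labels))
  tab <- table(labels, truth)
  agree <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[ij[1], ij[2]]
    tab <- tab[-ij[1], -ij[2], drop = FALSE]
  }
  as.numeric(agree) / length(truth)
}

#' Write a simulated dataset to disk in pipeline input formats
#'
#' GTF + repeats BED + peaks BED, TSV count tables, SJ-dialect junction
#' files per sample, read-end TSV, design TSV and ground-truth TSV. Every
#' file a downstream reader consumes round-trips.
#'
#' @param sim [simulate_genome()] output.
#' @param counts [simulate_counts()] output.
#' @param ends optional [simulate_read_ends()] output.
#' @param dir output directory.
#' @param spec the [simulation_spec()] used (recorded in the header).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, counts, ends = NULL, dir,
                             spec = simulation_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$genome, dir)
  pk <- sim$peaks
  # name = "record_id;profile": the id keys peak_counts.tsv, the profile
  # drives peak-set merging in the workflow
  mcols(pk)$name <- paste0(
    mcols(pk)$peak_id, ";",
    vapply(mcols(pk)$sources, `[`, "", 1))
  write_bed6(pk, file.path(dir, "peaks.bed"))
  write_count_matrix(counts$exon_counts, file.path(dir, "exon_counts.tsv"))
  write_count_matrix(counts$peak_counts, file.path(dir, "peak_counts.tsv"))
  for (s in counts$design$sample)
    write_sj_tab(counts$junctions, counts$junction_counts[, s],
                 file.path(dir, paste0("SJ_", s, ".tab")))
  write.table(counts$design, file.path(dir, "design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(ends))
    write.table(ends, file.path(dir, "read_ends.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sprintf("seed\t%d", spec$seed), file.path(dir, "seed.txt"))
  invisible(dir)
}
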