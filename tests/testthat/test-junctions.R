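two_gene_genome <- function() {
  genes <- gi("chr1", c(0, 10000, 4000), c(9000, 20000, 9500), c("+", "+", "+"),
              gene_id = c("G1", "G2", "G3"), biotype = "pc")
  exons <- gi("chr1",
              c(0, 2000, 8000, 10000, 15000, 4000),
              c(500, 2500, 9000, 11000, 20000, 4500), c("+", "+", "+", "+",
                                                        "+", "+"),
              gene_id = c("G1", "G1", "G1", "G2", "G2", "G3"),
              exon_id = paste0("E", 1:6))
  AnnotatedGenome(genes, exons)
}

test_that("SJ dialect round-trips and carries unique-read counts", {
  jx <- gi("chr1", c(500, 2500), c(2000, 8000), "+")
  f <- tempfile()
  write_sj_tab(jx, c(12, 7), f)
  back <- read_sj_tab(f)
  expect_equal(grange_df(back), grange_df(jx))
  expect_equal(S4Vectors::mcols(back)$reads, c(12L, 7L))
  panel <- read_sj_panel(c(s1 = f, s2 = f))
  expect_equal(unname(panel$counts[, "s1"]), c(12L, 7L))
})

test_that("junction filter drops ambiguous hosts and weak support", {
  genome <- two_gene_genome()
  jx <- c(gi("chr1", 500, 2000, "+"),     # inside G1 only
          gi("chr1", 4600, 6000, "+"),    # inside G1 and G3: ambiguous
          gi("chr1", 11000, 15000, "+"))  # inside G2 only
  counts <- matrix(c(20, 50, 9, 50, 50, 0), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  res <- filter_junctions(jx, counts, genome, min_total_reads = 10)
  expect_length(res$junctions, 1)
  expect_equal(S4Vectors::mcols(res$junctions)$host_gene, "G1")
  # the 9-read junction (row 3) fails support; row 2 fails ambiguity
  res2 <- filter_junctions(jx, counts, genome, min_total_reads = 5)
  expect_length(res2$junctions, 2)
})

test_that("splicing index normalizes to one per site", {
  jx <- gi("chr1", c(500, 500), c(2000, 4000), "+")  # shared donor at 501
  counts <- matrix(c(80, 20, 8, 2), ncol = 2,
                   dimnames = list(NULL, c("t1", "t2")))
  si <- splicing_index(jx, counts, "donor")
  expect_equal(unname(si[, "t1"]), c(0.8, 0.2))
  expect_equal(unname(si[, "t2"]), c(0.8, 0.2))
  # single junction at a site: SI = 1; zero-total site: NA
  jx2 <- gi("chr1", 500, 3000, "-")
  si2 <- splicing_index(jx2, matrix(c(5, 0), 1), "acceptor")
  expect_equal(unname(si2[1, ]), c(1, NA))
  set.seed(601)
  for (i in 1:5) {
    df <- random_intervals(40, 50000, 3000, "+")
    jxr <- granges_of(df)
    cnt <- matrix(rpois(40 * 3, 50), ncol = 3,
                  dimnames = list(NULL, paste0("t", 1:3)))
    si <- splicing_index(jxr, cnt, "donor")
    key <- attr(si, "site_key")
    sums <- rowsum(si, key)
    per_site_n <- as.vector(table(key)[rownames(sums)])
    expect_equal(unname(sums[!is.na(sums[, 1]), 1]),
                 rep(1, sum(!is.na(sums[, 1]))))
  }
})

test_that("differential junction usage flags the planted novel junction", {
  spec <- simulation_spec(seed = 61, n_genes = 80)
  sim <- simulate_genome(spec)
  cnt <- simulate_counts(sim, spec)
  filt <- filter_junctions(cnt$junctions, cnt$junction_counts, sim$genome,
                           min_total_reads = 10)
  keep_ids <- S4Vectors::mcols(filt$junctions)$junction_id
  novel <- S4Vectors::mcols(cnt$junctions)$novel[
    match(keep_ids, S4Vectors::mcols(cnt$junctions)$junction_id)]
  res <- differential_junction_usage(filt$junctions, filt$counts, cnt$design)
  idx <- match(keep_ids, res$feature_id)
  expect_gt(mean(res$padj[idx][novel] < 0.05, na.rm = TRUE), 0.8)
  expect_true(all(res$log2fc[idx][novel] > 0, na.rm = TRUE))
  expect_lt(mean(res$padj[idx][!novel] < 0.05, na.rm = TRUE), 0.1)
})

panel_fixture <- function() {
  # gene 0..100k with annotated exon structure on +; intronic peak; donors
  genes <- gi("chrP", 0, 100000, "+", gene_id = "G1", biotype = "pc")
  exons <- gi("chrP", c(0, 30000, 60000), c(1000, 31000, 61000), "+",
              gene_id = "G1", exon_id = paste0("E", 1:3))
  genome <- AnnotatedGenome(genes, exons)
  intronic <- gi("chrP", 40000, 42000, "+", peak_id = "pk1",
                 sources = IRanges::CharacterList(list("A")),
                 host_gene = "G1", intronic = TRUE)
  list(genome = genome, intronic = intronic,
       donors = annotated_donor_sites(genome))
}

test_that("stringent panel filter keeps compliant junctions and attributes decoys", {
  fx <- panel_fixture()
  donor1 <- 1001   # after exon E1 (1-based first intronic base)
  # three compliant junctions: annotated donor, acceptor inside the peak,
  # donor shared, high SI, deep support
  mk <- function(s, e) gi("chrP", s - 1, e, "+")  # 0-based helper
  compliant <- c(mk(donor1, 40500), mk(donor1, 41000), mk(donor1, 41500))
  # decoys, each failing exactly one rule
  outside_gene <- gi("chrP", 200000, 201000, "+")        # rule: host gene
  bad_donor <- mk(20000, 40600)                           # donor unannotated
  bad_acceptor <- mk(donor1, 50000)                       # acceptor not in peak
  jx <- c(compliant, outside_gene, bad_donor, bad_acceptor)
  counts <- matrix(600, nrow = length(jx), ncol = 3,
                   dimnames = list(NULL, paste0("t", 1:3)))
  counts[] <- 6e8  # every tissue passes the 1e9 spliced-read floor
  res <- stringent_panel_filter(jx, counts, fx$genome, fx$intronic, fx$donors,
                                tissue_min = 1e9, si_min = 0.01,
                                read_min = 500)
  expect_length(res$junctions, 3)
  expect_equal(res$status[4:6],
               c("host_gene", "donor_annotated", "acceptor_in_peak"))
  expect_equal(res$status[1:3], rep("pass", 3))
  expect_equal(res$attrition$n_in[1], 6)
  expect_equal(res$attrition$n_out[nrow(res$attrition)], 3)
})

test_that("SI and support thresholds of the panel filter are sharp", {
  fx <- panel_fixture()
  donor1 <- 1001
  mk <- function(s, e) gi("chrP", s - 1, e, "+")
  jx <- c(mk(donor1, 40500), mk(donor1, 41000))
  # junction 2 has SI 0.9% in every tissue: dropped by the SI rule
  counts <- rbind(c(1e9, 1e9, 1e9), c(9.07e6, 9.07e6, 9.07e6))
  colnames(counts) <- paste0("t", 1:3)
  res <- stringent_panel_filter(jx, counts, fx$genome, fx$intronic, fx$donors)
  expect_equal(res$status[2], "si")
  # a donor used by a single junction is dropped
  solo <- mk(donor1, 40500)
  counts2 <- matrix(1e9, 1, 3, dimnames = list(NULL, paste0("t", 1:3)))
  res2 <- stringent_panel_filter(solo, counts2, fx$genome, fx$intronic,
                                 fx$donors)
  expect_equal(res2$status, "donor_multi")
  # raising read_min never grows the surviving set
  jx3 <- c(mk(donor1, 40500), mk(donor1, 41000))
  counts3 <- matrix(c(700, 700, 700, 600, 600, 600), nrow = 2, byrow = TRUE,
                    dimnames = list(NULL, paste0("t", 1:3)))
  lo <- stringent_panel_filter(jx3, counts3, fx$genome, fx$intronic,
                               fx$donors, tissue_min = 0, read_min = 100)
  hi <- stringent_panel_filter(jx3, counts3, fx$genome, fx$intronic,
                               fx$donors, tissue_min = 0, read_min = 5000)
  expect_gte(length(lo$junctions), length(hi$junctions))
})

test_that("nearest TE distances follow the exhaustive scan and the 0 rule", {
  genes <- gi("chrD", 0, 10000, "+", gene_id = "G1", biotype = "pc")
  exons <- gi("chrD", c(0, 9000), c(100, 10000), "+", gene_id = "G1")
  reps <- gi("chrD", c(2000, 5000), c(3000, 6000), c("+", "-"),
             family = c("L1", "Alu"), class_name = c("LINE", "SINE"))
  genome <- AnnotatedGenome(genes, exons, reps)
  # acceptor 10 bases upstream of the L1 start (0-based 1990 -> gap 10)
  site <- gi("chrD", 1989, 1990, "+")
  d <- nearest_te_distance(site, genome, families = c("L1", "Alu"))
  expect_equal(d$distance[d$family == "L1" & d$orientation == "sense"], 10)
  # inside the antisense Alu: distance 0
  site2 <- gi("chrD", 5500, 5501, "+")
  d2 <- nearest_te_distance(site2, genome, families = c("L1", "Alu"))
  expect_equal(d2$distance[d2$family == "Alu" &
                             d2$orientation == "antisense"], 0)
  # family absent from the gene: NA sentinel
  expect_true(is.na(d$distance[d$family == "Alu" & d$orientation == "sense"]))
  # random instances vs exhaustive oracle
  set.seed(602)
  for (i in 1:10) {
    rdf <- random_intervals(8, 9000, 500)
    rdf$chrom <- "chrD"
    rr <- granges_of(rdf)
    S4Vectors::mcols(rr)$family <- "L1"
    S4Vectors::mcols(rr)$class_name <- "LINE"
    gnm <- AnnotatedGenome(genes, exons, rr)
    pos0 <- sample(200:8800, 1)
    st <- gi("chrD", pos0, pos0 + 1, "+")
    dd <- nearest_te_distance(st, gnm, families = "L1")
    for (orient in c("sense", "antisense")) {
      want_strand <- if (orient == "sense") "+" else "-"
      sel <- rdf$strand == want_strand
      want <- if (any(sel))
        oracle_min_gap(pos0 + 1, rdf$start[sel], rdf$end[sel]) else NA_real_
      got <- dd$distance[dd$orientation == orient]
      expect_equal(got, want)
    }
  }
})

test_that("window survey finds planted sites under pluggable scorers", {
  set.seed(603)
  seqc <- paste(sample(c("A", "C", "T"), 2000, replace = TRUE), collapse = "")
  # plant AG dinucleotides at known positions (no G elsewhere -> no other AG)
  substring(seqc, 1000, 1001) <- "AG"
  substring(seqc, 1100, 1101) <- "AG"
  # indicator scorer of the planted position
  ind <- function(pos) as.numeric(pos == 1100)
  r <- window_site_survey(ind, 1100, "acceptor", seqc, window = 500, seed = 2)
  expect_true(r$novel_is_best)
  expect_equal(r$best_pos, 1100)
  r2 <- window_site_survey(ind, 1000, "acceptor", seqc, window = 500, seed = 2)
  expect_false(r2$novel_is_best)
  # constant scorer: best equals novel equals the constant
  cst <- function(pos) 0.4
  r3 <- window_site_survey(cst, 1000, "acceptor", seqc, window = 500, seed = 2)
  expect_equal(r3$novel_score, r3$best_score)
  expect_true(all(r3$random_scores == 0.4))
  # no candidate dinucleotide in the window: undefined sentinel
  seq_no <- paste(rep("C", 1200), collapse = "")
  r4 <- window_site_survey(cst, 600, "acceptor", seq_no, window = 200)
  expect_equal(r4$n_candidates, 0)
  expect_true(is.na(r4$novel_is_best))
})

test_that("the toy hexamer scorer ranks a planted strong site best", {
  set.seed(604)
  backbone <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  motif <- "AGGTAAGT"
  substring(backbone, 700, 707) <- motif
  scorer <- make_hexamer_scorer(rep(motif, 20), backbone)
  r <- window_site_survey(scorer, 702, "donor", backbone, window = 400,
                          seed = 3)
  expect_true(r$novel_is_best)
})
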