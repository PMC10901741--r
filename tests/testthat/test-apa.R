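apa_design <- make_design(c("c1", "c2", "t1"),
                          c("control", "control", "treatment"))

test_that("read-end collapse matches interval arithmetic", {
  ends <- data.frame(chrom = "chr1", pos = c(101, 141), strand = "+",
                     sample = "c1")
  r <- collapse_read_ends(ends, pad = 50)
  expect_length(r, 1)
  expect_equal(GenomicRanges::start(r), 51)
  expect_equal(GenomicRanges::end(r), 191)
  # separation beyond 2*pad yields two regions
  ends2 <- data.frame(chrom = "chr1", pos = c(101, 301), strand = "+",
                      sample = "c1")
  expect_length(collapse_read_ends(ends2, pad = 50), 2)
  # opposite strands never merge
  ends3 <- data.frame(chrom = "chr1", pos = c(101, 111),
                      strand = c("+", "-"), sample = "c1")
  expect_length(collapse_read_ends(ends3, pad = 50), 2)
})

test_that("collapse equals the per-base oracle, is order-stable and idempotent", {
  set.seed(701)
  for (i in 1:6) {
    n <- 400
    ends <- data.frame(chrom = "chrT", pos = sample.int(20000, n, TRUE) + 100,
                       strand = sample(c("+", "-"), n, TRUE),
                       sample = sample(c("c1", "t1"), n, TRUE))
    r <- collapse_read_ends(ends, pad = 50)
    padded <- data.frame(chrom = ends$chrom, start = ends$pos - 50,
                         end = ends$pos + 50, strand = ends$strand)
    want <- oracle_reduce(padded$chrom, padded$start, padded$end,
                          padded$strand)
    got <- grange_df(r)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$start, got$strand), ],
                 want[order(want$start, want$strand), ], ignore_attr = TRUE)
    # order invariance
    r2 <- collapse_read_ends(ends[sample(n), ], pad = 50)
    expect_equal(grange_df(r2), grange_df(r))
    # idempotence: collapsing the regions' own bounds changes nothing
    rr <- grange_df(GenomicRanges::reduce(r))
    rr <- rr[order(rr$start, rr$strand), ]
    self <- grange_df(r)[order(grange_df(r)$start, grange_df(r)$strand), ]
    expect_equal(rr, self, ignore_attr = TRUE)
    # every end lies in exactly one region
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(ends$chrom,
                             IRanges::IRanges(ends$pos, ends$pos),
                             strand = ends$strand), r)
    expect_equal(length(hits), n)
  }
})

test_that("end counting conserves reads per condition", {
  ends <- data.frame(chrom = "chr1",
                     pos = c(100, 105, 110, 100, 102),
                     strand = "+",
                     sample = c("c1", "c1", "c2", "t1", "t1"))
  r <- count_ends(collapse_read_ends(ends, 50), ends, apa_design)
  expect_equal(sum(S4Vectors::mcols(r)$n_control), 3)
  expect_equal(sum(S4Vectors::mcols(r)$n_treatment), 2)
  expect_error(count_ends(collapse_read_ends(ends, 50),
                          transform(ends, sample = "zz"), apa_design),
               "missing from design")
  set.seed(702)
  ends2 <- data.frame(chrom = "chrT", pos = sample.int(5000, 500, TRUE),
                      strand = "+",
                      sample = sample(c("c1", "c2", "t1"), 500, TRUE))
  r2 <- count_ends(collapse_read_ends(ends2, 50), ends2, apa_design)
  expect_equal(sum(S4Vectors::mcols(r2)$n_control),
               sum(ends2$sample %in% c("c1", "c2")))
  expect_equal(sum(S4Vectors::mcols(r2)$n_treatment),
               sum(ends2$sample == "t1"))
})

make_regions <- function(gene, nc, nt) {
  # two regions for one gene with given per-region condition counts
  r <- gi("chrA", c(1000, 3000), c(1200, 3200), "+",
          region_id = paste0(gene, c("_r1", "_r2")),
          host_gene = gene)
  S4Vectors::mcols(r)$n_control <- nc
  S4Vectors::mcols(r)$n_treatment <- nt
  r
}

test_that("differential polyA thresholds are sharp at 20 reads / 20 points", {
  # exactly 20 reads with an exact 20-pp shift: called (>= semantics)
  r <- make_regions("G1", nc = c(7, 3), nt = c(5, 5))
  res <- differential_polya(r, min_reads = 20, min_shift = 0.20)
  expect_true(res$calls$called)
  expect_equal(res$calls$max_shift, 0.20)
  # 19 reads with a 50-pp shift: never called
  r2 <- make_regions("G2", nc = c(9, 1), nt = c(4, 5))
  res2 <- differential_polya(r2)
  expect_false(res2$calls$called)
  expect_equal(res2$calls$reason, "below read support")
  # 100 reads, 70/30 vs 45/55: shift 25 pp, called
  r3 <- make_regions("G3", nc = c(35, 15), nt = c(22.5, 27.5))
  expect_true(differential_polya(r3)$calls$called)
  # identical distributions: never called
  r4 <- make_regions("G4", nc = c(30, 10), nt = c(30, 10))
  res4 <- differential_polya(r4)
  expect_false(res4$calls$called)
  expect_equal(res4$calls$max_shift, 0)
  # zero reads in one condition: not callable, with reason
  r5 <- make_regions("G5", nc = c(30, 10), nt = c(0, 0))
  res5 <- differential_polya(r5)
  expect_false(res5$calls$called)
  expect_match(res5$calls$reason, "zero reads")
})

test_that("planted polyA switches are recovered end to end", {
  spec <- simulation_spec(seed = 71, n_genes = 100)
  sim <- simulate_genome(spec)
  ends <- simulate_read_ends(sim, spec)
  des <- make_design(unique(ends$sample),
                     rep(c("control", "treatment"), each = spec$n_replicates))
  res <- apa_call(ends, sim$genome, des)
  m <- merge(res$calls, sim$truth[, c("gene_id", "apa_switched")],
             by = "gene_id")
  expect_equal(sum(m$called & m$apa_switched), sum(m$apa_switched))
  expect_lte(sum(m$called & !m$apa_switched), ceiling(0.01 * sum(!m$apa_switched)))
  # regions assigned to the right strand/gene
  expect_true(all(!is.na(S4Vectors::mcols(res$regions)$host_gene)))
})

test_that("a null switch spec yields no calls", {
  spec <- simulation_spec(seed = 72, n_genes = 60, apa_switch_pp = 0,
                          apa_switch_fraction = 0.15)
  sim <- simulate_genome(spec)
  ends <- simulate_read_ends(sim, spec)
  des <- make_design(unique(ends$sample),
                     rep(c("control", "treatment"), each = spec$n_replicates))
  res <- apa_call(ends, sim$genome, des)
  expect_equal(sum(res$calls$called), 0)
})
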