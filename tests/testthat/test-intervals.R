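test_that("interval validation rejects empty and inverted records", {
  expect_error(gi("chr1", 20, 20), "empty or inverted")
  expect_error(gi("chr1", c(5, 30), c(10, 25)), "record 2")
  expect_silent(validate_intervals(gi("chr1", 0, 1)))
  expect_error(validate_intervals(gi("chr1", 0, 10, "*"), stranded = TRUE),
               "unstranded")
})

test_that("reduce merges overlapping and touching intervals", {
  expect_length(reduce_intervals(GenomicRanges::GRanges()), 0)
  r <- reduce_intervals(gi("chr1", c(10, 15), c(20, 30), "+"))
  expect_equal(grange_df(r), data.frame(chrom = "chr1", start = 11, end = 30,
                                        strand = "+"))
  # touching intervals merge (zero min-gap semantics)
  r <- reduce_intervals(gi("chr1", c(10, 20), c(20, 30), "+"))
  expect_equal(nrow(grange_df(r)), 1)
  # strand separation
  r <- reduce_intervals(gi("chr1", c(10, 15), c(20, 30), c("+", "-")))
  expect_length(r, 2)
})

test_that("reduce matches the per-base occupancy oracle on random sets", {
  set.seed(101)
  for (i in 1:40) {
    df <- random_intervals(sample(5:60, 1))
    got <- grange_df(reduce_intervals(granges_of(df)))
    want <- oracle_reduce(df$chrom, df$start, df$end, df$strand)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$start, got$strand), ],
                 want[order(want$start, want$strand), ],
                 ignore_attr = TRUE)
  }
})

test_that("reduce is idempotent", {
  set.seed(102)
  for (i in 1:10) {
    x <- reduce_intervals(granges_of(random_intervals(30)))
    expect_identical(grange_df(reduce_intervals(x)), grange_df(x))
  }
})

test_that("flatten_gene returns the exon span and rejects exonless genes", {
  g <- flatten_gene(gi("chr1", c(100, 500), c(200, 600), "+"))
  expect_equal(grange_df(g),
               data.frame(chrom = "chr1", start = 101, end = 600,
                          strand = "+"))
  single <- gi("chr1", 100, 200, "-")
  expect_equal(grange_df(flatten_gene(single)), grange_df(single))
  expect_error(flatten_gene(GenomicRanges::GRanges()), "no exons")
  set.seed(103)
  for (i in 1:20) {
    df <- random_intervals(sample(1:8, 1), strands = "+")
    fp <- grange_df(flatten_gene(granges_of(df)))
    expect_equal(fp$start, min(df$start))
    expect_equal(fp$end, max(df$end))
  }
})

test_that("priority fragmentation follows the per-base labeling oracle", {
  fp <- gi("chrT", 0, 1000, "+")
  ex <- gi("chrT", 100, 200, "+")
  rp <- gi("chrT", 150, 400, "+")
  fr <- fragment_by_priority("G1", fp, list(exon = ex, "repeat" = rp))
  df <- grange_df(fr)
  expect_equal(df$start, c(1, 101, 201, 401))
  expect_equal(df$end, c(100, 200, 400, 1000))
  expect_equal(S4Vectors::mcols(fr)$label,
               c("intron", "exon", "repeat", "intron"))
})

test_that("fragmentation with no repeats or peaks alternates exon/intron", {
  fp <- gi("chrT", 0, 1000, "+")
  ex <- gi("chrT", c(100, 500), c(200, 600), "+")
  fr <- fragment_by_priority("G1", fp, list(exon = ex))
  expect_equal(S4Vectors::mcols(fr)$label,
               c("intron", "exon", "intron", "exon", "intron"))
  expect_equal(sum(GenomicRanges::width(fr)), 1000)
})

test_that("random fragmentations agree with the oracle at every base", {
  set.seed(104)
  for (i in 1:25) {
    fp_start <- 1L; fp_end <- 2000L
    feats_df <- list(
      exon = random_intervals(sample(1:5, 1), 1800, 300, "+"),
      "repeat" = random_intervals(sample(0:4, 1), 1800, 300, "+"),
      peak = random_intervals(sample(0:3, 1), 1800, 300, "+"))
    feats_df <- Filter(function(d) nrow(d) > 0, feats_df)
    feats_gr <- lapply(feats_df, granges_of)
    fr <- fragment_by_priority("G", gi("chrT", 0, 2000, "+"), feats_gr,
                               priority = c("exon", "repeat", "peak"))
    # reconstruct per-base labels from fragments
    got <- rep(NA_character_, 2000)
    d <- grange_df(fr)
    for (j in seq_len(nrow(d)))
      got[d$start[j]:d$end[j]] <- S4Vectors::mcols(fr)$label[j]
    want <- oracle_fragment_labels(fp_start, fp_end, feats_df,
                                   c("exon", "repeat", "peak"))
    expect_equal(got, want)
    # exact length conservation
    expect_equal(sum(GenomicRanges::width(fr)), 2000L)
    # disjointness
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("raising a label's priority never shrinks its labeled length", {
  set.seed(105)
  for (i in 1:10) {
    feats <- list(exon = granges_of(random_intervals(3, 1800, 400, "+")),
                  "repeat" = granges_of(random_intervals(3, 1800, 400, "+")))
    fp <- gi("chrT", 0, 2000, "+")
    lab_len <- function(priority) {
      fr <- fragment_by_priority("G", fp, feats, priority)
      sum(GenomicRanges::width(fr)[S4Vectors::mcols(fr)$label == "repeat"])
    }
    expect_gte(lab_len(c("repeat", "exon")), lab_len(c("exon", "repeat")))
  }
})

test_that("genome-wide fragmentation builds both counting references", {
  spec <- simulation_spec(seed = 2, n_genes = 6)
  sim <- simulate_genome(spec)
  # exon > repeat > intron reference (repeats prioritized over introns)
  fr <- fragment_genome(sim$genome, peaks = sim$peaks)
  expect_setequal(unique(S4Vectors::mcols(fr)$label),
                  c("exon", "repeat", "intron"))
  w <- tapply(GenomicRanges::width(fr), S4Vectors::mcols(fr)$host_gene, sum)
  fpw <- setNames(GenomicRanges::width(sim$genome$genes),
                  S4Vectors::mcols(sim$genome$genes)$gene_id)
  expect_equal(as.vector(w[names(fpw)]), unname(fpw))
  # exon > peak reference (exons prioritized over peaks)
  fr2 <- fragment_genome(sim$genome, peaks = sim$peaks,
                         priority = c("exon", "peak"))
  expect_setequal(unique(S4Vectors::mcols(fr2)$label),
                  c("exon", "peak", "intron"))
  # fragments are disjoint within every gene
  for (g in names(fpw)) {
    d <- grange_df(fr2[S4Vectors::mcols(fr2)$host_gene == g])
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("unknown priority labels are rejected", {
  fp <- gi("chrT", 0, 100, "+")
  expect_error(fragment_by_priority("G", fp, list(exon = gi("chrT", 1, 5, "+")),
                                    priority = c("exon", "enhancer")),
               "unknown label")
})
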