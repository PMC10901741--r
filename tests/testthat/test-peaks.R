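test_that("peak merging unions intervals and contributing profiles", {
  sets <- list(A = gi("chr1", 10, 50, "+"), B = gi("chr1", 40, 80, "+"))
  m <- merge_peak_sets(sets)
  expect_length(m, 1)
  expect_equal(grange_df(m),
               data.frame(chrom = "chr1", start = 11, end = 80, strand = "+"))
  expect_equal(sort(unlist(S4Vectors::mcols(m)$sources)), c("A", "B"))
  # opposite strands stay separate
  m2 <- merge_peak_sets(list(A = gi("chr1", 10, 50, "+"),
                             B = gi("chr1", 10, 50, "-")))
  expect_length(m2, 2)
  expect_error(merge_peak_sets(list(A = gi("chr1", 1, 5, "*"))), "unstranded")
})

test_that("merging matches the per-base oracle and conserves covered bases", {
  set.seed(201)
  for (i in 1:10) {
    sets <- lapply(setNames(1:3, c("A", "B", "C")), function(j)
      granges_of(random_intervals(60)))
    m <- merge_peak_sets(sets)
    all_df <- do.call(rbind, lapply(sets, grange_df))
    want <- oracle_reduce(all_df$chrom, all_df$start, all_df$end,
                          all_df$strand)
    got <- grange_df(m)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$start, got$strand), ],
                 want[order(want$start, want$strand), ], ignore_attr = TRUE)
    expect_equal(sum(GenomicRanges::width(m)), sum(want$end - want$start + 1))
  }
})

test_that("host assignment requires same-strand containment", {
  genes <- gi("chr1", c(0, 2000), c(1000, 3000), "+",
              gene_id = c("G1", "G2"), biotype = "pc")
  pk <- function(s, e, st = "+") {
    p <- gi("chr1", s, e, st, peak_id = "p",
            sources = IRanges::CharacterList(list("A")))
    p
  }
  expect_equal(S4Vectors::mcols(
    assign_host_genes(pk(100, 200), genes))$host_gene, "G1")
  # straddles the boundary: no host
  expect_true(is.na(S4Vectors::mcols(
    assign_host_genes(pk(900, 1100), genes))$host_gene))
  # wrong strand: no host
  expect_true(is.na(S4Vectors::mcols(
    assign_host_genes(pk(100, 200, "-"), genes))$host_gene))
  # any-overlap mode assigns the straddler
  expect_equal(S4Vectors::mcols(assign_host_genes(
    pk(900, 1100), genes, mode = "any"))$host_gene, "G1")
})

test_that("host assignment equals a brute-force containment scan", {
  set.seed(202)
  genes_df <- data.frame(chrom = "chrT",
                         start = seq(1, by = 3000, length.out = 12),
                         end = seq(2500, by = 3000, length.out = 12),
                         strand = rep(c("+", "-"), 6))
  genes <- granges_of(genes_df)
  S4Vectors::mcols(genes)$gene_id <- sprintf("G%02d", 1:12)
  for (i in 1:5) {
    pdf <- random_intervals(50, 36000, 800)
    peaks <- granges_of(pdf)
    S4Vectors::mcols(peaks)$peak_id <- sprintf("p%02d", 1:50)
    got <- S4Vectors::mcols(assign_host_genes(peaks, genes))$host_gene
    want <- vapply(seq_len(50), function(j) {
      hit <- which(pdf$start[j] >= genes_df$start &
                     pdf$end[j] <= genes_df$end &
                     pdf$strand[j] == genes_df$strand)
      if (length(hit)) sprintf("G%02d", hit[1]) else NA_character_
    }, "")
    expect_equal(got, want)
  }
})

test_that("host assignment is stable under peak permutation", {
  set.seed(203)
  genes <- gi("chrT", c(0, 5000), c(4000, 9000), "+",
              gene_id = c("G1", "G2"), biotype = "pc")
  pdf <- random_intervals(30, 9000, 500, "+")
  peaks <- granges_of(pdf)
  S4Vectors::mcols(peaks)$peak_id <- sprintf("p%02d", 1:30)
  a <- assign_host_genes(peaks, genes)
  perm <- sample(30)
  b <- assign_host_genes(peaks[perm], genes)
  expect_equal(S4Vectors::mcols(b)$host_gene[order(perm)],
               S4Vectors::mcols(a)$host_gene)
})

intronic_fixture <- function() {
  genes <- gi("chr1", 0, 2000, "+", gene_id = "G1", biotype = "pc")
  exons <- gi("chr1", c(150, 1500), c(200, 1600), "+",
              gene_id = "G1", exon_id = c("E1", "E2"))
  AnnotatedGenome(genes, exons)
}

test_that("intronic peaks subtract exonic bases", {
  genome <- intronic_fixture()
  p <- gi("chr1", 100, 300, "+", peak_id = "pk1",
          sources = IRanges::CharacterList(list("A")))
  p <- assign_host_genes(p, genome)
  ip <- intronic_peaks(p, genome)
  d <- grange_df(ip)
  # exon occupies 151..200 internally; fragments are 101..150 and 201..300
  expect_equal(d$start, c(101, 201))
  expect_equal(d$end, c(150, 300))
  expect_equal(S4Vectors::mcols(ip)$peak_id, c("pk1.1", "pk1.2"))
  expect_true(all(S4Vectors::mcols(ip)$intronic))
})

test_that("fully intronic peaks pass unchanged, fully exonic peaks vanish", {
  genome <- intronic_fixture()
  intr <- assign_host_genes(
    gi("chr1", 300, 500, "+", peak_id = "pk1",
       sources = IRanges::CharacterList(list("A"))), genome)
  out <- intronic_peaks(intr, genome)
  expect_equal(grange_df(out), grange_df(intr))
  exonic <- assign_host_genes(
    gi("chr1", 160, 190, "+", peak_id = "pk2",
       sources = IRanges::CharacterList(list("A"))), genome)
  expect_length(intronic_peaks(exonic, genome), 0)
})

test_that("intronic peaks never overlap exons and match the subtraction oracle", {
  set.seed(204)
  genome <- intronic_fixture()
  exdf <- grange_df(genome$exons)
  for (i in 1:10) {
    pdf <- random_intervals(20, 1900, 400, "+")
    pdf$chrom <- "chr1"
    peaks <- granges_of(pdf)
    S4Vectors::mcols(peaks)$peak_id <- sprintf("p%02d", 1:20)
    S4Vectors::mcols(peaks)$sources <-
      IRanges::CharacterList(as.list(rep("A", 20)))
    peaks <- assign_host_genes(peaks, genome)
    ip <- intronic_peaks(peaks, genome)
    if (length(ip))
      expect_length(IRanges::findOverlaps(ip, genome$exons), 0)
    # oracle comparison per input peak
    hosted <- which(!is.na(S4Vectors::mcols(peaks)$host_gene))
    want_total <- 0
    for (j in hosted) {
      o <- oracle_subtract(pdf$start[j], pdf$end[j], exdf$start, exdf$end)
      want_total <- want_total + sum(o$end - o$start + 1)
    }
    expect_equal(sum(GenomicRanges::width(ip)), want_total)
  }
})

test_that("peak count matrix assembles with fill-zero and rejects negatives", {
  pk <- gi("chr1", c(0, 100), c(50, 150), "+",
           peak_id = c("p1", "p2"))
  m <- build_peak_count_matrix(pk, list(A = c(p1 = 3, p2 = 1),
                                        B = c(p2 = 5)))
  expect_equal(unname(m), matrix(c(3L, 1L, 0L, 5L), 2))
  expect_equal(sum(m), 9)
  expect_error(build_peak_count_matrix(pk, list(A = c(p1 = -1))), "negative")
  expect_error(build_peak_count_matrix(pk, list(A = c(px = 1))), "unknown peak")
})
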