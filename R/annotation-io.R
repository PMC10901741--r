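# Readers and writers for gene models (GTF, GENCODE dialect), repeat
# annotations (repeatMasker .out or BED6-with-family) and peak/interval BED
# files, plus the AnnotatedGenome container they populate.

#' AnnotatedGenome container
#'
#' Bundles one assembly's gene models, repeat annotation and (optionally)
#' sequences. Genes are flattened exon unions: there is no transcript
#' isoform model, matching the flattened-gene analyses this package
#' implements.
#'
#' @param genes `GRanges` of gene footprints with `gene_id` and `biotype`.
#' @param exons `GRanges` of exons with `gene_id` (and optionally `exon_id`).
#' @param repeats `GRanges` of repeat elements with `family` and
#'   `class_name`; strand must be "+" or "-".
#' @param seqs optional `Biostrings::DNAStringSet` named by chromosome.
#' @return an object of class `AnnotatedGenome`.
#' @export
AnnotatedGenome <- function(genes, exons, repeats = GenomicRanges::GRanges(),
                            seqs = NULL) {
  validate_intervals(genes)
  validate_intervals(exons)
  if (length(repeats)) {
    validate_intervals(repeats, stranded = TRUE)
    if (is.null(mcols(repeats)$family) || any(!nzchar(mcols(repeats)$family)))
      stop_input("every repeat needs a non-empty family label")
  }
  if (is.null(mcols(genes)$gene_id)) stop_input("genes need a gene_id column")
  if (is.null(mcols(exons)$gene_id)) stop_input("exons need a gene_id column")
  orphan <- setdiff(mcols(exons)$gene_id, mcols(genes)$gene_id)
  if (length(orphan)) stop_input("exon references unknown gene '%s'", orphan[1])
  if (is.null(mcols(genes)$biotype)) mcols(genes)$biotype <- "protein_coding"
  structure(list(genes = genes, exons = exons, repeats = repeats, seqs = seqs),
            class = "AnnotatedGenome")
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf("AnnotatedGenome: %d genes, %d exons, %d repeats%s\n",
              length(x$genes), length(x$exons), length(x$repeats),
              if (is.null(x$seqs)) "" else
                sprintf(", %d sequence(s)", length(x$seqs))))
  invisible(x)
}

#' Standard-chromosome filter
#'
#' The default mirrors the usual "standard chromosomes" restriction:
#' scaffolds and alternative loci carrying "_" in their name, and
#' unplaced/random/alt contigs, are excluded.
#'
#' @param chroms character vector of chromosome names.
#' @param exclude_regex names matching this regex are dropped.
#' @return logical vector, TRUE for standard chromosomes.
#' @export
is_standard_chrom <- function(chroms, exclude_regex = "_|^chrUn|random|alt|^Un") {
  !grepl(exclude_regex, chroms)
}

#' Read gene models from GTF (GENCODE dialect)
#'
#' Uses `rtracklayer` for parsing; gene footprints are taken from `gene`
#' records when present and derived from exon spans otherwise. GTF 1-based
#' inclusive coordinates are kept in the internal 1-based representation.
#'
#' @param path GTF file.
#' @param standard_chrom_only drop non-standard chromosomes (default TRUE).
#' @param exclude_regex passed to [is_standard_chrom()].
#' @return list with `genes` and `exons` GRanges.
#' @export
read_gtf_genes <- function(path, standard_chrom_only = TRUE,
                           exclude_regex = "_|^chrUn|random|alt|^Un") {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_input("failed to parse GTF '%s': %s",
                                                path, conditionMessage(e)))
  if (standard_chrom_only)
    gr <- gr[is_standard_chrom(as.character(GenomicRanges::seqnames(gr)),
                               exclude_regex)]
  typ <- as.character(mcols(gr)$type)
  exons <- gr[typ == "exon"]
  if (length(exons) == 0) stop_input("no exon records in '%s'", path)
  ex <- GenomicRanges::granges(exons)
  mcols(ex)$gene_id <- as.character(mcols(exons)$gene_id)
  if (!is.null(mcols(exons)$exon_id))
    mcols(ex)$exon_id <- as.character(mcols(exons)$exon_id)
  generec <- gr[typ == "gene"]
  if (length(generec)) {
    genes <- GenomicRanges::granges(generec)
    mcols(genes)$gene_id <- as.character(mcols(generec)$gene_id)
    bt <- mcols(generec)$gene_type %||% mcols(generec)$gene_biotype
    mcols(genes)$biotype <- if (is.null(bt)) "protein_coding" else as.character(bt)
  } else {
    sp <- split(ex, mcols(ex)$gene_id)
    genes <- unlist(range(sp), use.names = FALSE)
    mcols(genes)$gene_id <- names(sp)
    mcols(genes)$biotype <- "protein_coding"
  }
  list(genes = genes, exons = ex)
}

#' Read a repeat annotation
#'
#' Accepts repeatMasker `.out` (auto-detected from the header or an `.out`
#' extension) or BED6 where the name field is `family` or `family;class`.
#' repeatMasker 1-based inclusive coordinates and its "C" (complement)
#' strand code are converted at this boundary.
#'
#' @param path annotation file.
#' @return `GRanges` with `family` and `class_name` metadata.
#' @export
read_repeats <- function(path) {
  first <- readLines(path, n = 1)
  rm_out <- grepl("\\.out$", path) || grepl("SW|score", first)
  if (rm_out) read_repeatmasker_out(path) else read_repeats_bed(path)
}

read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  # header: two column-name lines + one blank
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop_input("no repeat records in '%s'", path)
  fields <- strsplit(trimws(body), "\\s+")
  n <- vapply(fields, length, 1L)
  bad <- which(n < 11)
  if (length(bad)) stop_input("malformed repeatMasker line %d in '%s'",
                              bad[1] + 3L, path)
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  start <- as.integer(m[, 6]); end <- as.integer(m[, 7])
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad)) stop_input("coordinate inversion at repeatMasker line %d",
                              bad[1] + 3L)
  strand <- ifelse(m[, 9] == "C", "-", "+")
  cf <- strsplit(m[, 11], "/", fixed = TRUE)
  class_name <- vapply(cf, `[`, "", 1)
  family <- vapply(cf, function(x) if (length(x) > 1) x[2] else x[1], "")
  GenomicRanges::GRanges(m[, 5], IRanges::IRanges(start, end), strand = strand,
                         family = family, class_name = class_name,
                         rep_name = m[, 10])
}

read_repeats_bed <- function(path) {
  gr <- read_bed6(path)
  nm <- mcols(gr)$name
  parts <- strsplit(nm, ";", fixed = TRUE)
  mcols(gr)$family <- vapply(parts, `[`, "", 1)
  mcols(gr)$class_name <- vapply(parts, function(x)
    if (length(x) > 1) x[2] else NA_character_, "")
  mcols(gr)$name <- NULL
  validate_intervals(gr, stranded = TRUE)
  gr
}

#' Read a BED6 file
#'
#' BED 0-based half-open coordinates converted to the internal 1-based
#' representation; `name` and `score` kept as metadata.
#'
#' @param path BED file.
#' @return `GRanges` with `name` and `score` columns.
#' @export
read_bed6 <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = c("character", "integer", "integer", "character",
                              "character", "character"),
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand")),
    error = function(e) stop_input("failed to parse BED '%s': %s", path,
                                   conditionMessage(e)))
  bad <- which(df$start >= df$end)
  if (length(bad)) stop_input("coordinate inversion at BED line %d of '%s'",
                              bad[1], path)
  gi(df$chrom, df$start, df$end, df$strand, name = df$name, score = df$score)
}

#' Write intervals as BED6
#'
#' @param gr `GRanges`; a `name` metadata column is used if present (peak
#'   `sources` sets are collapsed with commas).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  nm <- mcols(gr)$name
  if (is.null(nm) && !is.null(mcols(gr)$sources))
    nm <- vapply(mcols(gr)$sources, function(s) paste(sort(s), collapse = ","), "")
  if (is.null(nm) && !is.null(mcols(gr)$family)) {
    nm <- mcols(gr)$family
    cl <- mcols(gr)$class_name
    if (!is.null(cl)) nm <- ifelse(is.na(cl), nm, paste(nm, cl, sep = ";"))
  }
  if (is.null(nm)) nm <- paste0("iv_", seq_along(gr))
  sc <- mcols(gr)$score %||% rep(0, length(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = sc,
                   strand = as.character(GenomicRanges::strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a gene model as GTF
#'
#' Emits `gene` and `exon` records in GENCODE-style GTF (1-based inclusive).
#'
#' @param genome an [AnnotatedGenome].
#' @param path output GTF.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genome, path) {
  attr_of <- function(gid, bt, eid = NULL) {
    a <- sprintf('gene_id "%s"; gene_type "%s";', gid, bt)
    if (!is.null(eid)) a <- paste0(a, sprintf(' exon_id "%s";', eid))
    a
  }
  g <- genome$genes
  bt_by_gene <- setNames(mcols(g)$biotype, mcols(g)$gene_id)
  glines <- sprintf("%s\ttetrap\tgene\t%d\t%d\t.\t%s\t.\t%s",
                    as.character(GenomicRanges::seqnames(g)),
                    GenomicRanges::start(g), GenomicRanges::end(g),
                    as.character(GenomicRanges::strand(g)),
                    attr_of(mcols(g)$gene_id, mcols(g)$biotype))
  e <- genome$exons
  eid <- mcols(e)$exon_id %||% paste0(mcols(e)$gene_id, ".E",
                                      seq_along(e))
  elines <- sprintf("%s\ttetrap\texon\t%d\t%d\t.\t%s\t.\t%s",
                    as.character(GenomicRanges::seqnames(e)),
                    GenomicRanges::start(e), GenomicRanges::end(e),
                    as.character(GenomicRanges::strand(e)),
                    attr_of(mcols(e)$gene_id,
                            unname(bt_by_gene[mcols(e)$gene_id]), eid))
  writeLines(c(glines, elines), path)
  invisible(path)
}

#' Read a full annotation into an AnnotatedGenome
#'
#' @param gtf_path GTF/GFF gene models.
#' @param repeat_path optional repeat annotation (repeatMasker `.out` or
#'   BED6-with-family).
#' @param fasta_path optional FASTA of chromosome sequences.
#' @param standard_chrom_only restrict to standard chromosomes.
#' @return an [AnnotatedGenome].
#' @export
read_annotation <- function(gtf_path, repeat_path = NULL, fasta_path = NULL,
                            standard_chrom_only = TRUE) {
  gm <- read_gtf_genes(gtf_path, standard_chrom_only)
  repeats <- if (!is.null(repeat_path)) read_repeats(repeat_path)
             else GenomicRanges::GRanges()
  seqs <- if (!is.null(fasta_path)) Biostrings::readDNAStringSet(fasta_path)
          else NULL
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*", "", names(seqs))
  AnnotatedGenome(gm$genes, gm$exons, repeats, seqs)
}

#' Write an AnnotatedGenome to a directory
#'
#' Emits `genes.gtf`, `repeats.bed` and (when sequences are present)
#' `genome.fa`, in the same dialects [read_annotation()] consumes.
#'
#' @param genome an [AnnotatedGenome].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(genome, file.path(dir, "genes.gtf"))
  if (length(genome$repeats))
    write_bed6(genome$repeats, file.path(dir, "repeats.bed"))
  if (!is.null(genome$seqs))
    Biostrings::writeXStringSet(genome$seqs, file.path(dir, "genome.fa"))
  invisible(dir)
}

#' Write labeled fragments as TSV
#'
#' Columns: chrom, start (0-based), end, label, source_id, host_gene,
#' strand.
#'
#' @param frags fragment `GRanges` from [fragment_by_priority()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(frags, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(frags)),
                   start = GenomicRanges::start(frags) - 1L,
                   end = GenomicRanges::end(frags),
                   label = mcols(frags)$label,
                   source_id = mcols(frags)$source_id,
                   host_gene = mcols(frags)$host_gene,
                   strand = as.character(GenomicRanges::strand(frags)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
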