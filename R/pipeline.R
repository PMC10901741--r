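# Orchestration: flat key-value configuration, the two end-to-end
# workflows (exonization and APA), and the machine-readable run manifest.

#' Pipeline configuration
#'
#' Flat key-value configuration holding input paths, the analysis
#' thresholds at their published defaults, and the seed.
#'
#' @param gtf,repeats,peaks,exon_counts,peak_counts,design,read_ends input
#'   paths (any may be NULL when the corresponding stage is not run).
#' @param min_total_reads junction/gene read filter (default 10).
#' @param peak_padj,peak_lfc,control_band classification thresholds
#'   (defaults 0.05, 2, 0.5).
#' @param apa_pad,apa_min_reads,apa_min_shift APA thresholds (defaults 50,
#'   20, 0.20).
#' @param panel_si,panel_reads stringent-panel thresholds (defaults 0.01,
#'   500).
#' @param survey_window splice-site survey window (default 500).
#' @param seed RNG seed (default 1).
#' @return list with class `pipeline_config`.
#' @export
pipeline_config <- function(gtf = NULL, repeats = NULL, peaks = NULL,
                            exon_counts = NULL, peak_counts = NULL,
                            design = NULL, read_ends = NULL,
                            min_total_reads = 10, peak_padj = 0.05,
                            peak_lfc = 2, control_band = 0.5, apa_pad = 50,
                            apa_min_reads = 20, apa_min_shift = 0.20,
                            panel_si = 0.01, panel_reads = 500,
                            survey_window = 500, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a flat key-value configuration file
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `path` / the reloaded `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  keys <- names(cfg)
  vals <- vapply(cfg, function(v) if (is.null(v)) "" else as.character(v), "")
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  defaults <- pipeline_config()
  cfg <- defaults
  for (p in kv) {
    key <- p[1]; val <- if (length(p) > 1) p[2] else ""
    if (!key %in% names(defaults)) stop_input("unknown config key '%s'", key)
    cfg[key] <- list(if (!nzchar(val)) NULL
                     else if (suppressWarnings(!is.na(as.numeric(val))))
                       as.numeric(val) else val)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

read_design_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  make_design(df$sample, df$condition)
}

run_manifest <- function(cfg, outputs) {
  list(tool = "tetrap", version = as.character(packageVersion("tetrap")),
       seed = cfg$seed,
       thresholds = cfg[setdiff(names(cfg),
                                c("gtf", "repeats", "peaks", "exon_counts",
                                  "peak_counts", "design", "read_ends"))],
       config_digest = object_digest(cfg[order(names(cfg))]),
       outputs = outputs)
}

write_manifest <- function(manifest, path) {
  flat <- c(sprintf("tool=%s", manifest$tool),
            sprintf("version=%s", manifest$version),
            sprintf("seed=%s", manifest$seed),
            sprintf("config_digest=%s", manifest$config_digest),
            vapply(names(manifest$thresholds), function(k)
              sprintf("threshold.%s=%s", k,
                      paste(manifest$thresholds[[k]], collapse = ",")), ""),
            sprintf("output=%s", manifest$outputs))
  writeLines(flat, path)
  invisible(path)
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop_input("missing input: %s (%s)", what, path %||% "<unset>")
  path
}

#' Run the exonization workflow
#'
#' Reads annotation, peak sets and count tables from the configuration,
#' merges and host-assigns peaks, derives the intronic peak set, runs the
#' usage scan / fragmentation / classification chain, and writes merged
#' peaks (BED6), intronic peaks (BED6), the per-gene classification TSV
#' and a run manifest to `out_dir`. Deterministic stages are bit-identical
#' across reruns with the same inputs.
#'
#' @param cfg a [pipeline_config()] with gtf, peaks, exon_counts,
#'   peak_counts and design set.
#' @param out_dir output directory.
#' @return the classification data.frame, invisibly; files in `out_dir`.
#' @export
run_exonization_workflow <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gtf_path <- require_input(cfg$gtf, "gtf")
  genome <- read_annotation(gtf_path, cfg$repeats)
  design <- read_design_tsv(require_input(cfg$design, "design"))
  raw_peaks <- read_bed6(require_input(cfg$peaks, "peaks"))
  if (length(raw_peaks) == 0) {
    warning("empty peak file: writing empty classification")
    empty <- data.frame(gene_id = character(), label = character())
    write.table(empty, file.path(out_dir, "classification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_manifest(run_manifest(cfg, "classification.tsv"),
                   file.path(out_dir, "manifest.txt"))
    return(invisible(empty))
  }
  # BED name field: "record_id;profile" (plain names fall back to one
  # anonymous profile); the record_id keys the peak count table
  parts <- strsplit(mcols(raw_peaks)$name, ";", fixed = TRUE)
  rec_id <- vapply(parts, `[`, "", 1)
  profile <- vapply(parts, function(x) if (length(x) > 1) x[2] else "P1", "")
  mcols(raw_peaks)$rec_id <- rec_id
  sets <- split(GenomicRanges::granges(raw_peaks), profile)
  merged <- merge_peak_sets(as.list(sets))
  merged <- assign_host_genes(merged, genome)
  intr <- intronic_peaks(merged, genome)
  write_bed6(merged, file.path(out_dir, "merged_peaks.bed"))
  write_bed6(intr, file.path(out_dir, "intronic_peaks.bed"))

  exon_counts <- read_count_matrix(require_input(cfg$exon_counts,
                                                 "exon_counts"))
  peak_counts <- read_count_matrix(require_input(cfg$peak_counts,
                                                 "peak_counts"))
  # counts are keyed by input record id: attribute each intronic fragment
  # to the input record it overlaps most
  ov <- GenomicRanges::findOverlaps(intr, raw_peaks)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(
    intr[queryHits(ov)], raw_peaks[subjectHits(ov)]))
  best <- tapply(seq_along(ov), queryHits(ov), function(i) i[which.max(ow[i])])
  frag_rec <- rep(NA_character_, length(intr))
  frag_rec[as.integer(names(best))] <-
    mcols(raw_peaks)$rec_id[subjectHits(ov)[unlist(best)]]
  keep <- !is.na(frag_rec) & frag_rec %in% rownames(peak_counts)
  intr <- intr[keep]
  pc <- peak_counts[frag_rec[keep], , drop = FALSE]
  rownames(pc) <- mcols(intr)$peak_id
  res <- exonization_scan(genome, intr, exon_counts, pc, design,
                          padj_cut = cfg$peak_padj, up_lfc = cfg$peak_lfc,
                          control_band = cfg$control_band)
  write.table(res$classification, file.path(out_dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$prepost, file.path(out_dir, "prepost.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(run_manifest(cfg, "classification.tsv,prepost.tsv"),
                 file.path(out_dir, "manifest.txt"))
  invisible(res$classification)
}

#' Run the APA workflow
#'
#' Reads annotation, read ends and design, collapses read ends into polyA
#' regions, counts per condition, and writes regions (BED6), per-gene
#' calls and a manifest.
#'
#' @param cfg a [pipeline_config()] with gtf, read_ends and design set.
#' @param out_dir output directory.
#' @return the calls data.frame, invisibly.
#' @export
run_apa_workflow <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gtf_path <- require_input(cfg$gtf, "gtf")
  genome <- read_annotation(gtf_path, cfg$repeats)
  design <- read_design_tsv(require_input(cfg$design, "design"))
  ends <- read_read_ends(require_input(cfg$read_ends, "read_ends"))
  res <- apa_call(ends, genome, design, pad = cfg$apa_pad,
                  min_reads = cfg$apa_min_reads,
                  min_shift = cfg$apa_min_shift)
  mcols(res$regions)$name <- mcols(res$regions)$region_id
  write_bed6(res$regions, file.path(out_dir, "polya_regions.bed"))
  write.table(res$calls, file.path(out_dir, "apa_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$fractions, file.path(out_dir, "apa_fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(run_manifest(cfg, "apa_calls.tsv,apa_fractions.tsv"),
                 file.path(out_dir, "manifest.txt"))
  invisible(res$calls)
}
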