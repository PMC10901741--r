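# Peak-space analysis: column standardization of the unified peak x
# profile matrix, pluggable 2-D embedding and clustering, per-cluster
# provenance attribution and TE composition.

#' Column-standardize a count matrix
#'
#' Per-profile standardization to mean 0 and (population) standard
#' deviation 1; constant columns become all-zero and are flagged in the
#' `constant_columns` attribute.
#'
#' @param m peak x profile matrix (>= 2 rows and columns).
#' @return scaled numeric matrix with attribute `constant_columns`.
#' @export
scale_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  const <- sdev == 0
  sdev[const] <- 1
  out <- sweep(sweep(m, 2, mu), 2, sdev, "/")
  out[, const] <- 0
  attr(out, "constant_columns") <- colnames(m)[const] %||% which(const)
  out
}

#' PCA embedder factory
#'
#' Returns an embedder for [embed_and_cluster()]: principal-component
#' projection to `n` dimensions.
#'
#' @param n number of components (default 2).
#' @return function(matrix) -> coordinate matrix.
#' @export
pca_embedder <- function(n = 2) {
  function(m) {
    p <- prcomp(m, center = FALSE, scale. = FALSE)
    p$x[, seq_len(min(n, ncol(p$x))), drop = FALSE]
  }
}

#' k-means clusterer factory
#'
#' Returns a clusterer for [embed_and_cluster()]: k-means with `k` centers
#' on the (embedded or scaled) matrix, labels 0-based to match the
#' density-clustering convention where -1 marks noise (k-means emits no
#' noise).
#'
#' @param k number of clusters.
#' @param nstart restarts (default 10).
#' @return function(matrix) -> integer labels.
#' @export
kmeans_clusterer <- function(k, nstart = 10) {
  function(m) kmeans(m, centers = k, nstart = nstart)$cluster - 1L
}

#' Embed and cluster a scaled peak matrix
#'
#' Both algorithms are injected: `embedder(matrix)` returns 2-D (or n-D)
#' coordinates for plotting, `clusterer(matrix)` returns one integer label
#' per peak with -1 for noise. The clusterer runs on the scaled matrix
#' (mirroring the scheme where the plotting embedding and the clustering
#' space are decoupled). Deterministic under the fixed seed.
#'
#' @param scaled matrix from [scale_matrix()].
#' @param embedder function(matrix) -> coordinates; default [pca_embedder()].
#' @param clusterer function(matrix) -> labels; default
#'   [kmeans_clusterer()] with k = 3.
#' @param seed RNG seed.
#' @return list(coords, labels).
#' @export
embed_and_cluster <- function(scaled, embedder = pca_embedder(2),
                              clusterer = kmeans_clusterer(3), seed = 1) {
  coords <- with_seed(seed, embedder(scaled))
  labels <- with_seed(seed + 1L, clusterer(scaled))
  if (length(labels) != nrow(scaled))
    stop_input("clusterer returned %d labels for %d peaks", length(labels),
               nrow(scaled))
  list(coords = coords, labels = as.integer(labels))
}

#' Per-cluster provenance attribution
#'
#' For each cluster and profile: the fraction of cluster peaks whose source
#' set is exactly that profile (`exclusive_fraction`), the fraction whose
#' source set contains it (`participating_fraction`, which counts shared
#' peaks towards every contributing profile), and the overall fraction of
#' shared (multi-profile) peaks.
#'
#' @param labels integer cluster labels (-1 = noise), one per peak.
#' @param peaks peak `GRanges` with a `sources` CharacterList column.
#' @return data.frame (cluster, n_peaks, profile, exclusive_fraction,
#'   participating_fraction, shared_fraction).
#' @export
cluster_provenance <- function(labels, peaks) {
  if (length(labels) != length(peaks))
    stop_input("label count (%d) != peak count (%d)", length(labels),
               length(peaks))
  src <- mcols(peaks)$sources
  nsrc <- lengths(src)
  solo <- ifelse(nsrc == 1, vapply(src, `[`, "", 1), NA_character_)
  profs <- sort(unique(unlist(src)))
  do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    in_cl <- which(labels == cl)
    n <- length(in_cl)
    shared <- mean(nsrc[in_cl] > 1)
    data.frame(cluster = cl, n_peaks = n, profile = profs,
               exclusive_fraction = vapply(profs, function(p)
                 sum(!is.na(solo[in_cl]) & solo[in_cl] == p) / n, 0),
               participating_fraction = vapply(profs, function(p)
                 sum(vapply(src[in_cl], function(s) p %in% s, TRUE)) / n, 0),
               shared_fraction = shared)
  }))
}

#' Per-cluster TE composition
#'
#' TE family enrichment of each cluster's peaks relative to the full peak
#' universe (log2 observed/expected fractions).
#'
#' @param labels integer cluster labels.
#' @param peaks peak `GRanges` (stranded).
#' @param repeats repeat `GRanges` with `family`.
#' @param families families to tabulate (default: all present).
#' @return data.frame with a `cluster` column prepended to
#'   [log2_enrichment()] output; empty clusters are skipped.
#' @export
cluster_te_composition <- function(labels, peaks, repeats, families = NULL) {
  if (is.null(families)) families <- sort(unique(mcols(repeats)$family))
  background <- te_fractions(peaks, repeats, families)
  do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    sel <- peaks[labels == cl]
    if (length(sel) == 0) return(NULL)
    enr <- log2_enrichment(te_fractions(sel, repeats, families), background)
    cbind(cluster = cl, enr)
  }))
}
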