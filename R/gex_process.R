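## Minimal transcriptome processing contract: mito filtering, receptor-gene
## removal, normalization, graph clustering, and barcode matching against a
## V(D)J repertoire.

#' Remove cells with excessive mitochondrial content
#'
#' Drops cells whose fraction of UMIs on mitochondrial genes (gene symbols
#' starting with `mito_prefix`) is strictly greater than `max_fraction`.
#' A cell exactly at the boundary is retained.
#'
#' @param counts Genes x cells count matrix.
#' @param max_fraction Maximum tolerated mitochondrial UMI fraction
#'   (default 0.20).
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @return The column-filtered matrix. If no mitochondrial genes are found
#'   a warning is raised and nothing is removed.
#' @export
filter_cells_by_mito <- function(counts, max_fraction = 0.20, mito_prefix = "MT-") {
  stopifnot(max_fraction >= 0, max_fraction <= 1)
  mito <- startsWith(rownames(counts), mito_prefix)
  if (!any(mito)) {
    warning("no genes with prefix '", mito_prefix, "' found; no cells removed")
    return(counts)
  }
  tot <- Matrix::colSums(counts)
  mt <- Matrix::colSums(counts[mito, , drop = FALSE])
  frac <- ifelse(tot > 0, mt / tot, 0)
  counts[, frac <= max_fraction, drop = FALSE]
}

#' Remove B- and T-cell receptor segment genes
#'
#' Drops genes matching immunoglobulin or T-cell receptor segment patterns
#' (`IGHV...`, `IGKJ...`, `IGHA/IGHG/...` constant genes, `TRBV...`,
#' `TRAC`, ...), which would otherwise let clonotype identity drive the
#' transcriptional clustering. Non-receptor genes such as `IGF1` are kept.
#'
#' @param counts Genes x cells count matrix.
#' @return The row-filtered matrix, with attribute `n_removed`.
#' @export
remove_vdj_genes <- function(counts) {
  pat <- "^(IG[HKL][VDJ]|IGH[ADEGM]|TR[ABGD][VDJC])"
  drop <- grepl(pat, rownames(counts))
  out <- counts[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Library-size normalization with log transform
#'
#' Scales every cell to `scale_factor` total counts and applies `log1p` —
#' the standard counts-per-10k log-normalization.
#'
#' @param counts Genes x cells count matrix.
#' @param scale_factor Per-cell total after scaling (default 1e4).
#' @return A dense or sparse matrix of log-normalized values.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  sf <- scale_factor / tot
  log1p(Matrix::t(Matrix::t(counts) * sf))
}

#' Cluster cells on gene expression
#'
#' A contract over standard scRNA-seq machinery: log-normalize, select the
#' `n_hvg` most variable genes, reduce to `n_pcs` principal components, and
#' cluster a shared-nearest-neighbor graph with multilevel (Louvain)
#' modularity optimization at the given resolution. Deterministic under a
#' fixed seed. Correctness is asserted on planted-cluster fixtures
#' (adjusted Rand index against the planted labels), not bit-level.
#'
#' @param counts Genes x cells count matrix.
#' @param n_hvg Number of highly variable genes (default 2000; capped at
#'   the gene count with a warning).
#' @param n_pcs Number of principal components (default 10).
#' @param resolution Modularity resolution (default 0.5).
#' @param k Neighbors for the SNN graph (default 10, capped at n cells - 1).
#' @param seed Random seed (default 42).
#' @return A `cell_annotation` data frame: `barcode`, `cluster` (integer,
#'   0-based like the common toolkits), `phenotype` (`"unclassified"`),
#'   `in_vdj` (`NA` until [match_barcodes()]).
#' @export
cluster_cells <- function(counts, n_hvg = 2000, n_pcs = 10, resolution = 0.5,
                          k = 10, seed = 42) {
  if (ncol(counts) < 2) stop("need at least two cells")
  norm <- normalize_counts(counts)
  v <- apply(as.matrix(norm), 1, var)
  if (n_hvg > length(v)) {
    warning("fewer genes than n_hvg; using all ", length(v), " genes")
    n_hvg <- length(v)
  }
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(n_hvg)]
  x <- t(as.matrix(norm[hvg, , drop = FALSE]))
  if (all(v[hvg] == 0)) {
    cluster <- rep(0L, ncol(counts))   # identical cells: one cluster
  } else {
    n_pcs <- min(n_pcs, ncol(x) - 1, nrow(x) - 1)
    pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
    k <- min(k, nrow(pc) - 1)
    g <- snn_graph(pc, k)
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    cluster <- relabel_by_size(igraph::membership(cl))
  }
  data.frame(barcode = colnames(counts), cluster = cluster,
             phenotype = "unclassified", in_vdj = NA,
             stringsAsFactors = FALSE)
}

## shared-nearest-neighbor graph, Jaccard-weighted, as in the common
## scRNA toolkits
snn_graph <- function(pc, k) {
  d <- as.matrix(dist(pc))
  n <- nrow(d)
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) adj[i, nn[i, ]] <- 1
  shared <- adj %*% t(adj)
  union_size <- outer(rowSums(adj), rowSums(adj), "+") - shared
  w <- shared / union_size
  w[adj == 0 & t(adj) == 0] <- 0          # keep only kNN-connected pairs
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "max", weighted = TRUE)
}

## clusters renumbered 0,1,2,... by decreasing size (ties by first member)
relabel_by_size <- function(membership) {
  tab <- sort(table(membership), decreasing = TRUE)
  map <- setNames(seq_along(tab) - 1L, names(tab))
  unname(map[as.character(membership)])
}

#' Match GEX barcodes against a V(D)J repertoire
#'
#' Sets `in_vdj` on a cell annotation by intersecting barcodes with the
#' repertoire's paired cells, after normalizing a trailing `-<digit>`
#' suffix on both sides (cellranger appends lane suffixes to GEX barcodes).
#'
#' @param repertoire A `repertoire`.
#' @param annotation A `cell_annotation` data frame (see [cluster_cells()]).
#' @return The annotation with `in_vdj` filled in.
#' @export
match_barcodes <- function(repertoire, annotation) {
  vdj <- normalize_barcode(repertoire$cells$barcode)
  gex <- normalize_barcode(annotation$barcode)
  annotation$in_vdj <- gex %in% vdj
  if (nrow(annotation) > 0 && length(vdj) > 0 && !any(annotation$in_vdj)) {
    stop("no barcode overlap between GEX and VDJ; check barcode suffixes")
  }
  annotation
}

normalize_barcode <- function(x) sub("-[0-9]+$", "", x)

#' Transcriptional-cluster membership of the most expanded clones
#'
#' For each of the `top_n` most expanded clones, the fraction of its
#' GEX-matched cells falling in each transcriptional cluster. Only cells
#' found in both the V(D)J and GEX data are counted; rows sum to 1. Clones
#' with no matched cells are omitted with a warning.
#'
#' @param clonotypes A `clonotype_tbl`.
#' @param annotation A `cell_annotation` with `in_vdj` set.
#' @param top_n Number of expanded clones (default 10).
#' @return Numeric matrix, clones x clusters.
#' @export
cluster_membership_per_clone <- function(clonotypes, annotation, top_n = 10) {
  if (all(is.na(annotation$in_vdj))) stop("run match_barcodes() first")
  top <- rank_clones(clonotypes, top_n)
  ann <- annotation[annotation$in_vdj, , drop = FALSE]
  ann$norm_bc <- normalize_barcode(ann$barcode)
  clusters <- sort(unique(annotation$cluster))
  mat <- matrix(NA_real_, nrow(top), length(clusters),
                dimnames = list(top$clonotype_id, clusters))
  for (i in seq_len(nrow(top))) {
    bcs <- normalize_barcode(top$barcodes[[i]])
    hits <- ann$cluster[ann$norm_bc %in% bcs]
    if (length(hits) == 0) next
    tab <- table(factor(hits, levels = clusters))
    mat[i, ] <- as.numeric(tab) / length(hits)
  }
  drop <- apply(mat, 1, function(r) all(is.na(r)))
  if (any(drop)) {
    warning(sum(drop), " clone(s) had no GEX-matched cells and were omitted")
  }
  mat[!drop, , drop = FALSE]
}

#' Per-sample cluster membership
#'
#' Fraction of each sample's cells per transcriptional cluster (the
#' whole-repertoire counterpart of [cluster_membership_per_clone()]).
#' Rows sum to 1.
#'
#' @param annotation A `cell_annotation` with a `sample_id` column.
#' @return Numeric matrix, samples x clusters.
#' @export
sample_cluster_membership <- function(annotation) {
  stopifnot("sample_id" %in% names(annotation))
  tab <- table(annotation$sample_id, annotation$cluster)
  sweep(unclass(tab), 1, rowSums(tab), "/")
}
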