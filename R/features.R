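## Clone-level descriptive statistics of a repertoire.

#' Isotype composition of the most expanded clones
#'
#' Counts cells of each isotype within each of the `top_n` most expanded
#' clones. Cells of one clone may span several isotypes (class-switched
#' variants sharing a CDR3 pair). Row sums equal clone sizes.
#'
#' @param clonotypes A ranked `clonotype_tbl` (see [rank_clones()]).
#' @param repertoire The `repertoire` the clones were called on (isotypes
#'   live on cells, not clones). Must be a B-cell repertoire.
#' @param top_n Number of top clones to tabulate (default 30).
#' @return An integer matrix, clones (rows, named by clonotype id) by
#'   isotype (columns).
#' @export
isotype_per_clone <- function(clonotypes, repertoire, top_n = 30) {
  cells <- repertoire$cells
  if (nrow(cells) > 0 && all(cells$isotype == "TR")) {
    stop("T-cell repertoire: TR constant genes carry no antibody isotype")
  }
  top <- rank_clones(clonotypes, top_n)
  iso_of <- setNames(cells$isotype, cells$barcode)
  mat <- matrix(0L, nrow = nrow(top), ncol = length(ISOTYPES),
                dimnames = list(top$clonotype_id, ISOTYPES))
  for (i in seq_len(nrow(top))) {
    tab <- table(iso_of[top$barcodes[[i]]])
    mat[i, names(tab)] <- as.integer(tab)
  }
  mat
}

#' Combined CDR3 length distribution at the clone level
#'
#' Histogram of `nchar(CDRH3 aa) + nchar(CDRL3 aa)` over clones (each clone
#' counted once via its representative sequences).
#'
#' @param clonotypes A `clonotype_tbl`.
#' @return Named integer vector: combined length -> clone count, ascending
#'   by length.
#' @export
cdr3_length_distribution <- function(clonotypes) {
  if (nrow(clonotypes) == 0) return(setNames(integer(), character()))
  len <- nchar(clonotypes$cdr3h_aa) + nchar(clonotypes$cdr3l_aa)
  tab <- table(len)
  setNames(as.integer(tab), names(tab))
}

#' Position probability matrix of equal-length amino-acid sequences
#'
#' Per-position residue frequencies, the matrix behind a probability-scaled
#' sequence logo. Every column sums to 1.
#'
#' @param sequences Character vector of amino-acid strings, all the same
#'   length `L >= 1`.
#' @param alphabet Residue alphabet (default the 20 standard amino acids).
#'   Residues outside the alphabet are added as extra rows.
#' @return Numeric matrix, residues (rows) by positions (columns `1..L`).
#' @export
position_probability_matrix <- function(sequences,
                                        alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  if (length(sequences) == 0) stop("no sequences supplied")
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("sequences must all have the same length")
  if (L < 1) stop("sequences must be non-empty")
  chars <- do.call(rbind, strsplit(sequences, ""))
  alphabet <- union(alphabet, sort(unique(as.vector(chars))))
  mat <- vapply(seq_len(L), function(p) {
    tab <- table(factor(chars[, p], levels = alphabet))
    as.numeric(tab) / length(sequences)
  }, numeric(length(alphabet)))
  dimnames(mat) <- list(alphabet, seq_len(L))
  mat
}

#' V-J gene pairing counts for the most expanded clones
#'
#' Tabulates V-J gene pairs of one chain among the `top_n_clones` most
#' expanded clones, the count matrix behind a circos-style pairing plot.
#' With `cell_level = TRUE` each cell contributes one count; otherwise each
#' clone contributes one. Pairs below `count_threshold` are dropped from
#' the matrix; the returned `label` attribute marks pairs at or above
#' `label_threshold` (the ones a plot would annotate).
#'
#' @param clonotypes A `clonotype_tbl`.
#' @param chain `"heavy"` or `"light"`.
#' @param top_n_clones Number of expanded clones to include (default 10).
#' @param cell_level Count cells (`TRUE`, default) or clones.
#' @param count_threshold Minimum count kept (default 1).
#' @param label_threshold Count at which a pair is flagged for labeling
#'   (default 50).
#' @return Integer matrix V genes x J genes with attribute `label`
#'   (logical matrix of the same shape).
#' @export
vj_pairing_counts <- function(clonotypes, chain = c("heavy", "light"),
                              top_n_clones = 10, cell_level = TRUE,
                              count_threshold = 1, label_threshold = 50) {
  chain <- match.arg(chain)
  top <- rank_clones(clonotypes, top_n_clones)
  v <- top[[if (chain == "heavy") "hv" else "lv"]]
  j <- top[[if (chain == "heavy") "hj" else "lj"]]
  w <- if (cell_level) top$size else rep(1L, nrow(top))
  tab <- tapply(w, list(V = v, J = j), sum)
  tab[is.na(tab)] <- 0L
  mat <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  keep_v <- rowSums(mat >= count_threshold) > 0
  keep_j <- colSums(mat >= count_threshold) > 0
  mat <- mat[keep_v, keep_j, drop = FALSE]
  mat[mat < count_threshold] <- 0L
  label <- mat >= label_threshold
  attr(mat, "label") <- label
  mat
}

#' Heavy-chain V gene usage
#'
#' Counts usage of heavy-chain V genes, at the clone level (each clone once)
#' or the cell level, and returns the `top_n_genes` most used in descending
#' order (ties lexicographic).
#'
#' @param clonotypes A `clonotype_tbl`, or a list of them (one per sample)
#'   for a stacked multi-sample comparison.
#' @param top_n_genes Number of genes to keep (default 10).
#' @param clone_level Count clones (`TRUE`, default) or cells.
#' @return For a single table: named integer vector gene -> count. For a
#'   list: a matrix sample x gene over the union of each sample's top genes.
#' @export
vgene_usage <- function(clonotypes, top_n_genes = 10, clone_level = TRUE) {
  if (is.data.frame(clonotypes)) {
    return(vgene_usage_one(clonotypes, top_n_genes, clone_level))
  }
  per_sample <- lapply(clonotypes, vgene_usage_one, top_n_genes, clone_level)
  genes <- sort(unique(unlist(lapply(per_sample, names))))
  full <- lapply(clonotypes, vgene_usage_one, Inf, clone_level)
  out <- t(vapply(full, function(u) {
    v <- setNames(rep(0L, length(genes)), genes)
    hit <- intersect(names(u), genes)
    v[hit] <- u[hit]
    v
  }, integer(length(genes))))
  rownames(out) <- names(clonotypes)
  out
}

vgene_usage_one <- function(clonotypes, top_n_genes, clone_level) {
  w <- if (clone_level) rep(1L, nrow(clonotypes)) else clonotypes$size
  tab <- tapply(w, clonotypes$hv, sum)
  tab <- tab[order(-tab, names(tab))]
  out <- setNames(as.integer(tab), names(tab))
  head(out, min(length(out), top_n_genes))
}

#' Clonal diversity indices
#'
#' Diversity of the clone-size distribution. With proportions
#' \eqn{p_i = n_i / \sum n_i}: Shannon entropy \eqn{-\sum p_i \ln p_i}
#' (natural log), Simpson concentration \eqn{\sum p_i^2}, and Gini-Simpson
#' diversity \eqn{1 - \sum p_i^2}.
#'
#' @param clone_sizes Positive integer vector of clone sizes (at least one).
#' @param metric `"shannon"`, `"simpson"` or `"gini_simpson"`.
#' @return A non-negative number.
#' @examples
#' diversity(c(2, 1, 1), "shannon")  # 1.0397 nats
#' @export
diversity <- function(clone_sizes, metric = c("shannon", "simpson", "gini_simpson")) {
  metric <- match.arg(metric)
  if (length(clone_sizes) == 0) stop("at least one clone size is required")
  stopifnot(all(clone_sizes > 0))
  p <- clone_sizes / sum(clone_sizes)
  switch(metric,
         shannon = -sum(p * log(p)),
         simpson = sum(p^2),
         gini_simpson = 1 - sum(p^2))
}
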