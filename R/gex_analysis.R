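## Phenotype labeling, expanded-vs-unexpanded differential expression, and
## gene-set enrichment (hypergeometric and preranked GSEA).

#' Marker-based phenotype definitions
#'
#' A phenotype definition is a list with `label`, `positive` (genes that
#' must be detected) and `zero` (genes that must not be detected). The
#' default pair distinguishes memory-like CD8 T cells
#' (CD8A+, CD44+, SELL+, IL7R+, CCL5-) from effector-like ones
#' (CD8A+, CD44+, SELL-, IL7R-, CCL5+).
#'
#' @return A list of phenotype definitions.
#' @export
default_phenotypes <- function() {
  list(
    list(label = "memory_like",
         positive = c("CD8A", "CD44", "SELL", "IL7R"), zero = "CCL5"),
    list(label = "effector_like",
         positive = c("CD8A", "CD44", "CCL5"), zero = c("SELL", "IL7R"))
  )
}

#' Label cells with marker-defined phenotypes
#'
#' A cell is "positive" for a gene when its raw count exceeds
#' `positive_threshold` (default 0, i.e. any detection — appropriate for
#' the low RNA counts of droplet scSeq). Definitions are tested in order
#' and the first full match wins; cells matching none stay
#' `"unclassified"`. Genes absent from the matrix are treated as all-zero
#' with a warning.
#'
#' @param annotation A `cell_annotation`.
#' @param counts Genes x cells raw count matrix.
#' @param definitions List of phenotype definitions
#'   (default [default_phenotypes()]).
#' @param positive_threshold Count strictly above which a gene is called
#'   detected (default 0).
#' @return The annotation with `phenotype` filled in.
#' @export
assign_phenotype <- function(annotation, counts,
                             definitions = default_phenotypes(),
                             positive_threshold = 0) {
  if (length(definitions) == 0) stop("no phenotype definitions supplied")
  genes <- unique(unlist(lapply(definitions, function(d) c(d$positive, d$zero))))
  missing <- setdiff(genes, rownames(counts))
  if (length(missing)) {
    warning("gene(s) absent from matrix treated as zero: ",
            paste(missing, collapse = ", "))
  }
  detected <- function(g) {
    if (g %in% rownames(counts)) {
      as.vector(counts[g, annotation$barcode] > positive_threshold)
    } else rep(FALSE, nrow(annotation))
  }
  det <- vapply(genes, detected, logical(nrow(annotation)))
  if (nrow(annotation) == 1) det <- matrix(det, nrow = 1, dimnames = list(NULL, genes))
  phen <- rep("unclassified", nrow(annotation))
  for (d in definitions) {
    ok <- rep(TRUE, nrow(annotation))
    for (g in d$positive) ok <- ok & det[, g]
    for (g in d$zero) ok <- ok & !det[, g]
    unset <- phen == "unclassified"
    phen[unset & ok] <- d$label
  }
  annotation$phenotype <- phen
  annotation
}

#' Differential expression between expanded and unexpanded clones
#'
#' Splits GEX-matched cells into members of expanded clones (size > 1) and
#' unexpanded clones (size == 1), then tests every gene with a Wilcoxon
#' rank-sum test on log-normalized expression. The average log fold-change
#' is the difference of group means of `log1p` counts-per-10k; p-values are
#' Benjamini-Hochberg adjusted. Sorting by `avg_logFC` gives the "top
#' upregulated in expanded clones" view.
#'
#' @param counts Genes x cells raw count matrix.
#' @param clonotypes A `clonotype_tbl`.
#' @param annotation A `cell_annotation` with `in_vdj` set.
#' @return Data frame with `gene`, `avg_logFC`, `p`, `p_adj`, sorted by
#'   decreasing `avg_logFC`.
#' @export
de_expanded_vs_unexpanded <- function(counts, clonotypes, annotation) {
  ann <- annotation[annotation$in_vdj, , drop = FALSE]
  ann$norm_bc <- normalize_barcode(ann$barcode)
  exp_bc <- normalize_barcode(unlist(clonotypes$barcodes[clonotypes$size > 1]))
  une_bc <- normalize_barcode(unlist(clonotypes$barcodes[clonotypes$size == 1]))
  g1 <- ann$barcode[ann$norm_bc %in% exp_bc]
  g2 <- ann$barcode[ann$norm_bc %in% une_bc]
  if (length(g1) == 0 || length(g2) == 0) {
    stop("both expanded and unexpanded groups must be non-empty")
  }
  norm <- normalize_counts(counts[, c(g1, g2), drop = FALSE])
  x <- as.matrix(norm[, g1, drop = FALSE])
  y <- as.matrix(norm[, g2, drop = FALSE])
  p <- vapply(seq_len(nrow(norm)), function(i) {
    xi <- x[i, ]; yi <- y[i, ]
    if (all(xi == xi[1]) && all(yi == xi[1])) return(1)
    suppressWarnings(wilcox.test(xi, yi, exact = FALSE)$p.value)
  }, numeric(1))
  out <- data.frame(
    gene = rownames(norm),
    avg_logFC = rowMeans(x) - rowMeans(y),
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$avg_logFC), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap `k` when sampling `n = |gene_list|` genes
#' from a universe of `N` containing `K` set members:
#' \eqn{P(X \ge k)}. `ratio` is `k / K`, the fraction of the set hit.
#' P-values are BH-adjusted across sets. Genes outside the universe are
#' dropped with a warning.
#'
#' @param gene_list Character vector of hit genes (e.g. top DE genes).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector of all testable genes.
#' @return Data frame with `set`, `k`, `K`, `ratio`, `p`, `p_adj`, ordered
#'   by `p`.
#' @export
go_enrichment <- function(gene_list, gene_sets, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the universe dropped")
  }
  gene_list <- unique(intersect(gene_list, universe))
  n <- length(gene_list)
  N <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(gene_list, set))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K,
               ratio = if (K > 0) k / K else NA_real_, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preranked gene-set enrichment (weighted running sum)
#'
#' Classic weighted Kolmogorov-Smirnov enrichment score on a score-ranked
#' gene list: walking down the ranking, hits increment the running sum by
#' `|score| / sum(|score| over hits)` and misses decrement it by
#' `1 / (N - K)`; the enrichment score is the maximum deviation from zero
#' (signed). Significance is the fraction of random gene-label permutations
#' whose |ES| reaches the observed |ES| (with the +1 pseudocount standard
#' for permutation tests).
#'
#' @param scores Named numeric vector of ranking scores (names are genes);
#'   sorted internally in decreasing order.
#' @param gene_set Character vector of set genes; must intersect the list.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Random seed (default 42).
#' @return List with `es`, `p`, `n_hits`, and `running` (the running-sum
#'   profile in rank order, for enrichment plots).
#' @export
gsea_preranked <- function(scores, gene_set, n_perm = 1000, seed = 42) {
  stopifnot(n_perm >= 1)
  scores <- sort(scores, decreasing = TRUE)
  hit <- names(scores) %in% gene_set
  if (!any(hit)) stop("gene set does not intersect the ranked list")
  es_of <- function(hit) {
    N <- length(hit); K <- sum(hit)
    w <- abs(scores)
    inc <- ifelse(hit, w / sum(w[hit]), 0)
    dec <- ifelse(hit, 0, 1 / (N - K))
    run <- cumsum(inc - dec)
    run[which.max(abs(run))]
  }
  es <- es_of(hit)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) es_of(sample(hit)), numeric(1))
  p <- (1 + sum(abs(perm) >= abs(es))) / (1 + n_perm)
  w <- abs(scores)
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (length(hit) - sum(hit)))
  list(es = es, p = p, n_hits = sum(hit), running = cumsum(inc - dec))
}
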