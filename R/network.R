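## Clone similarity networks: vertices are clones (possibly from several
## samples), edges connect clones whose summed per-chain CDR3 edit distance
## falls strictly below a user threshold.

#' Summed per-chain CDR3 edit distance between two clones
#'
#' Levenshtein distance between the CDRH3 amino-acid representatives plus
#' Levenshtein distance between the CDRL3 representatives. Computed with
#' the full dynamic-programming edit distance ([utils::adist()]).
#'
#' @param a,b Single-row slices of a `clonotype_tbl`.
#' @return Non-negative integer.
#' @export
cdr3_pair_distance <- function(a, b) {
  as.integer(utils::adist(a$cdr3h_aa, b$cdr3h_aa) +
             utils::adist(a$cdr3l_aa, b$cdr3l_aa))
}

#' Build a clone similarity network
#'
#' Takes the `top_n_per_sample` most expanded clones of each sample,
#' computes all pairwise summed CDR3 edit distances, and draws an
#' undirected edge between clones separated by strictly less than
#' `threshold` amino-acid mutations. Vertices carry the sample of origin
#' and clone size; the graph is invariant to clone input order.
#'
#' @param clonotypes A `clonotype_tbl`, or a list of them (one per sample).
#' @param top_n_per_sample Expanded clones kept per sample (default 60).
#' @param threshold Strict upper bound on the summed edit distance
#'   (`>= 1`).
#' @return A `clone_network` list: `graph` (an [igraph] graph with vertex
#'   attributes `name`, `sample_id`, `size` and edge attribute `distance`),
#'   `vertices` and `edges` data frames, and `threshold`.
#' @export
build_network <- function(clonotypes, top_n_per_sample = 60, threshold = 10) {
  stopifnot(threshold >= 1)
  if (is.data.frame(clonotypes)) clonotypes <- list(clonotypes)
  tops <- lapply(clonotypes, rank_clones, top_n = top_n_per_sample)
  all <- do.call(rbind, tops)
  all <- all[order(all$sample_id, all$clonotype_id), , drop = FALSE]
  vid <- paste(all$sample_id, all$clonotype_id, sep = ":")
  n <- nrow(all)
  h <- utils::adist(all$cdr3h_aa)
  l <- utils::adist(all$cdr3l_aa)
  d <- h + l
  edges <- which(upper.tri(d) & d < threshold, arr.ind = TRUE)
  edge_df <- data.frame(from = vid[edges[, 1]], to = vid[edges[, 2]],
                        distance = as.integer(d[edges]),
                        stringsAsFactors = FALSE)
  vert_df <- data.frame(name = vid, sample_id = all$sample_id,
                        size = all$size, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = vert_df)
  structure(list(graph = g, vertices = vert_df, edges = edge_df,
                 threshold = as.integer(threshold)),
            class = "clone_network")
}

#' @export
print.clone_network <- function(x, ...) {
  cat("<clone_network>", nrow(x$vertices), "clones,", nrow(x$edges),
      "edges at summed edit distance <", x$threshold, "\n")
  invisible(x)
}

#' Connected components of a clone network with per-sample membership
#'
#' Standard connected components; each component is annotated with how many
#' member clones came from each sample, and flagged `cross_sample` when it
#' spans two or more samples (the signature of clonal convergence between
#' individuals).
#'
#' @param network A `clone_network`.
#' @return Data frame with `component`, `n_clones`, per-sample count
#'   columns, and `cross_sample`.
#' @export
cross_sample_components <- function(network) {
  comp <- igraph::components(network$graph)
  membership <- comp$membership
  samples <- sort(unique(network$vertices$sample_id))
  rows <- lapply(seq_len(comp$no), function(k) {
    members <- network$vertices[membership == k, , drop = FALSE]
    counts <- vapply(samples, function(s) sum(members$sample_id == s), integer(1))
    cbind(data.frame(component = k, n_clones = nrow(members)),
          as.data.frame(as.list(setNames(counts, samples))),
          data.frame(cross_sample = sum(counts > 0) >= 2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a clone network edge list to TSV
#'
#' @param network A `clone_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
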