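## Germline-rooted clone lineage trees. Each tip is one unique full-length
## heavy+light nucleotide concatenation; identical cells collapse into a
## single tip whose n_cells carries the multiplicity. Topology is inferred
## by neighbor joining on the pairwise alignment-distance matrix
## (substitutions + gap columns) and rooted at the germline tip.

#' Build a germline-rooted lineage tree for one clone
#'
#' Concatenates the attached heavy and light full-length sequences of each
#' member cell, collapses identical concatenations into single tips (the
#' tip label carries the cell count), prepends the germline reference
#' (heavy+light) as its own tip, infers a neighbor-joining tree from the
#' pairwise alignment distances, and roots it at the germline.
#'
#' @param repertoire A `repertoire` with sequences and germline refs attached.
#' @param clonotype A single-row slice of a `clonotype_tbl`.
#' @return A `clone_tree` list: `newick` (text), `tips` (data frame with
#'   `label`, `n_cells`, `seq_md5`), `root_label` (`"germline"`), and
#'   `phylo` (the [ape::phylo] object). Degenerate single-variant clones
#'   yield a two-taxon tree with a warning when the variant equals the
#'   germline.
#' @export
build_clone_tree <- function(repertoire, clonotype) {
  stopifnot(nrow(clonotype) == 1)
  germ <- extract_germline(repertoire, clonotype)
  cells <- repertoire$cells
  members <- cells[cells$barcode %in% clonotype$barcodes[[1]], , drop = FALSE]
  seqs <- paste0(members$heavy_full_nt, members$light_full_nt)
  ok <- !is.na(members$heavy_full_nt) & !is.na(members$light_full_nt)
  seqs <- seqs[ok]
  if (length(seqs) == 0) stop("clone has no attached sequences")
  germ_seq <- paste0(germ$heavy, germ$light)

  variants <- sort(unique(seqs))
  n_cells <- vapply(variants, function(v) sum(seqs == v), integer(1))
  labels <- paste0("variant", seq_along(variants), "_n", n_cells)
  if (length(variants) == 1 && variants[1] == germ_seq) {
    warning("all cells identical to germline; returning degenerate tree")
  }

  all_seqs <- c(germ_seq, variants)
  all_labels <- c("germline", labels)
  n <- length(all_seqs)
  d <- matrix(0, n, n, dimnames = list(all_labels, all_labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- align_global(all_seqs[i], all_seqs[j])
      d[i, j] <- d[j, i] <- aln$substitutions + aln$gap_columns
    }
  }
  phy <- nj_rooted(d)
  tips <- data.frame(
    label = all_labels,
    n_cells = c(0L, unname(n_cells)),
    seq_md5 = vapply(all_seqs, seq_digest, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(newick = ape::write.tree(phy), tips = tips,
                 root_label = "germline", phylo = phy),
            class = "clone_tree")
}

## NJ needs >= 3 taxa; smaller matrices get an explicit cherry/star tree.
nj_rooted <- function(d) {
  n <- nrow(d)
  if (n == 2) {
    txt <- sprintf("(%s:%f,%s:%f);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  phy <- ape::nj(as.dist(d))
  phy <- ape::root(phy, outgroup = "germline", resolve.root = TRUE)
  phy
}

seq_digest <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree>", nrow(x$tips) - 1L, "variant tip(s) +  germline root;",
      sum(x$tips$n_cells), "cells\n")
  invisible(x)
}

#' Patristic distance from the germline root to every tip
#'
#' Sum of branch lengths from the root to each tip; on additive distance
#' matrices the least-mutated variant is the closest tip.
#'
#' @param tree A `clone_tree`.
#' @return Named numeric vector over tip labels (germline excluded).
#' @export
root_to_tip_distances <- function(tree) {
  phy <- tree$phylo
  dmat <- ape::cophenetic.phylo(phy)
  d <- dmat["germline", setdiff(colnames(dmat), "germline")]
  d
}
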