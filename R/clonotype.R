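#' Define a clonotyping strategy
#'
#' The five supported strategies, from most to least restrictive on the
#' CDR3 axis:
#' \describe{
#'   \item{`cdr3.nt`}{identical concatenated CDRH3+CDRL3 nucleotide sequence
#'     (the cellranger-style default).}
#'   \item{`cdr3.aa`}{identical concatenated CDRH3+CDRL3 amino-acid sequence.}
#'   \item{`hvj.lvj`}{identical heavy V, heavy J, light V, light J germline
#'     gene names (allele suffixes such as `*01` stripped).}
#'   \item{`hvj.lvj.cdr3lengths`}{`hvj.lvj` plus identical CDRH3 and CDRL3
#'     amino-acid lengths.}
#'   \item{`hvj.lvj.cdr3length.cdr3homology`}{the previous, plus
#'     single-linkage clustering in which two cells link when the Hamming
#'     similarity of their concatenated CDRH3+CDRL3 amino-acid strings is at
#'     least `homology_threshold` (lengths are equal by construction).}
#' }
#'
#' @param name One of the strategy names above.
#' @param homology_threshold Similarity fraction in `[0, 1]`; used only by
#'   the homology strategy. Default 0.70.
#' @return A `clone_strategy` object.
#' @export
clone_strategy <- function(name = c("cdr3.nt", "cdr3.aa", "hvj.lvj",
                                    "hvj.lvj.cdr3lengths",
                                    "hvj.lvj.cdr3length.cdr3homology"),
                           homology_threshold = 0.70) {
  name <- match.arg(name)
  stopifnot(is.numeric(homology_threshold), length(homology_threshold) == 1,
            homology_threshold >= 0, homology_threshold <= 1)
  structure(list(name = name, homology_threshold = homology_threshold),
            class = "clone_strategy")
}

strip_allele <- function(gene) sub("\\*.*$", "", gene)

#' Group paired cells into clonotypes
#'
#' Partitions the paired cells of a repertoire under a clonotyping strategy
#' (see [clone_strategy()]). The result is independent of cell input order;
#' clonotype ids are `<strategy>_<rank>` where rank orders clones by
#' decreasing size with ties broken by the lexicographic representative
#' CDR3 nucleotide concatenation. The representative CDR3s of a clone are
#' the modal (then lexicographically smallest) member sequences.
#'
#' @param repertoire A `repertoire`; all cells must be paired.
#' @param strategy A `clone_strategy` (default `cdr3.nt`).
#' @return A data frame of class `clonotype_tbl`: one row per clonotype with
#'   `clonotype_id`, `strategy`, `sample_id`, `size`, `barcodes`
#'   (list-column), representative CDR3 columns, stripped germline gene
#'   columns `hv`, `hj`, `lv`, `lj`, and `raw_clonotype_id` (modal upstream
#'   clonotype label, used for germline lookup).
#' @export
clonotype_cells <- function(repertoire, strategy = clone_strategy("cdr3.nt")) {
  stopifnot(inherits(strategy, "clone_strategy"))
  cells <- repertoire$cells
  if (nrow(cells) > 0 && !all(cells$paired)) {
    stop("clonotyping requires paired cells only")
  }
  if (nrow(cells) == 0) return(empty_clonotype_tbl(strategy, repertoire$sample_id))

  hv <- strip_allele(cells$heavy_v_gene); hj <- strip_allele(cells$heavy_j_gene)
  lv <- strip_allele(cells$light_v_gene); lj <- strip_allele(cells$light_j_gene)
  concat_nt <- paste0(cells$heavy_cdr3_nt, cells$light_cdr3_nt)
  concat_aa <- paste0(cells$heavy_cdr3_aa, cells$light_cdr3_aa)

  key <- switch(strategy$name,
    "cdr3.nt" = concat_nt,
    "cdr3.aa" = concat_aa,
    "hvj.lvj" = paste(hv, hj, lv, lj, sep = "|"),
    "hvj.lvj.cdr3lengths" = paste(hv, hj, lv, lj,
                                  nchar(cells$heavy_cdr3_aa),
                                  nchar(cells$light_cdr3_aa), sep = "|"),
    "hvj.lvj.cdr3length.cdr3homology" = homology_keys(
      paste(hv, hj, lv, lj, nchar(cells$heavy_cdr3_aa),
            nchar(cells$light_cdr3_aa), sep = "|"),
      concat_aa, strategy$homology_threshold)
  )

  groups <- split(seq_len(nrow(cells)), key)
  clones <- lapply(groups, function(idx) {
    data.frame(
      sample_id = repertoire$sample_id,
      size = length(idx),
      cdr3h_aa = modal_value(cells$heavy_cdr3_aa[idx]),
      cdr3h_nt = modal_value(cells$heavy_cdr3_nt[idx]),
      cdr3l_aa = modal_value(cells$light_cdr3_aa[idx]),
      cdr3l_nt = modal_value(cells$light_cdr3_nt[idx]),
      hv = modal_value(hv[idx]), hj = modal_value(hj[idx]),
      lv = modal_value(lv[idx]), lj = modal_value(lj[idx]),
      raw_clonotype_id = modal_value(cells$heavy_raw_clonotype_id[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, clones)
  out$barcodes <- unname(lapply(groups, function(idx) sort(cells$barcode[idx])))
  o <- order(-out$size, paste0(out$cdr3h_nt, out$cdr3l_nt))
  out <- out[o, , drop = FALSE]
  out$clonotype_id <- paste0(strategy$name, "_", seq_len(nrow(out)))
  out$strategy <- strategy$name
  rownames(out) <- NULL
  out <- out[, clonotype_cols()]
  class(out) <- c("clonotype_tbl", "data.frame")
  out
}

clonotype_cols <- function() {
  c("clonotype_id", "strategy", "sample_id", "size", "barcodes",
    "cdr3h_aa", "cdr3h_nt", "cdr3l_aa", "cdr3l_nt",
    "hv", "hj", "lv", "lj", "raw_clonotype_id")
}

empty_clonotype_tbl <- function(strategy, sample_id) {
  out <- data.frame(clonotype_id = character(), strategy = character(),
                    sample_id = character(), size = integer(),
                    cdr3h_aa = character(), cdr3h_nt = character(),
                    cdr3l_aa = character(), cdr3l_nt = character(),
                    hv = character(), hj = character(), lv = character(),
                    lj = character(), raw_clonotype_id = character(),
                    stringsAsFactors = FALSE)
  out$barcodes <- list()
  out <- out[, clonotype_cols()]
  class(out) <- c("clonotype_tbl", "data.frame")
  out
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  top <- names(tab)[tab == tab[1]]
  sort(top)[1]
}

## Single-linkage homology clustering inside each (V,J,genes,lengths) gate.
## Within a gate all concatenated CDR3 strings have equal length, so the
## similarity is 1 - Hamming/len. Returns one grouping key per cell.
homology_keys <- function(gate_key, concat_aa, threshold) {
  keys <- character(length(gate_key))
  for (g in unique(gate_key)) {
    idx <- which(gate_key == g)
    comp <- single_linkage_components(concat_aa[idx], threshold)
    keys[idx] <- paste(g, comp, sep = "|hom")
  }
  keys
}

single_linkage_components <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1) return(1L)
  uniq <- unique(seqs)
  m <- length(uniq)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  L <- nchar(uniq[1])
  chars <- do.call(rbind, strsplit(uniq, ""))
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        sim <- sum(chars[i, ] == chars[j, ]) / L
        if (sim >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comp_of_uniq <- match(roots, sort(unique(roots)))
  comp_of_uniq[match(seqs, uniq)]
}

#' Count clonotypes under a strategy
#'
#' @inheritParams clonotype_cells
#' @return Number of clonotypes (non-negative integer).
#' @export
count_clones <- function(repertoire, strategy = clone_strategy("cdr3.nt")) {
  nrow(clonotype_cells(repertoire, strategy))
}

#' Rank clonotypes by clonal expansion
#'
#' Orders clonotypes by decreasing size, breaking ties by the lexicographic
#' representative CDR3 nucleotide concatenation and then by clonotype id,
#' and returns the first `top_n`.
#'
#' @param clonotypes A `clonotype_tbl`.
#' @param top_n Number of clones to keep (positive; capped at the list length).
#' @return The ranked, truncated `clonotype_tbl`.
#' @export
rank_clones <- function(clonotypes, top_n = nrow(clonotypes)) {
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n <= 0) {
    stop("top_n must be a positive integer")
  }
  o <- order(-clonotypes$size,
             paste0(clonotypes$cdr3h_nt, clonotypes$cdr3l_nt),
             clonotypes$clonotype_id)
  out <- clonotypes[o, , drop = FALSE]
  out <- head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("clonotype_tbl", "data.frame")
  out
}

#' Write a clonotype table to TSV
#'
#' Barcode list-columns are semicolon-joined so the table is plain text.
#'
#' @param clonotypes A `clonotype_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(clonotypes, path) {
  df <- as.data.frame(clonotypes)
  df$barcodes <- vapply(df$barcodes, paste, character(1), collapse = ";")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
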