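## Somatic hypermutation quantified as alignment mismatches against the
## extracted germline reference, over the full attached V(D)J sequence.

#' Global pairwise alignment with affine gaps
#'
#' End-to-end (Needleman-Wunsch/Gotoh) alignment of two nucleotide strings.
#' Default scoring: match +1, mismatch -1, and a gap of length k costs
#' `gap_open + k * gap_extend` (4 + k). Traceback is deterministic.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A list with `score`, `substitutions` (mismatched aligned
#'   columns), `gap_columns` (columns with a gap in either sequence; these
#'   are excluded from the substitution count and reported separately),
#'   `aligned_a`, `aligned_b`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 4, gap_extend = 1) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .align_global_cpp(a, b, match, mismatch, gap_open, gap_extend)
}

#' Count somatic hypermutation as germline alignment mismatches
#'
#' Number of substitution columns in the optimal global alignment of a cell
#' sequence against its germline reference (see [align_global()]). Gap
#' columns are not counted as mismatches; they are available via the
#' `gap_columns` attribute of the result. On indel-free sequence pairs of
#' equal length this equals the Hamming distance.
#'
#' @param cell_seq,germline_seq Non-empty nucleotide strings.
#' @return Non-negative integer with attribute `gap_columns`.
#' @export
count_shm <- function(cell_seq, germline_seq) {
  aln <- align_global(cell_seq, germline_seq)
  structure(aln$substitutions, gap_columns = aln$gap_columns)
}

#' Extract the germline reference sequences for a clonotype
#'
#' Looks up the paired heavy/light germline V(D)J-region sequences for a
#' clone in the repertoire's germline reference map. References are keyed
#' by the clone's upstream (cellranger-style) clonotype label as
#' `<raw_clonotype_id>_germline_heavy` / `<raw_clonotype_id>_germline_light`.
#'
#' @param repertoire A `repertoire` with `germline_refs` attached
#'   (see [attach_germline_refs()]).
#' @param clonotype A single-row slice of a `clonotype_tbl`.
#' @return A list with `heavy` and `light` nucleotide strings.
#' @export
extract_germline <- function(repertoire, clonotype) {
  stopifnot(nrow(clonotype) == 1)
  raw <- clonotype$raw_clonotype_id
  keys <- paste0(raw, c("_germline_heavy", "_germline_light"))
  refs <- repertoire$germline_refs
  if (is.na(raw) || !all(keys %in% names(refs))) {
    stop("no germline reference for clone ", clonotype$clonotype_id,
         " (reference id ", raw, ")")
  }
  list(heavy = unname(refs[keys[1]]), light = unname(refs[keys[2]]))
}

#' Per-cell somatic hypermutation for a repertoire
#'
#' For every paired cell with attached full-length sequences, counts
#' alignment mismatches against the clone's germline reference, separately
#' for heavy and light chains.
#'
#' @param repertoire A `repertoire` with sequences and germline refs attached.
#' @param clonotypes A `clonotype_tbl` over the same repertoire.
#' @return Data frame with `barcode`, `clonotype_id`, `mismatches_heavy`,
#'   `mismatches_light`, `total`.
#' @export
shm_per_cell <- function(repertoire, clonotypes) {
  cells <- repertoire$cells
  rows <- list()
  for (i in seq_len(nrow(clonotypes))) {
    cl <- clonotypes[i, , drop = FALSE]
    germ <- tryCatch(extract_germline(repertoire, cl), error = function(e) NULL)
    if (is.null(germ)) next
    members <- cells[cells$barcode %in% cl$barcodes[[1]], , drop = FALSE]
    for (k in seq_len(nrow(members))) {
      hseq <- members$heavy_full_nt[k]; lseq <- members$light_full_nt[k]
      if (is.na(hseq) || is.na(lseq)) next
      mh <- as.integer(count_shm(hseq, germ$heavy))
      ml <- as.integer(count_shm(lseq, germ$light))
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = members$barcode[k], clonotype_id = cl$clonotype_id,
        mismatches_heavy = mh, mismatches_light = ml, total = mh + ml,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(barcode = character(), clonotype_id = character(),
                      mismatches_heavy = integer(), mismatches_light = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean somatic hypermutation per expanded clone
#'
#' Mean heavy+light mismatch count over the member cells of each of the
#' `top_n` most expanded clones, in expansion-rank order. Clones with no
#' attached sequences (or no germline reference) are omitted with a warning.
#'
#' @param repertoire A `repertoire` with sequences and germline refs attached.
#' @param clonotypes A `clonotype_tbl`.
#' @param top_n Number of expanded clones to report (default 30).
#' @return Data frame with `clonotype_id`, `size`, `mean_shm`.
#' @export
shm_per_clone <- function(repertoire, clonotypes, top_n = 30) {
  top <- rank_clones(clonotypes, top_n)
  per_cell <- shm_per_cell(repertoire, top)
  means <- tapply(per_cell$total, per_cell$clonotype_id, mean)
  hit <- top$clonotype_id %in% names(means)
  if (any(!hit)) {
    warning(sum(!hit), " clone(s) had no scorable cells and were omitted")
  }
  out <- data.frame(clonotype_id = top$clonotype_id[hit],
                    size = top$size[hit],
                    mean_shm = as.numeric(means[top$clonotype_id[hit]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
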