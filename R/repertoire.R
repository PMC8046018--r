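## Assembly of paired-chain cell records from filtered contigs.
##
## A repertoire is an S3 list:
##   sample_id     scalar character
##   cells         data.frame, one row per paired barcode, with heavy_* /
##                 light_* column blocks mirroring the contig fields
##   unpaired      data.frame in the same layout for single-chain barcodes
##   summary       named integer vector of assembly bookkeeping
##   germline_refs named character vector: reference id -> nucleotide text

CONTIG_FIELDS <- c("contig_id", "chain", "v_gene", "d_gene", "j_gene",
                   "c_gene", "cdr3_aa", "cdr3_nt", "umis", "reads",
                   "raw_clonotype_id", "full_nt")

#' Assemble one paired-chain cell record per barcode
#'
#' Groups filtered contigs by barcode and pairs the heavy-like chain
#' (IGH or TRB) with the light-like chain (IGK/IGL or TRA). Within a locus
#' class the highest-UMI contig wins; ties break by read count, then by
#' lexicographic `contig_id`, so assembly is deterministic and invariant to
#' input order. Barcodes mixing B- and T-cell chains are dropped as
#' suspected doublets. Barcodes with two or more contigs in the same locus
#' class are dropped under `doublet_policy = "drop"` (default) or resolved
#' to the top-UMI contig under `"keep_top_umi"`. Unpaired barcodes are kept
#' in a side table and excluded from `cells`.
#'
#' @param contigs A filtered `contig_tbl` (see [filter_contigs()]).
#' @param sample_id Sample label stored on every cell.
#' @param doublet_policy `"drop"` or `"keep_top_umi"`.
#' @return A `repertoire` object; see Details. `summary` counts barcodes
#'   seen, paired, unpaired, dropped as same-class multiplets, and dropped
#'   as B/T-mixed doublets.
#' @export
assemble_cells <- function(contigs, sample_id,
                           doublet_policy = c("drop", "keep_top_umi")) {
  doublet_policy <- match.arg(doublet_policy)
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  df <- as.data.frame(contigs)
  df$.class <- chain_class(df$chain)
  df <- df[!is.na(df$.class), , drop = FALSE]

  barcodes <- unique(df$barcode)
  n_mixed <- 0L
  n_multiplet <- 0L
  rows_cells <- list()
  rows_unpaired <- list()

  for (bc in barcodes) {
    sub <- df[df$barcode == bc, , drop = FALSE]
    locus <- unique(ifelse(sub$chain %in% B_CHAINS, "B", "T"))
    if (length(locus) > 1) {            # B and T chains in one droplet
      n_mixed <- n_mixed + 1L
      next
    }
    heavy <- sub[sub$.class == "heavy", , drop = FALSE]
    light <- sub[sub$.class == "light", , drop = FALSE]
    if ((nrow(heavy) > 1 || nrow(light) > 1) && doublet_policy == "drop") {
      n_multiplet <- n_multiplet + 1L
      next
    }
    heavy <- top_contig(heavy)
    light <- top_contig(light)
    rec <- cell_row(bc, sample_id, heavy, light)
    if (!is.null(heavy) && !is.null(light)) {
      rows_cells[[length(rows_cells) + 1L]] <- rec
    } else {
      rows_unpaired[[length(rows_unpaired) + 1L]] <- rec
    }
  }
  if (n_mixed > 0) {
    warning(n_mixed, " barcode(s) mixed B and T chains; dropped as suspected doublets")
  }
  cells <- bind_cell_rows(rows_cells)
  unpaired <- bind_cell_rows(rows_unpaired)
  structure(list(
    sample_id = sample_id,
    cells = cells,
    unpaired = unpaired,
    summary = c(barcodes = length(barcodes),
                paired = nrow(cells),
                unpaired = nrow(unpaired),
                dropped_multiplet = n_multiplet,
                dropped_mixed_bt = n_mixed),
    germline_refs = character()
  ), class = "repertoire")
}

top_contig <- function(sub) {
  if (nrow(sub) == 0) return(NULL)
  o <- order(-sub$umis, -sub$reads, sub$contig_id)
  sub[o[1], , drop = FALSE]
}

cell_row <- function(barcode, sample_id, heavy, light) {
  rec <- data.frame(barcode = barcode, sample_id = sample_id,
                    stringsAsFactors = FALSE)
  for (side in c("heavy", "light")) {
    con <- if (side == "heavy") heavy else light
    for (f in CONTIG_FIELDS) {
      val <- if (is.null(con)) blank_field(f) else con[[f]]
      rec[[paste0(side, "_", f)]] <- val
    }
  }
  rec$isotype <- assign_isotype(rec$heavy_c_gene)
  rec$paired <- !is.null(heavy) && !is.null(light)
  rec
}

blank_field <- function(f) {
  if (f %in% c("umis", "reads")) NA_integer_ else NA_character_
}

bind_cell_rows <- function(rows) {
  if (length(rows) == 0) {
    tmpl <- cell_row("x", "x", NULL, NULL)
    return(tmpl[0, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.repertoire <- function(x, ...) {
  cat("<repertoire> sample", x$sample_id, "-", nrow(x$cells), "paired cells,",
      nrow(x$unpaired), "unpaired,", length(x$germline_refs),
      "germline reference(s)\n")
  invisible(x)
}

#' Flatten a repertoire back to a contig table
#'
#' Emits one contig row per retained chain (paired cells plus, optionally,
#' unpaired ones), in the normalized `contig_tbl` layout. Together with
#' [write_contigs()] and [load_contigs()] this round-trips losslessly.
#'
#' @param repertoire A `repertoire`.
#' @param include_unpaired Also emit the single-chain side table.
#' @return A `contig_tbl`.
#' @export
repertoire_contigs <- function(repertoire, include_unpaired = FALSE) {
  cells <- repertoire$cells
  if (include_unpaired) cells <- rbind(cells, repertoire$unpaired)
  rows <- list()
  for (side in c("heavy", "light")) {
    cols <- paste0(side, "_", CONTIG_FIELDS)
    sub <- cells[, c("barcode", cols), drop = FALSE]
    names(sub) <- c("barcode", CONTIG_FIELDS)
    sub <- sub[!is.na(sub$contig_id), , drop = FALSE]
    rows[[side]] <- sub
  }
  out <- do.call(rbind, rows)
  out$productive <- TRUE
  out$high_confidence <- TRUE
  out$is_cell <- TRUE
  out <- out[, names(empty_contig_tbl())]
  out <- out[order(out$barcode, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_tbl", "data.frame")
  out
}

#' Attach full-length contig nucleotide sequences from a FASTA file
#'
#' Populates the `full_nt` fields of a repertoire from a contig FASTA whose
#' record ids match `contig_id`s. Contigs without a matching FASTA record
#' are left unset and counted in a warning.
#'
#' @param repertoire A `repertoire`.
#' @param fasta Path to a contig FASTA file.
#' @return The repertoire with `full_nt` populated where ids matched.
#' @export
attach_sequences <- function(repertoire, fasta) {
  seqs <- read_fasta(fasta)
  n_missing <- 0L
  for (tbl in c("cells", "unpaired")) {
    cells <- repertoire[[tbl]]
    if (nrow(cells) == 0) next
    for (side in c("heavy", "light")) {
      idc <- paste0(side, "_contig_id")
      sqc <- paste0(side, "_full_nt")
      hit <- match(cells[[idc]], names(seqs))
      present <- !is.na(cells[[idc]])
      n_missing <- n_missing + sum(present & is.na(hit))
      cells[[sqc]] <- ifelse(!is.na(hit), unname(seqs[hit]), cells[[sqc]])
    }
    repertoire[[tbl]] <- cells
  }
  if (n_missing > 0) {
    warning(n_missing, " contig id(s) had no matching FASTA record")
  }
  repertoire
}

#' Load germline reference sequences into a repertoire
#'
#' Reads a germline reference FASTA (the per-clonotype references emitted
#' alongside cellranger output, keyed `<raw_clonotype_id>_germline_heavy` /
#' `..._germline_light` by the bundled simulator) into the repertoire's
#' reference map.
#'
#' @param repertoire A `repertoire`.
#' @param fasta Path to the germline FASTA.
#' @return The repertoire with `germline_refs` set.
#' @export
attach_germline_refs <- function(repertoire, fasta) {
  repertoire$germline_refs <- read_fasta(fasta)
  repertoire
}

## Small FASTA IO on top of Biostrings; duplicate ids are an input error
## because sequence attachment would be ambiguous.
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(as.character(set), ids)
}

write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
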