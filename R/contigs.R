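#' Load a cellranger-style filtered contig annotation table
#'
#' Reads a `filtered_contig_annotations.csv`-dialect table into a normalized
#' contig data frame. Boolean columns accept the cellranger spellings
#' (`"True"`/`"False"`, any case) as well as R logicals. The cellranger
#' `cdr3` column is normalized to `cdr3_aa`. Missing or `"None"` entries in
#' optional gene columns (`d_gene`, `c_gene`) become `NA`.
#'
#' @param path Path to a CSV file with at least the columns `barcode`,
#'   `chain`, `v_gene`, `j_gene`, `cdr3` (amino acid), `cdr3_nt`,
#'   `productive`, `high_confidence`, `is_cell` and `umis`.
#' @return A data frame of class `contig_tbl`, one row per contig, with
#'   columns `barcode`, `contig_id`, `chain`, `v_gene`, `d_gene`, `j_gene`,
#'   `c_gene`, `cdr3_aa`, `cdr3_nt`, `productive`, `high_confidence`,
#'   `is_cell`, `umis`, `reads`, `raw_clonotype_id`, `full_nt`.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' write.csv(data.frame(barcode = "AAAC-1", contig_id = "AAAC-1_contig_1",
#'   chain = "IGH", v_gene = "IGHV1-18", j_gene = "IGHJ4", cdr3 = "CARW",
#'   cdr3_nt = "TGTGCTCGCTGG", productive = "True", high_confidence = "True",
#'   is_cell = "True", umis = 4), csv, row.names = FALSE)
#' load_contigs(csv)
#' @export
load_contigs <- function(path) {
  if (!file.exists(path)) stop("contig file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) {
    warning("contig table is empty: ", path)
    return(empty_contig_tbl())
  }
  if ("cdr3" %in% names(df) && !("cdr3_aa" %in% names(df))) {
    names(df)[names(df) == "cdr3"] <- "cdr3_aa"
  }
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_aa", "cdr3_nt",
                "productive", "high_confidence", "is_cell", "umis")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("contig table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$chain), c(CHAINS, "Multi", "None"))
  if (length(bad)) {
    stop("unrecognized chain value(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    barcode = as.character(df$barcode),
    contig_id = as.character(pick_col(df, "contig_id",
                                      paste0(df$barcode, "_contig_", seq_len(nrow(df))))),
    chain = as.character(df$chain),
    v_gene = as.character(df$v_gene),
    d_gene = norm_gene(pick_col(df, "d_gene", NA_character_)),
    j_gene = as.character(df$j_gene),
    c_gene = norm_gene(pick_col(df, "c_gene", NA_character_)),
    cdr3_aa = as.character(df$cdr3_aa),
    cdr3_nt = as.character(df$cdr3_nt),
    productive = parse_cr_bool(df$productive),
    high_confidence = parse_cr_bool(df$high_confidence),
    is_cell = parse_cr_bool(df$is_cell),
    umis = as.integer(df$umis),
    reads = as.integer(pick_col(df, "reads", 0L)),
    raw_clonotype_id = as.character(pick_col(df, "raw_clonotype_id", NA_character_)),
    full_nt = as.character(pick_col(df, "full_nt", NA_character_)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("contig_tbl", "data.frame")
  out
}

empty_contig_tbl <- function() {
  out <- data.frame(
    barcode = character(), contig_id = character(), chain = character(),
    v_gene = character(), d_gene = character(), j_gene = character(),
    c_gene = character(), cdr3_aa = character(), cdr3_nt = character(),
    productive = logical(), high_confidence = logical(), is_cell = logical(),
    umis = integer(), reads = integer(), raw_clonotype_id = character(),
    full_nt = character(), stringsAsFactors = FALSE
  )
  class(out) <- c("contig_tbl", "data.frame")
  out
}

pick_col <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

norm_gene <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "None"] <- NA_character_
  x
}

parse_cr_bool <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) == "true"
}

#' Write contigs back in the cellranger CSV dialect
#'
#' Inverse of [load_contigs()]: booleans are emitted as `"True"`/`"False"`,
#' absent genes as `"None"`, and `cdr3_aa` as the cellranger `cdr3` column,
#' so a written table reloads field-by-field identical.
#'
#' @param contigs A `contig_tbl`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  df <- as.data.frame(contigs)
  for (col in c("productive", "high_confidence", "is_cell")) {
    df[[col]] <- ifelse(df[[col]], "True", "False")
  }
  for (col in c("d_gene", "c_gene")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "None", df[[col]])
  }
  names(df)[names(df) == "cdr3_aa"] <- "cdr3"
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Keep contigs that pass cellranger-style quality filters
#'
#' Retains contigs that are productive, high confidence, called as cells and
#' carry a non-empty CDR3 amino-acid sequence. Input order is preserved.
#'
#' @param contigs A `contig_tbl`.
#' @return The filtered `contig_tbl`.
#' @export
filter_contigs <- function(contigs) {
  keep <- contigs$productive & contigs$high_confidence & contigs$is_cell &
    !is.na(contigs$cdr3_aa) & nzchar(contigs$cdr3_aa)
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_tbl", "data.frame")
  out
}

#' Derive the antibody isotype from a heavy-chain constant gene
#'
#' Maps the cellranger `c_gene` call to an isotype class by constant-gene
#' prefix: `IGHA*` to IgA, `IGHG*` to IgG, `IGHM` to IgM, `IGHD` to IgD,
#' `IGHE` to IgE; T-cell constant genes (`TR*C*`) map to `TR`; anything
#' absent or unrecognized maps to `unknown`. Vectorized.
#'
#' @param c_gene Character vector of constant-gene names (`NA` allowed).
#' @return Character vector over `c("IgA","IgD","IgE","IgG","IgM","TR","unknown")`.
#' @examples
#' assign_isotype(c("IGHA1", "IGHG2", "IGHM", "TRBC2", NA))
#' @export
assign_isotype <- function(c_gene) {
  out <- rep("unknown", length(c_gene))
  g <- ifelse(is.na(c_gene), "", as.character(c_gene))
  out[startsWith(g, "IGHA")] <- "IgA"
  out[startsWith(g, "IGHG")] <- "IgG"
  out[startsWith(g, "IGHM")] <- "IgM"
  out[startsWith(g, "IGHD")] <- "IgD"
  out[startsWith(g, "IGHE")] <- "IgE"
  out[grepl("^TR[ABGD]C", g)] <- "TR"
  out
}
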