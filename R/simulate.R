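## Deterministic simulators emitting exactly the dialects the IO layer
## reads: a cellranger-style contig CSV + contig FASTA + per-clonotype
## germline FASTA with a planted-truth table, and an MTX expression triplet
## with planted clusters, markers and mitochondrial content.

## codons that never encode a stop, so planted CDR3s translate cleanly
SAFE_CODONS <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
                 "AAA", "CTT", "ATG", "AAT", "CCT", "CAA", "CGT", "TCT",
                 "ACT", "GTT", "TGG", "TAT")

#' Specify a synthetic repertoire
#'
#' Defaults describe a desk-scale convalescent-donor-like B-cell
#' repertoire: a couple of hundred paired cells, tens of clonal lineages
#' with power-law expansion, a few somatic point mutations per chain, and
#' an IgA-leaning isotype mix.
#'
#' @param n_cells Total paired cells (default 200).
#' @param n_clones Number of planted clonal lineages (default 40; must not
#'   exceed `n_cells`).
#' @param clone_size_law `"power_law"` (default, exponent `alpha`) or
#'   `"uniform"`.
#' @param alpha Power-law exponent for clone sizes (default 1.5).
#' @param shm_rate Poisson mean of planted nucleotide substitutions per
#'   chain per cell (default 3; 0 gives identical cells within a clone).
#' @param isotype_mix Named probability vector over isotypes (default
#'   IgA 0.45, IgG 0.30, IgM 0.25, reflecting the IgA-dominated expansion
#'   the package's motivating use case shows). Ignored for TCR.
#' @param receptor `"BCR"` (default) or `"TCR"`.
#' @param cdr3h_lengths,cdr3l_lengths Amino-acid length pools for planted
#'   CDR3s (defaults 13:17 and 9:11).
#' @param seed Random seed (default 1).
#' @return A `repertoire_sim_spec` list.
#' @export
repertoire_sim_spec <- function(n_cells = 200, n_clones = 40,
                                clone_size_law = c("power_law", "uniform"),
                                alpha = 1.5, shm_rate = 3,
                                isotype_mix = c(IgA = 0.45, IgG = 0.30, IgM = 0.25),
                                receptor = c("BCR", "TCR"),
                                cdr3h_lengths = 13:17, cdr3l_lengths = 9:11,
                                seed = 1) {
  clone_size_law <- match.arg(clone_size_law)
  receptor <- match.arg(receptor)
  if (n_clones > n_cells) stop("n_clones must not exceed n_cells")
  stopifnot(shm_rate >= 0, abs(sum(isotype_mix) - 1) < 1e-9)
  structure(list(n_cells = n_cells, n_clones = n_clones,
                 clone_size_law = clone_size_law, alpha = alpha,
                 shm_rate = shm_rate, isotype_mix = isotype_mix,
                 receptor = receptor, cdr3h_lengths = cdr3h_lengths,
                 cdr3l_lengths = cdr3l_lengths, seed = seed),
            class = "repertoire_sim_spec")
}

germline_pool <- function() {
  read_fasta(system.file("extdata", "germline_pool.fasta", package = "screp"))
}

ISOTYPE_CGENE <- c(IgA = "IGHA1", IgG = "IGHG1", IgM = "IGHM",
                   IgD = "IGHD", IgE = "IGHE")

random_cdr3_nt <- function(len_aa) {
  paste(sample(SAFE_CODONS, len_aa, replace = TRUE), collapse = "")
}

translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

mutate_nt <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_mut <- min(n_mut, length(chars))
  pos <- sample(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

## pool germlines are 300 nt; the planted CDR3 is spliced in after nt 150
CDR3_INSERT_AT <- 150L

#' Simulate a cellranger-style paired V(D)J dataset with planted lineages
#'
#' Each planted clone is a germline V/J pick per chain plus a planted CDR3
#' pair; the clone's unmutated ancestor (germline V-region with the CDR3
#' spliced in) is written to the germline reference FASTA. Member cells
#' carry Poisson(`shm_rate`) nucleotide substitutions per chain (no
#' indels), so the planted per-cell substitution counts in the truth table
#' equal alignment mismatches against the germline reference exactly.
#' Outputs parse through [load_contigs()]/[attach_sequences()]/
#' [attach_germline_refs()] losslessly and byte-identically per seed.
#'
#' @param spec A [repertoire_sim_spec()].
#' @param dir Output directory (created if needed).
#' @param sample_id Sample label (default `"sim1"`).
#' @return List with paths `contigs_csv`, `contig_fasta`, `germline_fasta`,
#'   `truth_csv` and the `truth` data frame (`barcode`, `clone`,
#'   `raw_clonotype_id`, per-chain and total planted substitution counts,
#'   `isotype`).
#' @export
simulate_repertoire <- function(spec, dir, sample_id = "sim1") {
  stopifnot(inherits(spec, "repertoire_sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  pool <- germline_pool()
  heavy_pool <- if (spec$receptor == "BCR") {
    pool[startsWith(names(pool), "IGH")]
  } else pool[startsWith(names(pool), "TRB")]
  light_pool <- if (spec$receptor == "BCR") {
    pool[startsWith(names(pool), "IGK") | startsWith(names(pool), "IGL")]
  } else pool[startsWith(names(pool), "TRA")]

  sizes <- plan_clone_sizes(spec)
  clones <- lapply(seq_len(spec$n_clones), function(i) {
    h_id <- sample(names(heavy_pool), 1)
    l_id <- sample(names(light_pool), 1)
    cdr3h <- random_cdr3_nt(sample(spec$cdr3h_lengths, 1))
    cdr3l <- random_cdr3_nt(sample(spec$cdr3l_lengths, 1))
    list(
      raw_id = paste0("clonotype", i),
      h_genes = strsplit(h_id, "_")[[1]], l_genes = strsplit(l_id, "_")[[1]],
      h_anc = splice_cdr3(heavy_pool[[h_id]], cdr3h),
      l_anc = splice_cdr3(light_pool[[l_id]], cdr3l),
      h_cdr3_len = nchar(cdr3h) %/% 3L, l_cdr3_len = nchar(cdr3l) %/% 3L
    )
  })

  rows <- list(); fasta <- character(); truth <- list()
  cell_idx <- 0L
  for (ci in seq_len(spec$n_clones)) {
    cl <- clones[[ci]]
    for (k in seq_len(sizes[ci])) {
      cell_idx <- cell_idx + 1L
      bc <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = "")
      bc <- sprintf("%s%04d", bc, cell_idx)   # guarantees uniqueness
      mh <- rpois(1, spec$shm_rate); ml <- rpois(1, spec$shm_rate)
      h_seq <- mutate_nt(cl$h_anc, mh); l_seq <- mutate_nt(cl$l_anc, ml)
      h_cdr3_nt <- substr(h_seq, CDR3_INSERT_AT + 1,
                          CDR3_INSERT_AT + 3 * cl$h_cdr3_len)
      l_cdr3_nt <- substr(l_seq, CDR3_INSERT_AT + 1,
                          CDR3_INSERT_AT + 3 * cl$l_cdr3_len)
      iso <- if (spec$receptor == "BCR") {
        sample(names(spec$isotype_mix), 1, prob = spec$isotype_mix)
      } else "TR"
      h_c_gene <- if (spec$receptor == "BCR") ISOTYPE_CGENE[[iso]] else "TRBC2"
      l_c_gene <- if (spec$receptor == "BCR") "IGKC" else "TRAC"
      h_chain <- if (spec$receptor == "BCR") "IGH" else "TRB"
      l_chain <- if (spec$receptor == "BCR") {
        if (startsWith(cl$l_genes[1], "IGK")) "IGK" else "IGL"
      } else "TRA"
      h_umis <- rpois(1, 4) + 1L; l_umis <- rpois(1, 6) + 1L
      mk_row <- function(suffix, chain, v, d, j, cg, cdr3nt, umis) {
        data.frame(barcode = bc, is_cell = "True",
                   contig_id = paste0(bc, "_contig_", suffix),
                   high_confidence = "True", chain = chain,
                   v_gene = v, d_gene = d, j_gene = j, c_gene = cg,
                   productive = "True", cdr3 = translate_nt(cdr3nt),
                   cdr3_nt = cdr3nt, reads = umis * 40L, umis = umis,
                   raw_clonotype_id = cl$raw_id, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- mk_row(
        1, h_chain, cl$h_genes[1],
        if (spec$receptor == "BCR") "IGHD3-10" else "TRBD1",
        cl$h_genes[2], h_c_gene, h_cdr3_nt, h_umis)
      rows[[length(rows) + 1L]] <- mk_row(
        2, l_chain, cl$l_genes[1], "None", cl$l_genes[2], l_c_gene,
        l_cdr3_nt, l_umis)
      fasta[paste0(bc, "_contig_1")] <- h_seq
      fasta[paste0(bc, "_contig_2")] <- l_seq
      truth[[cell_idx]] <- data.frame(
        barcode = bc, clone = ci, raw_clonotype_id = cl$raw_id,
        shm_heavy = mh, shm_light = ml, shm_total = mh + ml,
        isotype = iso, stringsAsFactors = FALSE)
    }
  }

  contigs_csv <- file.path(dir, "filtered_contig_annotations.csv")
  contig_fasta <- file.path(dir, "filtered_contig.fasta")
  germline_fasta <- file.path(dir, "concat_ref.fasta")
  truth_csv <- file.path(dir, "truth.csv")
  write.csv(do.call(rbind, rows), contigs_csv, row.names = FALSE, quote = FALSE)
  write_fasta(fasta, contig_fasta)
  germ <- unlist(lapply(clones, function(cl) {
    setNames(c(cl$h_anc, cl$l_anc),
             paste0(cl$raw_id, c("_germline_heavy", "_germline_light")))
  }))
  write_fasta(germ, germline_fasta)
  truth <- do.call(rbind, truth)
  write.csv(truth, truth_csv, row.names = FALSE)
  list(contigs_csv = contigs_csv, contig_fasta = contig_fasta,
       germline_fasta = germline_fasta, truth_csv = truth_csv, truth = truth)
}

splice_cdr3 <- function(germ, cdr3_nt) {
  paste0(substr(germ, 1, CDR3_INSERT_AT), cdr3_nt,
         substr(germ, CDR3_INSERT_AT + 1, nchar(germ)))
}

plan_clone_sizes <- function(spec) {
  n <- spec$n_cells; k <- spec$n_clones
  sizes <- rep(1L, k)
  extra <- n - k
  if (extra > 0) {
    w <- if (spec$clone_size_law == "uniform") rep(1, k) else seq_len(k)^(-spec$alpha)
    sizes <- sizes + as.integer(rmultinom(1, extra, w / sum(w)))
  }
  sizes
}

#' Convenience loader for a simulated repertoire directory
#'
#' Runs the full IO path (load, filter, assemble, attach sequences and
#' germline references) on the files written by [simulate_repertoire()] or
#' any cellranger-style directory laid out the same way.
#'
#' @param dir Directory with `filtered_contig_annotations.csv`,
#'   `filtered_contig.fasta`, `concat_ref.fasta`.
#' @param sample_id Sample label.
#' @param doublet_policy Passed to [assemble_cells()].
#' @return A `repertoire`.
#' @export
load_repertoire_dir <- function(dir, sample_id,
                                doublet_policy = c("drop", "keep_top_umi")) {
  contigs <- filter_contigs(load_contigs(file.path(dir, "filtered_contig_annotations.csv")))
  rep <- assemble_cells(contigs, sample_id, match.arg(doublet_policy))
  rep <- attach_sequences(rep, file.path(dir, "filtered_contig.fasta"))
  attach_germline_refs(rep, file.path(dir, "concat_ref.fasta"))
}

#' Specify a synthetic expression matrix
#'
#' Defaults give a desk-scale droplet-like experiment: negative-binomial
#' background counts, a handful of well-separated clusters defined by
#' disjoint marker blocks, ~10 mitochondrial genes with a planted fraction
#' of high-mito cells, and half the barcodes shared with a V(D)J
#' repertoire.
#'
#' @param n_cells,n_genes Matrix dimensions (defaults 200 x 500).
#' @param n_clusters Planted clusters (default 2).
#' @param n_markers_per_cluster Marker genes per cluster (default 20).
#' @param marker_mu,background_mu NB means for markers in their cluster and
#'   for background (defaults 5 and 0.3).
#' @param nb_size NB dispersion parameter (default 2).
#' @param mito_high_fraction Fraction of cells planted with mitochondrial
#'   content above 20% (default 0.1).
#' @param fraction_in_vdj Fraction of barcodes shared with the repertoire
#'   (default 0.5).
#' @param seed Random seed (default 1).
#' @return A `gex_sim_spec` list.
#' @export
gex_sim_spec <- function(n_cells = 200, n_genes = 500, n_clusters = 2,
                         n_markers_per_cluster = 20, marker_mu = 5,
                         background_mu = 0.3, nb_size = 2,
                         mito_high_fraction = 0.1, fraction_in_vdj = 0.5,
                         seed = 1) {
  if (n_clusters * n_markers_per_cluster + 10 + 6 > n_genes) {
    stop("markers, mito and phenotype genes exceed n_genes")
  }
  structure(as.list(environment()), class = "gex_sim_spec")
}

PHENO_GENES <- c("CD8A", "CD44", "SELL", "IL7R", "CCL5", "TCF7")

#' Simulate an expression matrix with planted clusters
#'
#' Genes comprise disjoint marker blocks (`MK<cluster>_<i>`, elevated in
#' their cluster), 10 mitochondrial genes (`MT-1`..`MT-10`, scaled so a
#' planted subset of cells exceeds 20% mitochondrial content), six T-cell
#' phenotype marker genes wired to clusters (cluster 0 memory-like:
#' SELL/IL7R on, CCL5 off; cluster 1 effector-like: CCL5 on, SELL/IL7R
#' off), and negative-binomial background genes (`GENE<i>`). When
#' `vdj_barcodes` is given, the first `fraction_in_vdj` of cells reuse
#' those barcodes with a `-1` suffix.
#'
#' @param spec A [gex_sim_spec()].
#' @param vdj_barcodes Optional barcodes of a simulated repertoire.
#' @return List with `counts` (genes x cells `dgCMatrix`) and `truth`
#'   (data frame: `barcode`, `cluster`, `mito_high`, `in_vdj`).
#' @export
simulate_gex <- function(spec, vdj_barcodes = NULL) {
  stopifnot(inherits(spec, "gex_sim_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_cells
  clusters <- rep(seq_len(spec$n_clusters) - 1L, length.out = n)

  n_share <- if (is.null(vdj_barcodes)) 0L else
    min(floor(spec$fraction_in_vdj * n), length(vdj_barcodes))
  barcodes <- sprintf("GEXBC%05d-1", seq_len(n))
  if (n_share > 0) {
    ## sample across the repertoire so shared cells span expanded and
    ## unexpanded clones alike
    shared <- sample(vdj_barcodes, n_share)
    barcodes[seq_len(n_share)] <- paste0(shared, "-1")
  }

  marker_names <- unlist(lapply(seq_len(spec$n_clusters) - 1L, function(cl)
    sprintf("MK%d_%02d", cl, seq_len(spec$n_markers_per_cluster))))
  mito_names <- paste0("MT-", 1:10)
  n_bg <- spec$n_genes - length(marker_names) - length(mito_names) - length(PHENO_GENES)
  bg_names <- sprintf("GENE%04d", seq_len(n_bg))
  genes <- c(marker_names, PHENO_GENES, mito_names, bg_names)

  counts <- matrix(rnbinom(length(genes) * n, mu = spec$background_mu,
                           size = spec$nb_size),
                   nrow = length(genes), dimnames = list(genes, barcodes))
  for (cl in seq_len(spec$n_clusters) - 1L) {
    mk <- sprintf("MK%d_%02d", cl, seq_len(spec$n_markers_per_cluster))
    cols <- clusters == cl
    counts[mk, cols] <- rnbinom(length(mk) * sum(cols), mu = spec$marker_mu,
                                size = spec$nb_size)
  }
  ## phenotype wiring: memory-like cluster 0, effector-like cluster 1
  on <- function(g, cols) counts[g, cols] <<-
    rpois(sum(cols), 3) + 1L
  off <- function(g, cols) counts[g, cols] <<- 0L
  c0 <- clusters == 0L; c1 <- clusters == 1L
  for (g in c("CD8A", "CD44")) { on(g, c0); on(g, c1) }
  on("SELL", c0); on("IL7R", c0); on("TCF7", c0); off("CCL5", c0)
  on("CCL5", c1); off("SELL", c1); off("IL7R", c1); off("TCF7", c1)

  ## mitochondrial content: scale MT counts so the planted high cells
  ## exceed the 20% filter boundary and the rest sit well below it
  mito_high <- seq_len(n) %in% sample(n, round(spec$mito_high_fraction * n))
  target_frac <- ifelse(mito_high, runif(n, 0.25, 0.4), runif(n, 0.01, 0.10))
  non_mito_tot <- colSums(counts[setdiff(genes, mito_names), , drop = FALSE])
  mito_tot <- pmax(1, round(target_frac / (1 - target_frac) * non_mito_tot))
  for (j in seq_len(n)) {
    counts[mito_names, j] <- as.integer(rmultinom(1, mito_tot[j], rep(1, 10)))
  }
  truth <- data.frame(barcode = barcodes, cluster = clusters,
                      mito_high = mito_high,
                      in_vdj = seq_len(n) <= n_share,
                      stringsAsFactors = FALSE)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       truth = truth)
}
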