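## Fixture builders and independent oracles shared across the suite.
## Oracles are deliberately naive re-derivations (full DP, enumeration,
## union-find) kept separate from the code paths they check.

## ---- contig/repertoire builders -------------------------------------------

contig_row <- function(barcode, chain, cdr3_aa = "CARW",
                       cdr3_nt = strrep("TGG", nchar(cdr3_aa)),
                       v_gene = "IGHV1-18", j_gene = "IGHJ4",
                       d_gene = "None", c_gene = "IGHM",
                       productive = "True", high_confidence = "True",
                       is_cell = "True", umis = 3, reads = 120,
                       contig_id = paste0(barcode, "_", chain),
                       raw_clonotype_id = "clonotype1") {
  data.frame(barcode = barcode, is_cell = is_cell, contig_id = contig_id,
             high_confidence = high_confidence, chain = chain,
             v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
             c_gene = c_gene, productive = productive, cdr3 = cdr3_aa,
             cdr3_nt = cdr3_nt, reads = reads, umis = umis,
             raw_clonotype_id = raw_clonotype_id, stringsAsFactors = FALSE)
}

write_contig_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  path
}

## directly build a paired cell row in the repertoire layout
make_cell <- function(barcode, hv = "IGHV1-18", hj = "IGHJ4",
                      lv = "IGKV1-39", lj = "IGKJ1",
                      cdr3h_aa = "CARDYW", cdr3l_aa = "CQQYNSYPF",
                      cdr3h_nt = NULL, cdr3l_nt = NULL,
                      c_gene = "IGHM", sample_id = "s1",
                      raw_clonotype_id = "clonotype1",
                      heavy_full_nt = NA_character_,
                      light_full_nt = NA_character_) {
  aa2nt <- function(aa) paste(rep("TGG", nchar(aa)), collapse = "")
  if (is.null(cdr3h_nt)) cdr3h_nt <- aa2nt(cdr3h_aa)
  if (is.null(cdr3l_nt)) cdr3l_nt <- aa2nt(cdr3l_aa)
  data.frame(
    barcode = barcode, sample_id = sample_id,
    heavy_contig_id = paste0(barcode, "_c1"), heavy_chain = "IGH",
    heavy_v_gene = hv, heavy_d_gene = NA_character_, heavy_j_gene = hj,
    heavy_c_gene = c_gene, heavy_cdr3_aa = cdr3h_aa, heavy_cdr3_nt = cdr3h_nt,
    heavy_umis = 3L, heavy_reads = 120L,
    heavy_raw_clonotype_id = raw_clonotype_id, heavy_full_nt = heavy_full_nt,
    light_contig_id = paste0(barcode, "_c2"), light_chain = "IGK",
    light_v_gene = lv, light_d_gene = NA_character_, light_j_gene = lj,
    light_c_gene = "IGKC", light_cdr3_aa = cdr3l_aa, light_cdr3_nt = cdr3l_nt,
    light_umis = 3L, light_reads = 120L,
    light_raw_clonotype_id = raw_clonotype_id, light_full_nt = light_full_nt,
    isotype = assign_isotype(c_gene), paired = TRUE,
    stringsAsFactors = FALSE
  )
}

rep_from_cells <- function(..., sample_id = "s1",
                           germline_refs = character()) {
  cells <- do.call(rbind, list(...))
  structure(list(sample_id = sample_id, cells = cells,
                 unpaired = cells[0, , drop = FALSE],
                 summary = c(barcodes = nrow(cells), paired = nrow(cells),
                             unpaired = 0L, dropped_multiplet = 0L,
                             dropped_mixed_bt = 0L),
                 germline_refs = germline_refs),
            class = "repertoire")
}

## a small simulated dataset reused by several files (built once per run)
sim_dir_small <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- tempfile("simsmall")
      simulate_repertoire(repertoire_sim_spec(n_cells = 60, n_clones = 12,
                                              shm_rate = 2, seed = 11), dir)
    }
    dir
  }
})

## ---- independent oracles ---------------------------------------------------

## full-DP Levenshtein (unit costs)
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j] + (x[i] != y[j]),
                           d[i, j + 1] + 1L, d[i + 1, j] + 1L)
  }
  d[n + 1, m + 1]
}

## affine-gap global alignment optimal score (three-state DP, score only);
## gap of length k costs open + k * ext
gotoh_score_oracle <- function(a, b, match = 1, mismatch = -1,
                               open = 4, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(-Inf, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (x[i] == y[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

## brute-force connected components over an edge list
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## exhaustive hypergeometric upper tail: draw n of N, K marked, P(X >= k)
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

## adjusted Rand index between two labelings
adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

## plant point substitutions (no indels) into a sequence
plant_subs <- function(seq, n_mut) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
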