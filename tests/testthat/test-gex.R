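toy_counts <- function(vals, genes, cells = paste0("C", seq_len(ncol(vals)))) {
  m <- Matrix::Matrix(vals, sparse = TRUE, dimnames = list(genes, cells))
  methods::as(m, "CsparseMatrix")
}

test_that("mitochondrial filter removes strictly above the boundary", {
  ## cell1: 25% mito (removed); cell2: exactly 20% (kept); cell3: 10% (kept)
  m <- toy_counts(matrix(c(25, 75, 20, 80, 10, 90), nrow = 2),
                  c("MT-ND1", "ACTB"))
  kept <- filter_cells_by_mito(m, max_fraction = 0.20)
  expect_equal(colnames(kept), c("C2", "C3"))
  expect_equal(ncol(filter_cells_by_mito(m, max_fraction = 1.0)), 3)
  no_mito <- toy_counts(matrix(1:4, nrow = 2), c("ACTB", "GAPDH"))
  expect_warning(out <- filter_cells_by_mito(no_mito), "no genes")
  expect_equal(dim(out), dim(no_mito))
})

test_that("receptor segment genes are removed, lookalikes retained", {
  genes <- c("IGHV3-23", "IGKJ2", "IGLV2-14", "IGHA1", "IGHG2", "TRBV19",
             "TRAC", "TRGJ1", "IGF1", "IGFBP3", "TRIM28", "ACTB")
  m <- toy_counts(matrix(1, nrow = length(genes), ncol = 2), genes)
  out <- remove_vdj_genes(m)
  expect_equal(rownames(out), c("IGF1", "IGFBP3", "TRIM28", "ACTB"))
  expect_equal(attr(out, "n_removed"), 8L)
  clean <- toy_counts(matrix(1, 2, 2), c("ACTB", "GAPDH"))
  expect_equal(rownames(remove_vdj_genes(clean)), rownames(clean))
})

test_that("cluster_cells recovers planted clusters and is deterministic", {
  sim <- simulate_gex(gex_sim_spec(n_cells = 120, n_genes = 300, n_clusters = 2,
                                   seed = 5))
  ann1 <- cluster_cells(sim$counts, n_hvg = 200, n_pcs = 5, seed = 42)
  ann2 <- cluster_cells(sim$counts, n_hvg = 200, n_pcs = 5, seed = 42)
  expect_identical(ann1$cluster, ann2$cluster)       # determinism contract
  ari <- adj_rand_index(ann1$cluster, sim$truth$cluster)
  expect_gte(ari, 0.9)
  ## identical cells collapse to one cluster
  const <- toy_counts(matrix(5, nrow = 10, ncol = 8), paste0("G", 1:10))
  annc <- cluster_cells(const, n_hvg = 10, n_pcs = 3)
  expect_equal(unique(annc$cluster), 0L)
  expect_error(cluster_cells(const[, 1, drop = FALSE]), "two cells")
})

test_that("cluster_cells warns when genes are fewer than n_hvg", {
  sim <- simulate_gex(gex_sim_spec(n_cells = 40, n_genes = 120,
                                   n_markers_per_cluster = 10, seed = 2))
  expect_warning(cluster_cells(sim$counts, n_hvg = 5000, n_pcs = 4), "n_hvg")
})

test_that("match_barcodes normalizes suffixes and detects disjoint sets", {
  rep <- rep_from_cells(make_cell("AAACGG"), make_cell("TTTGCC"))
  ann <- data.frame(barcode = c("AAACGG-1", "GGGAAA-1"), cluster = 0L,
                    phenotype = "unclassified", in_vdj = NA)
  out <- match_barcodes(rep, ann)
  expect_equal(out$in_vdj, c(TRUE, FALSE))
  disjoint <- data.frame(barcode = "CCCCCC-1", cluster = 0L,
                         phenotype = "unclassified", in_vdj = NA)
  expect_error(match_barcodes(rep, disjoint), "overlap")
  ## overlap equals brute-force set intersection on simulated data
  d <- sim_dir_small()
  srep <- load_repertoire_dir(d, "s1")
  gex <- simulate_gex(gex_sim_spec(n_cells = 80, n_genes = 200, seed = 3),
                      vdj_barcodes = srep$cells$barcode)
  ann2 <- data.frame(barcode = gex$truth$barcode, cluster = 0L,
                     phenotype = "unclassified", in_vdj = NA)
  out2 <- match_barcodes(srep, ann2)
  expect_equal(sum(out2$in_vdj),
               length(intersect(sub("-1$", "", gex$truth$barcode),
                                srep$cells$barcode)))
  expect_equal(sum(out2$in_vdj), floor(0.5 * 80))
})

test_that("cluster membership fractions are normalized over matched cells", {
  cells <- c(lapply(1:10, function(i) make_cell(paste0("E", i), cdr3h_aa = "CAAA")),
             lapply(1:3, function(i) make_cell(paste0("S", i), cdr3h_aa = paste0("CX", i))))
  rep <- do.call(rep_from_cells, cells)
  cl <- clonotype_cells(rep, clone_strategy("cdr3.aa"))
  ann <- data.frame(barcode = paste0(c(paste0("E", 1:10), paste0("S", 1:3)), "-1"),
                    cluster = c(rep(0L, 3), rep(6L, 7), 0L, 0L, 6L),
                    phenotype = "unclassified", in_vdj = NA)
  ann <- match_barcodes(rep, ann)
  mem <- cluster_membership_per_clone(cl, ann, top_n = 1)
  expect_equal(unname(mem[1, ]), c(0.3, 0.7))       # {0: 3/10, 6: 7/10}
  expect_true(all(abs(rowSums(mem) - 1) < 1e-9))
  ## single-cell clone -> a row with one 1.0
  mem_all <- cluster_membership_per_clone(cl, ann, top_n = 4)
  expect_true(all(abs(rowSums(mem_all) - 1) < 1e-9))
  ## whole-sample version also normalizes rows
  ann$sample_id <- rep(c("p1", "p2"), length.out = nrow(ann))
  sm <- sample_cluster_membership(ann)
  expect_true(all(abs(rowSums(sm) - 1) < 1e-9))
})

test_that("clones without GEX matches are omitted with a warning", {
  rep <- rep_from_cells(make_cell("AA", cdr3h_aa = "CAAA"),
                        make_cell("BB", cdr3h_aa = "CCCC"))
  cl <- clonotype_cells(rep, clone_strategy("cdr3.aa"))
  ann <- data.frame(barcode = "AA-1", cluster = 0L,
                    phenotype = "unclassified", in_vdj = NA)
  ann <- match_barcodes(rep, ann)
  expect_warning(mem <- cluster_membership_per_clone(cl, ann, top_n = 2), "omitted")
  expect_equal(nrow(mem), 1)
})

test_that("phenotype assignment follows the marker definitions", {
  genes <- c("CD8A", "CD44", "SELL", "IL7R", "CCL5", "TCF7", "ACTB")
  ## cell1: effector (CD8A+, CD44+, CCL5+, SELL-, IL7R-)
  ## cell2: memory   (all positives on, CCL5 off)
  ## cell3: all-zero on the classifier genes -> unclassified
  vals <- matrix(c(2, 1, 0, 0, 3, 0, 5,
                   1, 2, 1, 1, 0, 1, 5,
                   0, 0, 0, 0, 0, 0, 5), ncol = 3)
  m <- toy_counts(vals, genes)
  ann <- data.frame(barcode = colnames(m), cluster = 0L,
                    phenotype = "unclassified", in_vdj = NA)
  out <- assign_phenotype(ann, m)
  expect_equal(out$phenotype, c("effector_like", "memory_like", "unclassified"))
  ## missing marker genes are tolerated with a warning
  m2 <- toy_counts(vals[-3, , drop = FALSE], genes[-3])
  expect_warning(out2 <- assign_phenotype(ann, m2), "SELL")
  expect_error(assign_phenotype(ann, m, definitions = list()), "definitions")
})

test_that("the default phenotype pair is mutually exclusive over all marker patterns", {
  ## enumerate the 2^5 detection patterns of (CD8A, CD44, SELL, IL7R, CCL5)
  genes <- c("CD8A", "CD44", "SELL", "IL7R", "CCL5", "TCF7")
  patterns <- expand.grid(rep(list(0:1), 5))
  vals <- t(cbind(as.matrix(patterns), TCF7 = 0))
  rownames(vals) <- genes
  colnames(vals) <- paste0("P", seq_len(ncol(vals)))
  ann <- data.frame(barcode = colnames(vals), cluster = 0L,
                    phenotype = "unclassified", in_vdj = NA)
  out <- assign_phenotype(ann, toy_counts(vals, genes, cells = colnames(vals)))
  defs <- default_phenotypes()
  for (i in seq_len(nrow(patterns))) {
    det <- setNames(as.logical(patterns[i, ]), c("CD8A", "CD44", "SELL", "IL7R", "CCL5"))
    manual <- "unclassified"
    for (d in defs) {
      if (all(det[d$positive]) && all(!det[d$zero])) { manual <- d$label; break }
    }
    expect_equal(out$phenotype[i], manual)
  }
  ## no pattern can satisfy both definitions (SELL/IL7R/CCL5 constraints disjoint)
  both <- vapply(seq_len(nrow(patterns)), function(i) {
    det <- setNames(as.logical(patterns[i, ]), c("CD8A", "CD44", "SELL", "IL7R", "CCL5"))
    all(det[defs[[1]]$positive]) && all(!det[defs[[1]]$zero]) &&
      all(det[defs[[2]]$positive]) && all(!det[defs[[2]]$zero])
  }, logical(1))
  expect_false(any(both))
})

test_that("expanded-vs-unexpanded DE finds a planted gene and behaves at the null", {
  set.seed(21)
  n_per <- 30
  cells <- c(lapply(seq_len(n_per), function(i)
               make_cell(paste0("E", i), cdr3h_aa = "CAAA")),
             lapply(seq_len(n_per), function(i)
               make_cell(paste0("S", i), cdr3h_aa = paste0("CX", random_aa(4)))))
  rep <- do.call(rep_from_cells, cells)
  cl <- clonotype_cells(rep, clone_strategy("cdr3.aa"))
  expect_equal(sum(cl$size > 1), 1)
  genes <- c("PLANTED", paste0("G", 1:30))
  vals <- matrix(rpois(length(genes) * 2 * n_per, 5), nrow = length(genes))
  bc <- paste0(c(paste0("E", seq_len(n_per)), paste0("S", seq_len(n_per))), "-1")
  m <- toy_counts(vals, genes, bc)
  m["PLANTED", seq_len(n_per)] <- rpois(n_per, 20)   # 4-fold up in expanded
  ann <- data.frame(barcode = bc, cluster = 0L,
                    phenotype = "unclassified", in_vdj = NA)
  ann <- match_barcodes(rep, ann)
  de <- de_expanded_vs_unexpanded(m, cl, ann)
  hit <- de[de$gene == "PLANTED", ]
  expect_gt(hit$avg_logFC, 0)
  expect_lt(hit$p_adj, 0.05)
  expect_equal(de$gene[1], "PLANTED")               # top by avg logFC
  ## genes with identical normalized values in both groups: logFC 0, p 1
  ## (equal library sizes by construction)
  m2 <- toy_counts(matrix(rep(c(4, 6), 2 * n_per), nrow = 2), c("G1", "G2"), bc)
  de2 <- de_expanded_vs_unexpanded(m2, cl, ann)
  expect_equal(de2$p, c(1, 1))
  expect_equal(de2$avg_logFC, c(0, 0))
  ## BH adjustment is monotone in raw p order
  o <- order(de$p)
  expect_true(all(diff(de$p_adj[o]) > -1e-12))
  ## empty group errors
  cl_all1 <- cl[cl$size == 1, ]
  expect_error(de_expanded_vs_unexpanded(m, cl_all1, ann), "non-empty")
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  ## N=4, K=2, n=2, k=2 -> P = C(2,2)C(2,0)/C(4,2) = 1/6
  res <- go_enrichment(c("g1", "g2"), list(S = c("g1", "g2")),
                       universe = c("g1", "g2", "g3", "g4"))
  expect_equal(res$p, 1 / 6)
  expect_equal(res$ratio, 1)
  ## k = 0 -> p = 1
  res0 <- go_enrichment("g3", list(S = c("g1", "g2")),
                        universe = c("g1", "g2", "g3", "g4"))
  expect_equal(res0$p, 1)
  ## enumeration oracle for N <= 12, invariant to gene order
  set.seed(31)
  for (i in 1:10) {
    N <- sample(6:12, 1); K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    uni <- paste0("u", seq_len(N))
    set_genes <- uni[seq_len(K)]
    hits <- sample(uni, n)
    k <- length(intersect(hits, set_genes))
    res <- go_enrichment(hits, list(S = set_genes), uni)
    expect_equal(res$p, hyper_enum_oracle(N, K, n, k), tolerance = 1e-12)
    res_rev <- go_enrichment(rev(hits), list(S = rev(set_genes)), uni)
    expect_equal(res_rev$p, res$p)
  }
  expect_warning(go_enrichment(c("g1", "zzz"), list(S = "g1"),
                               universe = c("g1", "g2")), "outside")
  expect_error(go_enrichment("g1", list(S = "g1"), character()), "empty")
})

test_that("preranked GSEA reproduces the hand-walked toy and its symmetries", {
  scores <- c(gene1 = 3, gene2 = 2, gene3 = 1, gene4 = 0.5)
  res <- gsea_preranked(scores, "gene1", n_perm = 200, seed = 1)
  expect_equal(res$es, 1.0)                          # running sum peaks at 1 after rank 1
  expect_equal(res$running[1], 1.0)
  expect_gte(res$p, 0); expect_lte(res$p, 1)
  res_again <- gsea_preranked(scores, "gene1", n_perm = 200, seed = 1)
  expect_identical(res$p, res_again$p)               # reproducible at fixed seed
  ## all set genes at the top -> ES near +1
  set.seed(8)
  big <- setNames(sort(runif(50, 0.1, 5), decreasing = TRUE), paste0("g", 1:50))
  top_set <- names(big)[1:5]
  expect_gt(gsea_preranked(big, top_set, n_perm = 10, seed = 1)$es, 0.9)
  ## negating all scores flips the ES sign
  res_neg <- gsea_preranked(-scores, "gene4", n_perm = 10, seed = 1)
  res_pos <- gsea_preranked(scores, "gene4", n_perm = 10, seed = 1)
  expect_equal(res_neg$es, -res_pos$es)
  expect_error(gsea_preranked(scores, "absent"), "intersect")
})

test_that("MTX and GMT round trips work", {
  sim <- simulate_gex(gex_sim_spec(n_cells = 20, n_genes = 100, seed = 6))
  d <- tempfile()
  write_mtx(sim$counts, d)
  back <- read_mtx(d)
  expect_equal(as.matrix(back), as.matrix(sim$counts))
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tA\tB\tC", "SET2\tdesc\tX\tY"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets, list(SET1 = c("A", "B", "C"), SET2 = c("X", "Y")))
})
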