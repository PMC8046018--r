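test_that("count_shm counts substitutions and reports gaps separately", {
  s <- "ACGTACGTACGTACGTACGT"
  expect_equal(as.integer(count_shm(s, s)), 0)
  set.seed(2)
  mut <- plant_subs(s, 2)
  expect_equal(as.integer(count_shm(mut, s)), 2)
  ## a deletion shows up as gap columns, not substitutions
  del <- paste0(substr(s, 1, 8), substr(s, 12, 20))
  res <- count_shm(del, s)
  expect_equal(attr(res, "gap_columns"), 3L)
  expect_error(count_shm("", s), "non-empty")
})

test_that("alignment scores match an independent affine-gap DP oracle", {
  set.seed(42)
  for (i in 1:200) {
    a <- random_dna(sample(5:60, 1))
    ## derive b by substitutions plus occasional indels
    b <- plant_subs(a, sample(0:4, 1))
    if (runif(1) < 0.5) {
      cut <- sample(nchar(b) - 2, 1)
      b <- paste0(substr(b, 1, cut), substr(b, cut + sample(1:2, 1) + 1, nchar(b)))
    }
    if (nchar(b) == 0) b <- "A"
    aln <- align_global(a, b)
    expect_equal(aln$score, gotoh_score_oracle(a, b))
    ## the reported alignment re-scores to the optimum
    ca <- strsplit(aln$aligned_a, "")[[1]]; cb <- strsplit(aln$aligned_b, "")[[1]]
    gaps <- ca == "-" | cb == "-"
    rescore <- sum(ifelse(ca[!gaps] == cb[!gaps], 1, -1))
    runs <- rle(ifelse(ca == "-", "a", ifelse(cb == "-", "b", "m")))
    for (k in which(runs$values != "m")) rescore <- rescore - (4 + runs$lengths[k])
    expect_equal(rescore, aln$score)
  }
})

test_that("count_shm is symmetric, bounded, and equals Hamming on indel-free pairs", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_dna(60)
    n_mut <- sample(0:10, 1)
    b <- plant_subs(a, n_mut)
    expect_equal(as.integer(count_shm(a, b)), n_mut)     # Hamming, exactly
    expect_equal(as.integer(count_shm(b, a)), n_mut)     # symmetric
    expect_equal(attr(count_shm(a, b), "gap_columns"), 0L)
    c2 <- random_dna(sample(40:80, 1))
    expect_lte(as.integer(count_shm(a, c2)), max(nchar(a), nchar(c2)))
  }
})

test_that("extract_germline returns the planted ancestor per clone", {
  d <- sim_dir_small()
  rep <- load_repertoire_dir(d, "s1")
  cl <- clonotype_cells(rep, clone_strategy("hvj.lvj.cdr3length.cdr3homology"))
  germ <- extract_germline(rep, cl[1, , drop = FALSE])
  raw <- cl$raw_clonotype_id[1]
  expect_equal(germ$heavy, unname(rep$germline_refs[paste0(raw, "_germline_heavy")]))
  ## clones sharing a reference get identical germlines
  same <- cl[cl$raw_clonotype_id == raw, , drop = FALSE]
  if (nrow(same) > 1) {
    expect_equal(extract_germline(rep, same[2, , drop = FALSE]), germ)
  }
  bad <- cl[1, , drop = FALSE]
  bad$raw_clonotype_id <- "nosuch"
  expect_error(extract_germline(rep, bad), "germline")
})

test_that("planted per-cell substitution counts are recovered exactly", {
  d <- sim_dir_small()
  sim_truth <- read.csv(file.path(d, "truth.csv"), stringsAsFactors = FALSE)
  rep <- load_repertoire_dir(d, "s1")
  cl <- clonotype_cells(rep, clone_strategy("hvj.lvj.cdr3length.cdr3homology"))
  shm <- shm_per_cell(rep, cl)
  merged <- merge(shm, sim_truth, by = "barcode")
  expect_equal(nrow(merged), nrow(rep$cells))
  expect_equal(merged$mismatches_heavy, merged$shm_heavy)
  expect_equal(merged$mismatches_light, merged$shm_light)
  expect_equal(merged$total, merged$shm_total)
})

test_that("shm_per_clone averages member totals in expansion order", {
  d <- sim_dir_small()
  sim_truth <- read.csv(file.path(d, "truth.csv"), stringsAsFactors = FALSE)
  rep <- load_repertoire_dir(d, "s1")
  cl <- clonotype_cells(rep, clone_strategy("hvj.lvj.cdr3length.cdr3homology"))
  per_clone <- shm_per_clone(rep, cl, top_n = 5)
  ranked <- rank_clones(cl, 5)
  expect_equal(per_clone$clonotype_id, ranked$clonotype_id)
  truth_mean <- vapply(ranked$barcodes, function(b)
    mean(sim_truth$shm_total[sim_truth$barcode %in% b]), numeric(1))
  expect_equal(per_clone$mean_shm, unname(truth_mean))
})

test_that("clone trees collapse identical sequences and conserve cell counts", {
  germ_h <- random_dna(90); germ_l <- random_dna(60)
  refs <- c(clonotype9_germline_heavy = germ_h, clonotype9_germline_light = germ_l)
  set.seed(13)
  v1h <- plant_subs(germ_h, 1)
  v2h <- plant_subs(germ_h, 4)
  cells <- list(
    make_cell("B1", raw_clonotype_id = "clonotype9", heavy_full_nt = v1h, light_full_nt = germ_l),
    make_cell("B2", raw_clonotype_id = "clonotype9", heavy_full_nt = v1h, light_full_nt = germ_l),
    make_cell("B3", raw_clonotype_id = "clonotype9", heavy_full_nt = v2h, light_full_nt = germ_l)
  )
  rep <- do.call(rep_from_cells, cells)
  rep$germline_refs <- refs
  cl <- clonotype_cells(rep, clone_strategy("cdr3.aa"))
  tree <- build_clone_tree(rep, cl[1, , drop = FALSE])
  expect_equal(nrow(tree$tips), 3)                  # 2 variants + germline
  expect_equal(sum(tree$tips$n_cells), 3)           # clone size conserved
  expect_equal(sort(tree$tips$n_cells), c(0, 1, 2)) # collapsed tip carries 2
  ## Newick round-trips to the same topology
  reparsed <- ape::read.tree(text = tree$newick)
  expect_equal(sort(reparsed$tip.label), sort(tree$phylo$tip.label))
  expect_true(ape::all.equal.phylo(reparsed, tree$phylo, use.edge.length = FALSE))
  expect_equal(tree$root_label, "germline")
})

test_that("NJ recovers the true split of an additive 4-taxon matrix and ranks tips by mutation load", {
  ## mutation sets: v1 {p1}; v2 {p1,p2,p3}; v3 {p1,p2,p4} on disjoint positions
  ## -> additive distances with true split {germline,v1} | {v2,v3}
  base_h <- strrep("A", 60); base_l <- strrep("C", 30)
  sub_at <- function(s, pos, ch) { x <- strsplit(s, "")[[1]]; x[pos] <- ch; paste(x, collapse = "") }
  v1 <- sub_at(base_h, 1, "G")
  v23_core <- sub_at(sub_at(base_h, 1, "G"), 5, "T")
  v2 <- sub_at(v23_core, 10, "T")
  v3 <- sub_at(v23_core, 15, "T")
  cells <- list(
    make_cell("B1", cdr3h_aa = "CAAA", heavy_full_nt = v1, light_full_nt = base_l),
    make_cell("B2", cdr3h_aa = "CAAA", heavy_full_nt = v2, light_full_nt = base_l),
    make_cell("B3", cdr3h_aa = "CAAA", heavy_full_nt = v3, light_full_nt = base_l)
  )
  rep <- do.call(rep_from_cells, cells)
  rep$germline_refs <- c(clonotype1_germline_heavy = base_h,
                         clonotype1_germline_light = base_l)
  cl <- clonotype_cells(rep, clone_strategy("cdr3.aa"))
  tree <- build_clone_tree(rep, cl[1, , drop = FALSE])
  ## identify tips by root distance: v2,v3 (3 substitutions each) are sisters
  tips <- setdiff(tree$phylo$tip.label, "germline")
  d_root <- root_to_tip_distances(tree)
  near <- names(which.min(d_root))                  # least mutated variant
  far <- setdiff(tips, near)
  expect_true(ape::is.monophyletic(tree$phylo, far))
  ## least-mutated variant (1 substitution) sits closest to the germline root
  expect_equal(unname(d_root[near]), 1)
})

test_that("degenerate single-variant clones yield a two-taxon tree with warning", {
  g <- random_dna(60)
  cells <- list(make_cell("B1", heavy_full_nt = g, light_full_nt = g))
  rep <- do.call(rep_from_cells, cells)
  rep$germline_refs <- c(clonotype1_germline_heavy = g, clonotype1_germline_light = g)
  cl <- clonotype_cells(rep, clone_strategy("cdr3.aa"))
  expect_warning(tree <- build_clone_tree(rep, cl[1, , drop = FALSE]), "degenerate")
  expect_equal(nrow(tree$tips), 2)
})
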