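test_that("K2P distance follows the transition/transversion arithmetic", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # 20 sites, 2 transitions (A<->G), 1 transversion (A<->T): P=0.1, Q=0.05
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c("G", "G", "T", rep("A", 17)), collapse = "")
  expect_equal(k2p_distance(a, b),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)
  expect_equal(k2p_distance(a, b), 0.17018, tolerance = 1e-4)
})

test_that("K2P approaches the p-distance for small divergence", {
  a <- paste(rep("A", 1000), collapse = "")
  b <- paste(c("G", "G", "T", rep("A", 997)), collapse = "")
  p <- 3 / 1000
  expect_equal(k2p_distance(a, b), p, tolerance = 0.01)
})

test_that("saturated pairs are rejected by name", {
  haps <- structure(
    tibble::tibble(haplotype_id = c("Ha", "Hb"), n_members = c(1L, 1L),
                   members = list("a", "b"), signature = c("AAAA", "GGGG")),
    class = c("haplotype_tbl", "tbl_df", "tbl", "data.frame"))
  expect_error(k2p_matrix(haps, 4), "saturated.*Ha/Hb")
})

test_that("K2P matrix agrees with the reference implementation in ape", {
  sim <- paper_sim()
  haps <- collapse_haplotypes(sim$alignment)
  L <- length(sim$alignment$mask)
  d <- k2p_matrix(haps, L)
  # independent route: expand signatures to full masked sequences and use
  # ape's K80 distance
  reps <- vapply(haps$members, `[[`, character(1), 1)
  m <- sim$alignment$seq[reps, sim$alignment$mask, drop = FALSE]
  rownames(m) <- haps$haplotype_id
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "K80"))
  expect_equal(d, ref[rownames(d), colnames(d)], tolerance = 1e-10)
})

test_that("NJ recovers additive distances exactly", {
  # tree ((A:1,B:2):1.5,C:3,D:4); path-length matrix is additive
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5.5
  d["A", "D"] <- d["D", "A"] <- 6.5
  d["B", "C"] <- d["C", "B"] <- 6.5
  d["B", "D"] <- d["D", "B"] <- 7.5
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-10)
  # AB|CD is the internal split
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
})

test_that("NJ reproduces ultrametric path lengths", {
  tr0 <- ape::read.tree(text = "((a:1,b:1):2,((c:1.5,d:1.5):0.5,e:2):1);")
  d <- as.matrix(stats::cophenetic(tr0))
  tr <- nj_tree(d)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-10)
})

test_that("three taxa solve the three-point equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-10)
})

test_that("degenerate matrices give a trivial tree with a warning", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(tr <- nj_tree(d), "trivial")
  expect_setequal(tr$tip.label, c("a", "b"))
})

test_that("outgroup rooting splits the pendant edge and keeps path lengths", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  rooted <- root_with_outgroup(tr, "C")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  expect_true(which(rooted$tip.label == "C") %in% kids)
  expect_equal(as.matrix(stats::cophenetic(rooted))[rownames(d), colnames(d)],
               as.matrix(stats::cophenetic(tr))[rownames(d), colnames(d)],
               tolerance = 1e-12)
  expect_error(root_with_outgroup(tr, "Z"), "not a tip")
})

test_that("single-replicate bootstrap supports are all-or-nothing", {
  sim <- paper_sim()
  haps <- collapse_haplotypes(sim$alignment)
  bt <- bootstrap_support(sim$alignment, haps, replicates = 1, seed = 3)
  expect_true(all(bt$support %in% c(0, 100)))
})

test_that("bootstrap is reproducible and bounded", {
  sim <- paper_sim()
  haps <- collapse_haplotypes(sim$alignment)
  b1 <- bootstrap_support(sim$alignment, haps, replicates = 30, seed = 8)
  b2 <- bootstrap_support(sim$alignment, haps, replicates = 30, seed = 8)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
})

test_that("the rooted fixture tree separates the two wild clades", {
  sim <- paper_sim()
  haps <- collapse_haplotypes(sim$alignment)
  og <- unname(haplotype_of(haps)["BAR01"])
  bt <- bootstrap_support(sim$alignment, haps, replicates = 30, seed = 2,
                          outgroup = og)
  truth <- sim$truth$accessions
  hj <- unique(haplotype_of(haps)[truth$accession[truth$clade == "japonica_like"]])
  tr_noog <- ape::drop.tip(bt$tree, og)
  expect_true(ape::is.monophyletic(tr_noog, unique(hj)))
})
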