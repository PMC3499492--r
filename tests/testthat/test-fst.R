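# independent oracle: AMOVA variance components computed from scratch on
# raw sequences with explicit loops
brute_phist <- function(aln, g_a, g_b) {
  acc <- c(g_a, g_b)
  m <- aln$seq[acc, aln$mask, drop = FALSE]
  d <- matrix(0, length(acc), length(acc))
  for (i in seq_along(acc)) for (j in seq_along(acc)) {
    d[i, j] <- sum(m[i, ] != m[j, ])
  }
  n <- length(acc)
  lab <- rep(1:2, c(length(g_a), length(g_b)))
  ssd_t <- sum(d[upper.tri(d)]) / n
  if (ssd_t == 0) return(list(phi = 0, sw = 0, np = n - (length(g_a)^2 + length(g_b)^2) / n))
  ssd_wp <- 0
  for (g in 1:2) {
    idx <- which(lab == g)
    if (length(idx) > 1) {
      sub <- d[idx, idx]
      ssd_wp <- ssd_wp + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  sw <- ssd_wp / (n - 2)
  np <- n - (length(g_a)^2 + length(g_b)^2) / n
  sa <- (ssd_t - ssd_wp - sw) / np
  list(phi = sa / (sa + sw), sw = sw, np = np)
}

test_that("identical monomorphic groups give Phi-ST zero", {
  aln <- aln_from_strings(setNames(rep("ACGTACGT", 8), paste0("s", 1:8)))
  res <- pairwise_fst(aln, list(a = paste0("s", 1:5), b = paste0("s", 6:8)))
  expect_equal(res$phi_st, 0)
  expect_equal(res$sigma_a2, 0)
})

test_that("groups fixed for different haplotypes give Phi-ST one", {
  s <- c(setNames(rep("AAAA", 4), paste0("a", 1:4)),
         setNames(rep("AATT", 3), paste0("b", 1:3)))
  aln <- aln_from_strings(s)
  res <- pairwise_fst(aln, list(a = paste0("a", 1:4), b = paste0("b", 1:3)))
  expect_equal(res$phi_st, 1)
  expect_equal(res$sigma_w2, 0)
  expect_gt(res$sigma_a2, 0)
})

test_that("the worked three-vs-two example reproduces its components", {
  # group_a = {A, A, B}, group_b = {B, B}, d(A, B) = 1
  s <- c(x1 = "AAAA", x2 = "AAAA", x3 = "AAAT", y1 = "AAAT", y2 = "AAAT")
  aln <- aln_from_strings(s)
  res <- pairwise_fst(aln, list(a = c("x1", "x2", "x3"), b = c("y1", "y2")))
  expect_equal(res$sigma_w2, 2 / 9, tolerance = 1e-12)
  expect_equal(res$n_prime, 2.4)
  expect_equal(res$phi_st, 7 / 19, tolerance = 1e-12)
  expect_equal(round(res$phi_st, 3), 0.368)
})

test_that("Phi-ST agrees with the brute-force variance-component oracle", {
  for (seed in 1:8) {
    aln <- random_aln(9, 30, seed)
    acc <- accessions(aln)
    g_a <- acc[1:5]; g_b <- acc[6:9]
    res <- pairwise_fst(aln, list(a = g_a, b = g_b))
    oracle <- brute_phist(aln, g_a, g_b)
    expect_equal(max(0, min(1, oracle$phi)), res$phi_st, tolerance = 1e-12)
    expect_equal(oracle$sw, res$sigma_w2, tolerance = 1e-12)
    expect_equal(oracle$np, res$n_prime, tolerance = 1e-12)
  }
})

test_that("the Hudson variant behaves at the fixed and panmictic extremes", {
  s <- c(setNames(rep("AAAA", 3), paste0("a", 1:3)),
         setNames(rep("TTAA", 3), paste0("b", 1:3)))
  aln <- aln_from_strings(s)
  expect_equal(
    pairwise_fst(aln, list(a = paste0("a", 1:3), b = paste0("b", 1:3)),
                 estimator = "hudson")$phi_st, 1)
  same <- aln_from_strings(setNames(rep("ACGT", 6), paste0("s", 1:6)))
  expect_equal(
    pairwise_fst(same, list(a = paste0("s", 1:3), b = paste0("s", 4:6)),
                 estimator = "hudson")$phi_st, 0)
})

test_that("unknown group members are rejected", {
  aln <- aln_from_strings(c(a = "ACGT", b = "ACGT"))
  expect_error(pairwise_fst(aln, list(x = "a", y = "zz")), "zz")
})

test_that("the permutation test is seeded and sane", {
  s <- c(setNames(rep("AAAA", 5), paste0("a", 1:5)),
         setNames(rep("TTTT", 5), paste0("b", 1:5)))
  aln <- aln_from_strings(s)
  g <- list(a = paste0("a", 1:5), b = paste0("b", 1:5))
  r1 <- fst_permutation_test(aln, g, n_perm = 200, seed = 4)
  r2 <- fst_permutation_test(aln, g, n_perm = 200, seed = 4)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.05)
})

test_that("Phi-ST is centered at zero under panmixia and grows with divergence", {
  phis <- vapply(1:100, function(s) {
    m <- simulate_coalescent(12, 300, 0.02, seed = 3000 + s)
    aln <- organelle_alignment(
      list(loc1 = m), tibble::tibble(locus_id = "loc1",
                                     organelle = "chloroplast"))
    # random split: the group labels must be independent of the genealogy
    acc <- withr::with_seed(6000 + s, sample(accessions(aln)))
    pairwise_fst(aln, list(a = acc[1:6], b = acc[7:12]))$phi_st_raw
  }, numeric(1))
  se <- stats::sd(phis) / sqrt(length(phis))
  expect_lt(abs(mean(phis)), 3 * se)

  # fixed differences added between the halves: monotone 3-point sweep
  sweep_phi <- vapply(c(1L, 4L, 12L), function(k) {
    m <- simulate_coalescent(12, 300, 0.02, seed = 3500)
    m[7:12, seq_len(k)] <- "T"
    m[1:6, seq_len(k)] <- "A"
    aln <- organelle_alignment(
      list(loc1 = m), tibble::tibble(locus_id = "loc1",
                                     organelle = "chloroplast"))
    acc <- accessions(aln)
    pairwise_fst(aln, list(a = acc[1:6], b = acc[7:12]))$phi_st
  }, numeric(1))
  expect_true(all(diff(sweep_phi) > 0))
})

test_that("the differentiation matrix mirrors the study's affinity pattern", {
  sim <- paper_sim()
  haps <- collapse_haplotypes(sim$alignment)
  groups <- standard_groups(sim$samples, identify_ancestors(haps, sim$samples))
  f <- fst_matrix(sim$alignment, groups)
  get <- function(a, b) {
    f$phi_st[(f$group_a == a & f$group_b == b) |
               (f$group_a == b & f$group_b == a)]
  }
  # japonica is closer to subtropical wild rice, indica to tropical
  expect_lt(get("japonica", "subtropical"), get("japonica", "tropical"))
  expect_lt(get("indica", "tropical"), get("indica", "subtropical"))
  # japonica is undifferentiated from its own (subtropical) progenitors
  expect_equal(get("japonica", "subtropical_ancestors"), 0)
})
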