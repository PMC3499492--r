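quick_cfg <- function(seed, steps = 500, burn = 500, thin = 5, alpha = 1) {
  structure_config(mcmc_steps = steps, burn_in = burn, thinning = thin,
                   alpha = alpha, seed = seed)
}

test_that("marker encoding mirrors per-locus haplotypes", {
  aln <- aln_multi(
    list(l1 = c(a = "AAAA", b = "AAAA", c = "AAAA"),   # monomorphic
         l2 = c(a = "ACGT", b = "ACGA", c = "ACGA")),  # two alleles
    organelles = c("chloroplast", "mitochondrial"))
  X <- encode_markers(aln)
  expect_equal(unname(X[, "l1"]), c(1L, 1L, 1L))
  # majority per-locus haplotype gets allele 1
  expect_equal(unname(X[, "l2"]), c(2L, 1L, 1L))
  expect_equal(unname(attr(X, "n_alleles")), c(1L, 2L))
})

test_that("fixture marker alleles match the generator truth", {
  sim <- paper_sim()
  ingroup <- sim$samples$accession[sim$samples$species != "barthii"]
  X <- encode_markers(sim$alignment, scope = ingroup)
  expect_equal(ncol(X), 10L)
  # every locus with diagnostic substitutions separates the two clades
  truth <- sim$truth
  clade <- setNames(truth$accessions$clade, truth$accessions$accession)[ingroup]
  diag_loci <- unique(truth$columns$locus[
    grepl("^diagnostic", truth$columns$origin)])
  for (l in diag_loci) {
    tab <- table(clade, X[, l])
    # no allele is shared between the clades
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("mixture log-likelihood is invariant under label permutation", {
  withr::with_seed(5, {
    X <- matrix(sample(1:3, 40, TRUE), 10, 4)
    offs <- c(0L, 3L, 6L, 9L)
    Q <- matrix(rgamma(20, 1), 10, 2); Q <- Q / rowSums(Q)
    P <- matrix(rgamma(2 * 12, 1), 2, 12)
    for (l in 1:4) P[, offs[l] + 1:3] <- P[, offs[l] + 1:3] /
        rowSums(P[, offs[l] + 1:3])
    ll <- haplorigin:::gibbs_loglik(X, Q, P, offs)
    ll_perm <- haplorigin:::gibbs_loglik(X, Q[, 2:1], P[2:1, ], offs)
    expect_equal(ll, ll_perm, tolerance = 1e-12)
  })
})

test_that("unstructured data gives symmetric memberships and prefers K=1", {
  X <- fixed_pop_markers(1, 30, 8)  # everyone identical
  attr(X, "n_alleles") <- rep(1L, 8)
  f1 <- run_gibbs(X, 1, quick_cfg(2))
  f2 <- run_gibbs(X, 2, quick_cfg(2))
  expect_equal(unname(colMeans(f2$Q)), c(0.5, 0.5), tolerance = 0.05)
  expect_gte(f1$lnpd, f2$lnpd)
})

test_that("two fixed populations are assigned to their own clusters", {
  X <- fixed_pop_markers(2, 10, 20)
  fit <- run_gibbs(X, 2, quick_cfg(7, alpha = 0.2))
  truth <- rbind(matrix(rep(c(1, 0), each = 10), 10),
                 matrix(rep(c(0, 1), each = 10), 10))
  Qa <- align_clusters(fit$Q, truth)
  expect_true(all(Qa[1:10, 1] > 0.95))
  expect_true(all(Qa[11:20, 2] > 0.95))
})

test_that("sampler output is reproducible and rows sum to one", {
  X <- fixed_pop_markers(2, 5, 6)
  f1 <- run_gibbs(X, 3, quick_cfg(11, steps = 200, burn = 200))
  f2 <- run_gibbs(X, 3, quick_cfg(11, steps = 200, burn = 200))
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$lnpd, f2$lnpd)
  expect_equal(unname(rowSums(f1$Q)), rep(1, 10), tolerance = 1e-9)
})

test_that("K selection maximizes Ln P(D) with ties to the smaller K", {
  expect_equal(select_k(tibble::tibble(K = 4L, lnpd = -10)), 4L)
  expect_equal(select_k(tibble::tibble(K = c(2L, 3L, 4L),
                                       lnpd = c(-5, -5, -7))), 2L)
  expect_equal(select_k(tibble::tibble(K = c(4L, 2L, 3L),
                                       lnpd = c(-7, -6, -2))), 3L)
})

test_that("hard assignment applies the strict majority rule", {
  Q <- rbind(c(0.7, 0.3), c(0.6, 0.4), c(0.34, 0.66))
  colnames(Q) <- c("cluster_1", "cluster_2")
  a <- assign_clusters(Q)
  expect_equal(a$assignment, c("cluster_1", "mixed", "cluster_2"))
  Q3 <- matrix(c(0.34, 0.33, 0.33), 1)
  colnames(Q3) <- paste0("cluster_", 1:3)
  expect_equal(assign_clusters(Q3)$assignment, "mixed")
  expect_error(assign_clusters(Q, threshold = 1.2), "threshold")
})

test_that("cluster alignment undoes a column permutation", {
  withr::with_seed(3, {
    Q <- matrix(rgamma(60, 1), 20, 3); Q <- Q / rowSums(Q)
    colnames(Q) <- paste0("cluster_", 1:3)
    perm <- c(3, 1, 2)
    expect_equal(unname(align_clusters(Q[, perm], Q)), unname(Q))
  })
})

test_that("invalid sampler inputs are rejected", {
  X <- fixed_pop_markers(2, 3, 4)
  expect_error(run_gibbs(X, 10, quick_cfg(1)), "between 1 and")
  expect_error(structure_config(mcmc_steps = 100, thinning = 200),
               "thinning")
})
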