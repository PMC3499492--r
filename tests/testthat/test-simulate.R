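test_that("identical seeds give byte-identical outputs", {
  sc <- paper_scenario(seed = 77L)
  s1 <- simulate_organelle(sc)
  s2 <- simulate_organelle(sc)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_identical(s1$samples, s2$samples)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(s1, d1); write_fixture(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a mutation-free scenario is monomorphic in the ingroup", {
  sc <- sim_scenario(theta_cp = 0, theta_mt = 0, n_diagnostic_cp = 0,
                     n_diagnostic_mt = 0, h3_offset_cp = 0,
                     cultivar_design = list(japonica = c(J1 = 23L),
                                            indica = c(J1 = 27L)),
                     distinct_haplotypes = FALSE, seed = 5L)
  sim <- simulate_organelle(sc)
  ingroup <- sim$samples$accession[sim$samples$species != "barthii"]
  haps <- collapse_haplotypes(sim$alignment, ingroup)
  expect_equal(nrow(haps), 1L)
  d <- diversity_stats(sim$alignment, ingroup)
  expect_equal(d$S, 0L)
})

test_that("the study-scale fixture reproduces the sampling design", {
  sim <- paper_sim()
  s <- sim$samples
  expect_equal(sum(s$subspecies == "indica"), 27L)
  expect_equal(sum(s$subspecies == "japonica"), 23L)
  expect_equal(sum(s$species == "rufipogon" & s$group == "tropical"), 73L)
  expect_equal(sum(s$species == "rufipogon" & s$group == "subtropical"), 46L)
  expect_equal(sum(s$species == "barthii"), 1L)
  expect_equal(sim$alignment$total_length, 9161L)
  expect_true(sim$alignment$total_length >= 9089 &&
                sim$alignment$total_length <= 9233)
  # no gaps or ambiguity: every column analyzable
  expect_equal(length(sim$alignment$mask), 9161L)
})

test_that("the fixture realizes the designed haplotype structure", {
  sim <- paper_sim()
  s <- sim$samples
  wild <- s$accession[s$species == "rufipogon"]
  cult <- s$accession[s$species == "sativa"]
  expect_equal(nrow(collapse_haplotypes(sim$alignment, wild)), 15L)
  expect_equal(sim$truth$n_wild_haplotypes, 15L)
  expect_equal(nrow(collapse_haplotypes(sim$alignment, cult)), 3L)
  expect_equal(nrow(collapse_haplotypes(sim$alignment)), 16L)
  # mitochondrial cultivated partition: exactly 2 haplotypes split 27/23
  mt <- partition_view(sim$alignment, "mitochondrial")
  hmt <- collapse_haplotypes(mt, cult)
  expect_equal(nrow(hmt), 2L)
  expect_setequal(hmt$n_members, c(27L, 23L))
  # the ~20% haplotype retention bottleneck
  expect_equal(3 / 15, 0.2)
  # collapsed membership agrees with truth labels
  hap_of <- haplotype_of(collapse_haplotypes(sim$alignment, wild))
  truth_hap <- setNames(sim$truth$accessions$haplotype,
                        sim$truth$accessions$accession)
  tab <- table(hap_of[wild], truth_hap[wild])
  expect_true(all(rowSums(tab > 0) == 1))  # one-to-one label mapping
})

test_that("the infinite-sites discipline holds in the ingroup", {
  sim <- paper_sim()
  ingroup <- sim$samples$accession[sim$samples$species != "barthii"]
  m <- sim$alignment$seq[ingroup, sim$alignment$mask, drop = FALSE]
  n_states <- apply(m, 2, function(x) length(unique(x)))
  expect_true(all(n_states <= 2))
  # forced diagnostics never collide with random mutation columns
  expect_false(any(duplicated(sim$truth$columns$column)))
})

test_that("impossible bottlenecks are rejected with a diagnosis", {
  sc <- sim_scenario(theta_cp = 0, theta_mt = 0, n_diagnostic_cp = 0,
                     n_diagnostic_mt = 0, h3_offset_cp = 0,
                     distinct_haplotypes = FALSE, seed = 5L)
  # three founders but only one realized wild haplotype
  expect_error(simulate_organelle(sc), "founder haplotypes")
})

test_that("coalescent alignments are seeded and dimensioned", {
  m1 <- simulate_coalescent(6, 200, 0.01, seed = 4)
  m2 <- simulate_coalescent(6, 200, 0.01, seed = 4)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(6L, 200L))
  m3 <- simulate_coalescent(6, 200, 0.01, seed = 5)
  expect_false(identical(m1, m3))
})
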