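haps_from_sigs <- function(sigs) {
  structure(
    tibble::tibble(haplotype_id = names(sigs),
                   n_members = rep(1L, length(sigs)),
                   members = as.list(names(sigs)),
                   signature = unname(sigs)),
    class = c("haplotype_tbl", "tbl_df", "tbl", "data.frame"))
}

# brute-force MST cost by enumerating spanning trees (n <= 5)
enum_mst_cost <- function(d) {
  n <- nrow(d)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (pick in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(edges[pick, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) {
      best <- min(best, sum(d[edges[pick, , drop = FALSE]]))
    }
  }
  best
}

test_that("compatible chain data yields a path without medians", {
  net <- build_mj_network(haps_from_sigs(c(h1 = "000", h2 = "100", h3 = "110")))
  expect_equal(sum(net$nodes$kind == "median"), 0L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$steps, c(1L, 1L))
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(sort(as.integer(deg)), c(1L, 1L, 2L))
})

test_that("a mutually distant triplet gains its Steiner median", {
  net <- build_mj_network(haps_from_sigs(c(h1 = "100", h2 = "010", h3 = "001")))
  med <- net$nodes[net$nodes$kind == "median", ]
  expect_equal(nrow(med), 1L)
  expect_equal(med$signature, "000")
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$steps == 1L))
  expect_equal(network_cost(net), 3)  # < any spanning tree cost (4)
})

test_that("fully sampled perfect phylogenies reproduce the spanning tree", {
  # every internal node sampled; 4 segregating columns
  sigs <- c(anc = "0000", a = "1000", b = "1100", c = "0010", d = "0011")
  net <- build_mj_network(haps_from_sigs(sigs))
  expect_equal(sum(net$nodes$kind == "median"), 0L)
  expect_equal(nrow(net$edges), 4L)           # a tree over 5 nodes
  expect_equal(sum(net$edges$steps), 4L)      # = number of segregating sites
  d <- hamming_matrix(sigs)
  expect_equal(sum(net$edges$steps), enum_mst_cost(d))
})

test_that("network cost never exceeds the sampled-haplotype MST cost", {
  for (seed in 1:6) {
    sigs <- withr::with_seed(seed, {
      v <- unique(vapply(1:5, function(i) {
        paste(sample(0:1, 8, TRUE), collapse = "")
      }, character(1)))
      setNames(v, paste0("h", seq_along(v)))
    })
    net <- build_mj_network(haps_from_sigs(sigs))
    expect_lte(network_cost(net), enum_mst_cost(hamming_matrix(sigs)))
    # every edge's steps equals the endpoint Hamming distance
    node_sig <- setNames(net$nodes$signature, net$nodes$id)
    all_d <- hamming_matrix(node_sig)
    expect_equal(net$edges$steps,
                 all_d[cbind(net$edges$from, net$edges$to)],
                 ignore_attr = TRUE)
    # connected, and all sampled haplotypes present
    expect_true(igraph::is_connected(net$graph))
    expect_true(all(names(sigs) %in% net$nodes$id))
    expect_false(any(duplicated(net$nodes$signature)))
  }
})

test_that("raising epsilon only ever adds links over a fixed node set", {
  for (seed in 7:10) {
    sigs <- withr::with_seed(seed, {
      v <- unique(vapply(1:6, function(i) {
        paste(sample(0:1, 10, TRUE), collapse = "")
      }, character(1)))
      setNames(v, paste0("h", seq_along(v)))
    })
    key <- function(net) paste(net$edges$from, net$edges$to)
    n0 <- build_mj_network(haps_from_sigs(sigs), epsilon = 0, medians = FALSE)
    n1 <- build_mj_network(haps_from_sigs(sigs), epsilon = 1, medians = FALSE)
    n2 <- build_mj_network(haps_from_sigs(sigs), epsilon = 2, medians = FALSE)
    expect_true(all(key(n0) %in% key(n1)))
    expect_true(all(key(n1) %in% key(n2)))
    # the spanning-network phase is still connected and spans all nodes
    expect_true(igraph::is_connected(n0$graph))
  }
})

test_that("identical input yields byte-identical GraphML", {
  sim <- paper_sim()
  haps <- collapse_haplotypes(sim$alignment)
  net1 <- build_mj_network(haps)
  net2 <- build_mj_network(haps)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(annotate_network(net1, haps, sim$samples), f1)
  write_network_graphml(annotate_network(net2, haps, sim$samples), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("annotation counts members per category and conserves totals", {
  aln <- aln_from_strings(c(w1 = "AAAA", w2 = "AAAA", c1 = "AAAA",
                            c2 = "AATT", o1 = "TTTT"))
  samples <- samples_for(
    c("w1", "w2", "c1", "c2", "o1"),
    species = c("rufipogon", "rufipogon", "sativa", "sativa", "barthii"),
    subspecies = c("none", "none", "indica", "indica", "none"))
  haps <- collapse_haplotypes(aln)
  net <- annotate_network(build_mj_network(haps), haps, samples)
  shared <- net$nodes[net$nodes$id == "H1", ]
  expect_equal(shared$n_rufipogon, 2L)
  expect_equal(shared$n_indica, 1L)
  expect_equal(shared$n_japonica, 0L)
  expect_equal(sum(net$nodes$n_barthii), 1L)
  expect_equal(
    sum(net$nodes$n_rufipogon + net$nodes$n_indica +
          net$nodes$n_japonica + net$nodes$n_barthii),
    nrow(samples))
  bad <- samples[samples$accession != "w2", ]
  expect_error(annotate_network(build_mj_network(haps), haps, bad), "w2")
})
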