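# Haplotype phylogeny: Kimura two-parameter distances over the masked
# columns, neighbor-joining, nonparametric bootstrap over concatenated
# masked columns, outgroup rooting.

TRANSITIONS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' proportions of transition and transversion differences over the
#' compared sites. Saturated pairs (logarithm domain violations) are
#' rejected with an informative error rather than given an arbitrary large
#' distance.
#'
#' @param a,b Character vectors of single bases (equal length), or strings.
#' @return Distance in substitutions per site (>= 0; 0 iff no differences).
#' @export
k2p_distance <- function(a, b) {
  if (length(a) == 1 && nchar(a[1]) > 1) a <- strsplit(a, "")[[1]]
  if (length(b) == 1 && nchar(b[1]) > 1) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) abort("Sequences have unequal length.")
  if (!length(a)) abort("Need at least one comparable site.")
  diff <- a != b
  ts <- sum(diff & paste0(a, b) %in% names(TRANSITIONS))
  tv <- sum(diff) - ts
  k2p_from_counts(ts, tv, length(a))
}

k2p_from_counts <- function(ts, tv, L, pair = NULL) {
  P <- ts / L; Q <- tv / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(paste0("K2P distance saturated",
                 if (!is.null(pair)) paste0(" for pair ", pair[1], "/", pair[2]),
                 " (P = ", signif(P, 3), ", Q = ", signif(Q, 3), ")."))
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2P distance matrix between haplotypes
#'
#' Distances are computed per analyzed site: transition/transversion
#' differences are counted on the variable masked columns of the haplotype
#' signatures, and divided by the full masked length, so invariant columns
#' contribute to the denominator as in a whole-alignment comparison.
#'
#' @param haps A `haplotype_tbl` from [collapse_haplotypes()].
#' @param L Total analyzed length (defaults to the masked length implied by
#'   the source alignment is not known here, so pass the alignment's
#'   `length(aln$mask)`).
#' @return Symmetric numeric matrix of K2P distances.
#' @export
k2p_matrix <- function(haps, L) {
  counts <- pair_site_counts(haps)
  n <- nrow(haps)
  d <- matrix(0, n, n, dimnames = list(haps$haplotype_id, haps$haplotype_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        ts <- sum(counts$ts[[pair_key(i, j, n)]])
        tv <- sum(counts$tv[[pair_key(i, j, n)]])
        d[i, j] <- d[j, i] <- k2p_from_counts(
          ts, tv, L, pair = haps$haplotype_id[c(i, j)])
      }
    }
  }
  d
}

pair_key <- function(i, j, n) (i - 1L) * n + j

# per-pair, per-variable-column transition/transversion indicators; shared
# by k2p_matrix and the bootstrap resampler
pair_site_counts <- function(haps) {
  chars <- do.call(rbind, strsplit(haps$signature, ""))
  if (is.null(dim(chars)) || nrow(haps) == 1) {
    chars <- matrix(character(0), nrow = nrow(haps), ncol = 0)
  }
  n <- nrow(haps)
  ts <- list(); tv <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        dif <- chars[i, ] != chars[j, ]
        is_ts <- dif & paste0(chars[i, ], chars[j, ]) %in% names(TRANSITIONS)
        ts[[pair_key(i, j, n)]] <- is_ts
        tv[[pair_key(i, j, n)]] <- dif & !is_ts
      }
    }
  }
  list(ts = ts, tv = tv, n_var = ncol(chars))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q-criterion). Negative branch lengths are
#' clamped to zero; the raw lengths are kept in the `raw_edge_length`
#' attribute. With fewer than 3 taxa a trivial tree is returned with a
#' warning.
#'
#' @param d Symmetric numeric distance matrix with taxon dimnames.
#' @return An `ape::phylo` (unrooted).
#' @export
nj_tree <- function(d) {
  if (any(d < 0) || any(abs(d - t(d)) > 1e-12)) {
    abort("Distance matrix must be symmetric and non-negative.")
  }
  n <- nrow(d)
  if (n < 3) {
    warn("Fewer than 3 taxa: returning a trivial tree.")
    if (n == 1) {
      return(ape::read.tree(text = paste0("(", rownames(d)[1], ");")))
    }
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                         rownames(d)[1], d[1, 2] / 2,
                                         rownames(d)[2], d[1, 2] / 2)))
  }
  tr <- ape::nj(as.dist(d))
  raw <- tr$edge.length
  tr$edge.length <- pmax(raw, 0)
  attr(tr, "raw_edge_length") <- raw
  tr
}

#' Root a tree on an outgroup leaf
#'
#' The root is placed at the midpoint of the outgroup's pendant edge, so
#' leaf-to-leaf path lengths are preserved.
#'
#' @param tree An `ape::phylo`.
#' @param outgroup Tip label of the outgroup.
#' @return A rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    abort(paste0("Outgroup ", outgroup, " is not a tip of the tree."))
  }
  tip <- which(tree$tip.label == outgroup)
  pend <- which(tree$edge[, 2] == tip)
  half <- tree$edge.length[pend] / 2
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  # resolve.root leaves the outgroup's full pendant length on one side and
  # a zero-length root edge on the other; split it at the midpoint
  root_node <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  og_edge <- kids[rooted$edge[kids, 2] == which(rooted$tip.label == outgroup)]
  other <- setdiff(kids, og_edge)
  rooted$edge.length[og_edge] <- half
  rooted$edge.length[other] <- rooted$edge.length[other] + half
  rooted
}

#' Bootstrap support for a haplotype NJ tree
#'
#' Alignment columns (the full masked concatenation, invariant columns
#' included) are resampled with replacement; for each replicate the K2P
#' distance matrix and NJ tree are recomputed, and the support of each
#' internal bipartition of the reference tree is the percentage of
#' replicate trees containing it. Reproducible given `seed`.
#'
#' @param aln An [organelle_alignment()]; its mask defines the columns.
#' @param haps Haplotypes over `aln` (from [collapse_haplotypes()]).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param outgroup Optional tip to root the returned tree on.
#' @return A `haplo_tree`: list with `tree` (`ape::phylo`, internal node
#'   labels = support percentages), `support` (numeric vector) and
#'   `replicates`.
#' @export
bootstrap_support <- function(aln, haps, replicates = 1000, seed = 1,
                              outgroup = NULL) {
  if (replicates < 1) abort("replicates must be >= 1.")
  L <- length(aln$mask)
  counts <- pair_site_counts(haps)
  n <- nrow(haps)
  ref <- nj_tree(k2p_matrix(haps, L))

  boot_trees <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      w_all <- stats::rmultinom(1, L, rep(1 / L, L))[, 1]
      w_var <- w_all[seq_len(counts$n_var)]  # variable columns listed first
      d <- matrix(0, n, n, dimnames = list(haps$haplotype_id, haps$haplotype_id))
      for (i in seq_len(n - 1)) {
        for (j in seq.int(i + 1, n)) {
          key <- pair_key(i, j, n)
          ts <- sum(w_var[counts$ts[[key]]])
          tv <- sum(w_var[counts$tv[[key]]])
          d[i, j] <- d[j, i] <- k2p_from_counts(
            ts, tv, L, pair = haps$haplotype_id[c(i, j)])
        }
      }
      nj_tree(d)
    })
  })

  class(boot_trees) <- "multiPhylo"
  cl <- ape::prop.clades(ref, boot_trees, rooted = FALSE)
  cl[is.na(cl)] <- 0
  support <- round(100 * cl / replicates, 1)
  ref$node.label <- as.character(support)
  pp <- ape::prop.part(ref)
  bipartitions <- tibble(
    node = ape::Ntip(ref) + seq_along(pp),
    tips = lapply(pp, function(i) ref$tip.label[i]),
    support = support
  )
  if (!is.null(outgroup)) {
    ref <- root_with_outgroup(ref, outgroup)
  }
  structure(list(tree = ref, support = support, replicates = replicates,
                 bipartitions = bipartitions),
            class = "haplo_tree")
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("<haplo_tree> ", ape::Ntip(x$tree), " haplotypes, ",
      x$replicates, " bootstrap replicates\n", sep = "")
  print(x$tree)
  invisible(x)
}

#' @describeIn bootstrap_support Tidy edge table of the supported tree.
#' @param x A `haplo_tree`.
#' @param ... Unused.
#' @export
tidy.haplo_tree <- function(x, ...) {
  tr <- x$tree
  labs <- c(tr$tip.label, tr$node.label %||% rep(NA, tr$Nnode))
  tibble(
    parent = tr$edge[, 1],
    child = tr$edge[, 2],
    length = tr$edge.length,
    child_label = labs[tr$edge[, 2]],
    is_tip = tr$edge[, 2] <= ape::Ntip(tr)
  )
}

#' Write a supported tree as newick
#'
#' Support percentages are carried as internal node labels.
#'
#' @param x A `haplo_tree` or `ape::phylo`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(x, path) {
  tr <- if (inherits(x, "haplo_tree")) x$tree else x
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP layout
#' @param d Square distance matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(
    format(nrow(d)),
    vapply(seq_len(nrow(d)), function(i) {
      paste(formatC(rownames(d)[i], width = -10),
            paste(formatC(d[i, ], format = "f", digits = 6), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
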