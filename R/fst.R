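# Pairwise differentiation between labeled groups: two-level AMOVA Phi-ST
# on pairwise sequence differences (the Arlequin-style estimator for
# haplotype sequence data), with a Hudson 1 - Hw/Hb variant for
# sensitivity analysis.

#' Pairwise Phi-ST between two groups of accessions
#'
#' Distance-based AMOVA with pairwise nucleotide differences on the masked
#' columns as squared distances. With groups `p` of sizes `n_p` (total
#' `n`):
#' \preformatted{
#'   SSD_WP = sum_p (1/n_p) sum_{i<j in p} d_ij
#'   SSD_T  = (1/n)  sum_{i<j} d_ij
#'   sigma_w2 = SSD_WP / (n - 2)
#'   n' = n - sum_p n_p^2 / n
#'   sigma_a2 = (SSD_T - SSD_WP - sigma_w2) / n'
#'   Phi_ST = sigma_a2 / (sigma_a2 + sigma_w2)
#' }
#' Conventions: when the total sum of squared distances is zero (all
#' sequences identical) Phi-ST is defined as 0; a negative `sigma_a2` is
#' clamped so Phi-ST lies in `[0, 1]`, with the raw value returned in
#' `phi_st_raw`.
#'
#' @param aln An [organelle_alignment()].
#' @param groups Named list of exactly two character vectors of accessions.
#' @param estimator `"amova"` (default) or `"hudson"` (`1 - Hw/Hb`, mean
#'   within- over between-group pairwise differences).
#' @return A one-row tibble: `group_a`, `group_b`, `phi_st`, `phi_st_raw`,
#'   `sigma_a2`, `sigma_w2`, `n_prime`, `n_a`, `n_b`.
#' @export
pairwise_fst <- function(aln, groups, estimator = c("amova", "hudson")) {
  estimator <- match.arg(estimator)
  if (length(groups) != 2 || is.null(names(groups))) {
    abort("`groups` must be a named list of two accession vectors.")
  }
  acc_a <- groups[[1]]; acc_b <- groups[[2]]
  missing <- setdiff(c(acc_a, acc_b), accessions(aln))
  if (length(missing)) {
    abort(paste0("Unknown accessions/group members: ",
                 paste(missing, collapse = ", ")))
  }
  if (!length(acc_a) || !length(acc_b)) abort("Both groups need >= 1 sequence.")

  all_acc <- c(acc_a, acc_b)
  d <- pair_diff_matrix(aln, all_acc)
  lab <- rep(c(1L, 2L), c(length(acc_a), length(acc_b)))
  res <- amova_phist(d, lab)

  if (estimator == "hudson") {
    hb <- mean(d[lab == 1L, lab == 2L, drop = FALSE])
    hw_terms <- c(
      if (length(acc_a) > 1) d[lab == 1L, lab == 1L][upper.tri(diag(length(acc_a)))],
      if (length(acc_b) > 1) d[lab == 2L, lab == 2L][upper.tri(diag(length(acc_b)))]
    )
    hw <- if (length(hw_terms)) mean(hw_terms) else 0
    res$phi_st <- if (hb == 0) 0 else max(0, min(1, 1 - hw / hb))
    res$phi_st_raw <- if (hb == 0) 0 else 1 - hw / hb
  }

  tibble(group_a = names(groups)[1], group_b = names(groups)[2],
         phi_st = res$phi_st, phi_st_raw = res$phi_st_raw,
         sigma_a2 = res$sigma_a2, sigma_w2 = res$sigma_w2,
         n_prime = res$n_prime,
         n_a = length(acc_a), n_b = length(acc_b))
}

# core AMOVA variance components on a pairwise-difference matrix with
# integer group labels (1, 2)
amova_phist <- function(d, lab) {
  n <- length(lab)
  sizes <- tabulate(lab)
  ssd_t <- sum(d[upper.tri(d)]) / n
  ssd_wp <- 0
  for (g in unique(lab)) {
    idx <- which(lab == g)
    if (length(idx) > 1) {
      dg <- d[idx, idx, drop = FALSE]
      ssd_wp <- ssd_wp + sum(dg[upper.tri(dg)]) / length(idx)
    }
  }
  if (ssd_t == 0) {
    return(list(phi_st = 0, phi_st_raw = 0, sigma_a2 = 0, sigma_w2 = 0,
                n_prime = n - sum(sizes^2) / n))
  }
  sigma_w2 <- if (n > 2) ssd_wp / (n - 2) else 0
  n_prime <- n - sum(sizes^2) / n
  ms_ap <- ssd_t - ssd_wp  # between-group SSD, df = 1 for two groups
  sigma_a2 <- (ms_ap - sigma_w2) / n_prime
  denom <- sigma_a2 + sigma_w2
  phi_raw <- if (denom == 0) 0 else sigma_a2 / denom
  list(phi_st = max(0, min(1, phi_raw)), phi_st_raw = phi_raw,
       sigma_a2 = sigma_a2, sigma_w2 = sigma_w2, n_prime = n_prime)
}

# pairwise nucleotide differences between accessions over masked columns,
# computed on collapsed haplotypes for speed
pair_diff_matrix <- function(aln, acc) {
  haps <- collapse_haplotypes(aln, acc)
  hap_of <- haplotype_of(haps)[acc]
  k <- hamming_matrix(haps)
  d <- k[hap_of, hap_of, drop = FALSE]
  dimnames(d) <- list(acc, acc)
  d
}

#' Pairwise Phi-ST matrix over several groups
#'
#' @param aln An [organelle_alignment()].
#' @param groups Named list of accession vectors (>= 2 groups).
#' @param estimator Passed to [pairwise_fst()].
#' @return A tibble with one row per unordered group pair.
#' @export
fst_matrix <- function(aln, groups, estimator = "amova") {
  nm <- names(groups)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    pairwise_fst(aln, groups[p], estimator = estimator)
  })
}

#' Permutation test for Phi-ST
#'
#' Permutes group labels across the pooled accessions and recomputes
#' Phi-ST; the p-value is the fraction of permuted values greater than or
#' equal to the observed one (with the +1 correction).
#'
#' @param aln An [organelle_alignment()].
#' @param groups Named list of two accession vectors.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return A one-row tibble: observed `phi_st`, `p_value`, `n_perm`.
#' @export
fst_permutation_test <- function(aln, groups, n_perm = 1000, seed = 1) {
  obs <- pairwise_fst(aln, groups)$phi_st
  acc <- c(groups[[1]], groups[[2]])
  n_a <- length(groups[[1]])
  d <- pair_diff_matrix(aln, acc)
  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- rep(2L, length(acc))
      lab[sample(length(acc), n_a)] <- 1L
      amova_phist(d, lab)$phi_st
    }, numeric(1))
  })
  tibble(phi_st = obs,
         p_value = (sum(perm_stats >= obs) + 1) / (n_perm + 1),
         n_perm = n_perm)
}

#' Standard comparison groups for the differentiation table
#'
#' Builds the named accession groups used in the pairwise differentiation
#' summary: the two cultivated subspecies, the two wild latitude groups,
#' and (when an ancestry summary is supplied) the wild progenitor
#' accessions split by latitude group.
#'
#' @param samples Validated sample metadata.
#' @param ancestry Optional output of [identify_ancestors()].
#' @return Named list of accession character vectors.
#' @export
standard_groups <- function(samples, ancestry = NULL) {
  g <- list(
    japonica = samples$accession[samples$subspecies == "japonica"],
    indica = samples$accession[samples$subspecies == "indica"],
    tropical = samples$accession[samples$group == "tropical"],
    subtropical = samples$accession[samples$group == "subtropical"]
  )
  if (!is.null(ancestry)) {
    prog <- ancestry$accession[ancestry$progenitor_of != "none"]
    g$tropical_ancestors <- intersect(prog, g$tropical)
    g$subtropical_ancestors <- intersect(prog, g$subtropical)
  }
  g[lengths(g) > 0]
}
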