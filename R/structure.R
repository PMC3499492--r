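# Model-based clustering of multilocus haploid data: admixture model with
# independent allele frequencies, fitted by Gibbs sampling. Each
# individual i carries one allele x_il per locus l; its origin z_il is
# cluster-distributed with individual admixture proportions q_i, and
# cluster k holds allele frequencies p_kl. Conjugate updates:
#   z_il | q, p  ~ Categorical over k of q_ik p_kl[x_il]
#   p_kl. | z    ~ Dirichlet(lambda + allele counts assigned to k)
#   q_i  | z     ~ Dirichlet(alpha + per-cluster counts over loci)
# Model evidence is approximated as mean(lnL) - var(lnL)/2 over retained
# sweeps, with lnL the mixture log-likelihood at the sweep's (q, p).

#' MCMC configuration for the admixture Gibbs sampler
#'
#' Defaults mirror the study protocol: 100,000 burn-in sweeps, 100,000
#' sampling sweeps, thinning interval 10, admixture parameter `alpha = 1`
#' (fixed) and allele-frequency prior `lambda = 1`. Tests and quick runs
#' should pass much smaller `burn_in`/`mcmc_steps`.
#'
#' @param mcmc_steps Post-burn-in sweeps.
#' @param burn_in Discarded initial sweeps.
#' @param thinning Keep every `thinning`-th post-burn-in sweep.
#' @param alpha Dirichlet admixture parameter (fixed, not resampled).
#' @param lambda Dirichlet allele-frequency parameter.
#' @param seed Integer seed.
#' @return A `structure_config` list.
#' @export
structure_config <- function(mcmc_steps = 100000, burn_in = 100000,
                             thinning = 10, alpha = 1, lambda = 1, seed = 1) {
  if (mcmc_steps < 1 || burn_in < 0 || thinning < 1) {
    abort("MCMC sizes must be positive.")
  }
  if (thinning > mcmc_steps) abort("thinning cannot exceed mcmc_steps.")
  structure(list(mcmc_steps = mcmc_steps, burn_in = burn_in,
                 thinning = thinning, alpha = alpha, lambda = lambda,
                 seed = seed),
            class = "structure_config")
}

#' Encode per-locus haplotypes as a marker table
#'
#' Collapses each locus separately within the scope; the distinct per-locus
#' haplotypes are the alleles of that marker (numbered by decreasing
#' frequency), and each haploid individual carries one allele per locus.
#'
#' @param aln An [organelle_alignment()].
#' @param scope Accessions to encode (default: all).
#' @return A `marker_table`: integer matrix individuals x loci, with a
#'   `n_alleles` attribute (alleles per locus).
#' @export
encode_markers <- function(aln, scope = NULL) {
  scope <- scope %||% accessions(aln)
  sub <- subset_accessions(aln, scope)
  X <- matrix(0L, length(scope), nrow(aln$loci),
              dimnames = list(scope, aln$loci$locus_id))
  for (i in seq_len(nrow(aln$loci))) {
    li <- aln$loci[i, ]
    cols <- intersect(seq.int(li$start, li$end), aln$mask)
    m <- sub$seq[, cols, drop = FALSE]
    sig <- apply(m, 1, paste, collapse = "")
    first <- !duplicated(sig)
    lev <- sig[first]
    counts <- table(factor(sig, levels = lev))
    ord <- order(-as.integer(counts), seq_along(lev))
    X[, i] <- match(sig, lev[ord])
  }
  structure(X, n_alleles = apply(X, 2, max), class = c("marker_table", "matrix"))
}

#' Fit the admixture model for one K by Gibbs sampling
#'
#' @param markers A `marker_table` from [encode_markers()] (or any integer
#'   matrix of 1-based allele codes, individuals x loci).
#' @param K Number of clusters (1 <= K <= number of individuals).
#' @param config A [structure_config()].
#' @return A list: `Q` (posterior-mean membership matrix, rows sum to 1),
#'   `lnpd` (model evidence approximation), `lnl` (retained log-likelihood
#'   trace), `K`.
#' @export
run_gibbs <- function(markers, K, config = structure_config()) {
  X <- unclass(markers)
  n <- nrow(X); L <- ncol(X)
  if (!n || !L) abort("Marker table is empty.")
  if (K < 1 || K > n) abort("K must be between 1 and the individual count.")
  n_alleles <- attr(markers, "n_alleles") %||% apply(X, 2, max)
  alpha <- config$alpha; lambda <- config$lambda

  # allele lookup offsets so p can live in one K x sum(A_l) matrix
  offs <- cumsum(c(0L, n_alleles[-L]))
  Xoff <- sweep(X, 2, offs, "+")  # n x L, flat allele index
  A_tot <- sum(n_alleles)
  col_locus <- rep(seq_len(L), n_alleles)

  withr::with_seed(config$seed, {
    P <- matrix(0, K, A_tot)
    for (l in seq_len(L)) {
      cols <- which(col_locus == l)
      g <- matrix(rgamma(K * length(cols), shape = lambda), K)
      P[, cols] <- g / rowSums(g)
    }
    Qm <- matrix(rgamma(n * K, shape = alpha), n, K)
    Qm <- Qm / rowSums(Qm)

    n_keep <- config$mcmc_steps %/% config$thinning
    Q_acc <- matrix(0, n, K)
    lnl_keep <- numeric(n_keep)
    kept <- 0L
    total <- config$burn_in + config$mcmc_steps

    for (sweep_i in seq_len(total)) {
      # z update: Gumbel-max over K for all (i, l) cells at once
      logits <- array(0, dim = c(n, L, K))
      logQ <- log(Qm); logP <- log(P)
      for (k in seq_len(K)) {
        logits[, , k] <- logQ[, k] + matrix(logP[k, Xoff], n, L)
      }
      gum <- -log(-log(array(runif(n * L * K), dim = c(n, L, K))))
      Z <- max.col(matrix(logits + gum, n * L, K))  # n*L vector in 1..K
      dim(Z) <- c(n, L)

      # p update: Dirichlet with allele counts per (k, flat allele)
      cnt_p <- matrix(
        tabulate((as.vector(Xoff) - 1L) * K + as.vector(Z), K * A_tot),
        K, A_tot)
      g <- matrix(rgamma(K * A_tot, shape = lambda + cnt_p), K)
      for (l in seq_len(L)) {
        cols <- which(col_locus == l)
        P[, cols] <- g[, cols, drop = FALSE] /
          rowSums(g[, cols, drop = FALSE])
      }

      # q update: Dirichlet with per-individual cluster counts
      cnt_q <- vapply(seq_len(K), function(k) rowSums(Z == k), numeric(n))
      if (n == 1) cnt_q <- matrix(cnt_q, 1, K)
      g <- matrix(rgamma(n * K, shape = alpha + cnt_q), n, K)
      Qm <- g / rowSums(g)

      s <- sweep_i - config$burn_in
      if (s >= 1 && s %% config$thinning == 0) {
        kept <- kept + 1L
        Q_acc <- Q_acc + Qm
        mix <- matrix(0, n, L)
        for (k in seq_len(K)) {
          mix <- mix + Qm[, k] * matrix(P[k, Xoff], n, L)
        }
        lnl_keep[kept] <- sum(log(mix))
      }
    }

    Q <- Q_acc / kept
    dimnames(Q) <- list(rownames(X), paste0("cluster_", seq_len(K)))
    lnpd <- mean(lnl_keep) - if (kept > 1) var(lnl_keep) / 2 else 0
    list(Q = Q, lnpd = lnpd, lnl = lnl_keep, K = K)
  })
}

# mixture log-likelihood at given (Q, P); reference implementation used by
# tests to cross-check the sampler's bookkeeping
gibbs_loglik <- function(X, Q, P_flat, offs) {
  n <- nrow(X); L <- ncol(X); K <- nrow(P_flat)
  ll <- 0
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      ll <- ll + log(sum(Q[i, ] * P_flat[, offs[l] + X[i, l]]))
    }
  }
  ll
}

#' Run the clustering over a range of K and select the best
#'
#' Fits [run_gibbs()] for each K, selects `best_k` as the argmax of the
#' Ln P(D) approximation (ties broken toward smaller K), and derives hard
#' assignments by the strict majority-membership rule.
#'
#' @param markers A `marker_table`.
#' @param k_range Integer vector of K values (default 2:10).
#' @param config A [structure_config()]; each K uses `seed + K` so runs are
#'   independent but reproducible.
#' @param threshold Membership threshold for hard assignment (default 0.6;
#'   strictly greater than).
#' @return A `structure_result`: list with `runs` (per-K fits), `lnpd`
#'   (tibble K x Ln P(D)), `best_k`, `Q` (best-K matrix), `assignments`
#'   (tibble: individual, assignment).
#' @export
run_structure <- function(markers, k_range = 2:10,
                          config = structure_config(), threshold = 0.6) {
  runs <- lapply(k_range, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    run_gibbs(markers, k, cfg)
  })
  names(runs) <- paste0("K", k_range)
  lnpd <- tibble(K = as.integer(k_range),
                 lnpd = vapply(runs, `[[`, numeric(1), "lnpd"))
  best_k <- select_k(lnpd)
  Q <- runs[[paste0("K", best_k)]]$Q
  structure(list(runs = runs, lnpd = lnpd, best_k = best_k, Q = Q,
                 assignments = assign_clusters(Q, threshold)),
            class = "structure_result")
}

#' Select K by the model-evidence approximation
#'
#' @param lnpd A tibble with columns `K` and `lnpd` (as in
#'   [run_structure()]'s `lnpd` element).
#' @return The K maximizing Ln P(D); ties go to the smaller K.
#' @export
select_k <- function(lnpd) {
  lnpd <- arrange(as_tibble(lnpd), .data$K)
  lnpd$K[which.max(lnpd$lnpd)]
}

#' Hard cluster assignment by majority membership
#'
#' An individual is assigned to a cluster only when its membership
#' proportion strictly exceeds the threshold; otherwise it is `"mixed"`.
#'
#' @param Q Membership matrix (rows sum to 1).
#' @param threshold In (0, 1); default 0.6.
#' @return Tibble: `individual`, `assignment` (cluster column name or
#'   `"mixed"`), `max_q`.
#' @export
assign_clusters <- function(Q, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1).")
  best <- max.col(Q, ties.method = "first")
  maxq <- Q[cbind(seq_len(nrow(Q)), best)]
  tibble(
    individual = rownames(Q) %||% as.character(seq_len(nrow(Q))),
    assignment = ifelse(maxq > threshold, colnames(Q)[best], "mixed"),
    max_q = maxq
  )
}

#' Align cluster labels of a membership matrix to a reference
#'
#' Greedy maximal-overlap matching of columns, used only for reporting and
#' for comparing replicate runs (cluster labels are arbitrary under the
#' model).
#'
#' @param Q Membership matrix to relabel.
#' @param ref Reference matrix with the same number of rows.
#' @return `Q` with columns permuted to best match `ref`.
#' @export
align_clusters <- function(Q, ref) {
  K <- ncol(Q)
  Kr <- ncol(ref)
  overlap <- crossprod(ref, Q)  # Kr x K total joint membership
  perm <- integer(K)
  used_ref <- logical(Kr); used_q <- logical(K)
  for (step in seq_len(min(K, Kr))) {
    o <- overlap
    o[used_ref, ] <- -Inf; o[, used_q] <- -Inf
    ij <- arrayInd(which.max(o), dim(o))
    perm[ij[1]] <- ij[2]
    used_ref[ij[1]] <- TRUE; used_q[ij[2]] <- TRUE
  }
  if (K > Kr) perm[perm == 0] <- which(!used_q)
  out <- Q[, perm[perm > 0], drop = FALSE]
  colnames(out) <- colnames(ref)[seq_len(ncol(out))]
  out
}

#' @export
print.structure_result <- function(x, ...) {
  cat("<structure_result> K swept ", min(x$lnpd$K), "-", max(x$lnpd$K),
      "; best K = ", x$best_k, "\n", sep = "")
  print(x$lnpd)
  invisible(x)
}

#' @describeIn run_structure Long tibble of best-K memberships.
#' @param x A `structure_result`.
#' @param ... Unused.
#' @export
tidy.structure_result <- function(x, ...) {
  as_tibble(x$Q, rownames = "individual") |>
    tidyr::pivot_longer(-"individual", names_to = "cluster",
                        values_to = "proportion") |>
    left_join(x$assignments, by = "individual")
}

#' @describeIn run_structure One-row model summary.
#' @export
glance.structure_result <- function(x, ...) {
  tibble(best_k = x$best_k,
         lnpd_best = x$lnpd$lnpd[x$lnpd$K == x$best_k],
         k_min = min(x$lnpd$K), k_max = max(x$lnpd$K),
         n_mixed = sum(x$assignments$assignment == "mixed"))
}

#' Plot membership proportions as stacked bars
#'
#' @param object A `structure_result`.
#' @param order_by Optional factor/character vector (one per individual)
#'   used to group the bars, e.g. species or latitude group.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_result <- function(object, order_by = NULL, ...) {
  d <- tidy(object)
  if (!is.null(order_by)) {
    ord <- tibble(individual = rownames(object$Q), grp = order_by)
    d <- left_join(d, ord, by = "individual") |>
      mutate(individual = factor(.data$individual,
                                 levels = ord$individual[order(ord$grp)]))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$individual, y = .data$proportion,
                                  fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "membership")
}

#' Write structure outputs as TSV
#' @param x A `structure_result`.
#' @param q_path,lnpd_path Output files for the best-K Q matrix (with
#'   assignments) and the Ln P(D) by K table.
#' @return Invisibly, the paths.
#' @export
write_structure <- function(x, q_path, lnpd_path) {
  q <- as_tibble(x$Q, rownames = "individual") |>
    left_join(x$assignments[, c("individual", "assignment")], by = "individual")
  readr::write_tsv(q, q_path)
  readr::write_tsv(x$lnpd, lnpd_path)
  invisible(c(q_path, lnpd_path))
}
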