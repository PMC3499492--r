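# Standard polymorphism summaries on the masked alignment: segregating
# sites S, haplotype count h, haplotype diversity Hd, nucleotide diversity
# pi, and Watterson's theta from S. All per-site quantities use the full
# analyzed length L (the masked column count), matching how the study's
# printed values back-calculate.

#' Diversity statistics for one scope of a partitioned alignment
#'
#' Computes, over the analyzed (masked) columns:
#' \describe{
#'   \item{S}{number of segregating sites (columns with >1 state in scope)}
#'   \item{h}{number of distinct haplotypes}
#'   \item{Hd}{unbiased haplotype diversity, `n/(n-1) * (1 - sum p_i^2)`
#'     over haplotype frequencies `p_i`}
#'   \item{pi}{per-site nucleotide diversity: mean pairwise differences
#'     divided by L, computed over all C(n,2) sequence pairs}
#'   \item{theta_w}{Watterson's estimator `S / (a * L)` with
#'     `a = sum_{k=1}^{n-1} 1/k`}
#' }
#'
#' @param aln An [organelle_alignment()] (typically a [partition_view()]).
#' @param scope Accessions to include (default: all). At least 2 required.
#' @param scope_label Label recorded in the output row.
#' @param organelle_label Label recorded in the output row; defaults to
#'   `"combined"` for multi-organelle views.
#' @return A one-row tibble: `scope`, `organelle`, `n`, `S`, `h`, `Hd`,
#'   `pi`, `theta_w`, `L`.
#' @export
diversity_stats <- function(aln, scope = NULL, scope_label = "all",
                            organelle_label = NULL) {
  scope <- scope %||% accessions(aln)
  n <- length(scope)
  if (n < 2) abort("Diversity estimators need at least 2 sequences.")
  L <- length(aln$mask)
  if (L < 1) abort("No analyzable columns (empty mask).")
  organelle_label <- organelle_label %||%
    (if (length(unique(aln$loci$organelle)) == 1) aln$loci$organelle[[1]] else "combined")

  haps <- collapse_haplotypes(aln, scope)
  S <- length(variable_columns(haps))
  h <- nrow(haps)
  p <- haps$n_members / n
  Hd <- if (h == 1) 0 else n / (n - 1) * (1 - sum(p^2))

  # pi from haplotype frequencies: sum_{i<j} n_i n_j k_ij / (C(n,2) L);
  # identical to the all-pairs definition since within-haplotype d = 0
  k <- hamming_matrix(haps)
  cnt <- haps$n_members
  total_diffs <- sum((cnt %o% cnt) * k) / 2
  pi <- total_diffs / choose(n, 2) / L

  a <- sum(1 / seq_len(n - 1))
  theta_w <- S / (a * L)

  tibble(scope = scope_label, organelle = organelle_label,
         n = n, S = S, h = h, Hd = Hd, pi = pi, theta_w = theta_w, L = L)
}

#' Per-organelle and combined diversity summary for both species
#'
#' The standard six-row polymorphism table: chloroplast, mitochondrial and
#' combined views crossed with cultivated (*O. sativa*) and wild
#' (*O. rufipogon*) scopes. Because the chloroplast and mitochondrial masks
#' partition the combined mask, each species' combined S equals the sum of
#' its per-organelle S.
#'
#' @param aln An [organelle_alignment()] over all loci.
#' @param samples Validated sample metadata (see [validate_samples()]).
#' @return A tibble with one [diversity_stats()] row per (organelle,
#'   species) cell.
#' @export
diversity_table <- function(aln, samples) {
  scopes <- list(
    sativa = samples$accession[samples$species == "sativa"],
    rufipogon = samples$accession[samples$species == "rufipogon"]
  )
  views <- list(
    chloroplast = partition_view(aln, "chloroplast"),
    mitochondrial = partition_view(aln, "mitochondrial"),
    combined = aln
  )
  purrr::map_dfr(names(views), function(v) {
    purrr::map_dfr(names(scopes), function(s) {
      diversity_stats(views[[v]], scopes[[s]], scope_label = s,
                      organelle_label = v)
    })
  })
}

#' Write a diversity table in the printed-table layout
#'
#' `pi` and `theta_w` are reported multiplied by 10^3 at 2 decimal places,
#' the convention used for organelle-scale diversities.
#'
#' @param tab Output of [diversity_table()] or rows of [diversity_stats()].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(tab, path) {
  out <- tab |>
    mutate(Hd = round(.data$Hd, 3),
           pi_e3 = round(.data$pi * 1e3, 2),
           theta_e3 = round(.data$theta_w * 1e3, 2)) |>
    select("organelle", "scope", "n", "S", "h", "Hd", "pi_e3", "theta_e3", "L")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Unbiased haplotype diversity from haplotype counts
#'
#' Convenience closed form `n/(n-1) * (1 - sum p_i^2)`; with two haplotypes
#' this reduces to `n/(n-1) * 2 p q`.
#'
#' @param counts Integer vector of haplotype member counts.
#' @return Haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  n <- sum(counts)
  if (n < 2) abort("Need at least 2 sequences.")
  if (length(counts) == 1) return(0)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Watterson's theta per site from a segregating-site count
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (>= 2).
#' @param L Analyzed length in sites.
#' @return `S / (a * L)` with `a = sum_{k=1}^{n-1} 1/k`.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) abort("Need at least 2 sequences.")
  if (L < 1) abort("Need positive length.")
  S / (sum(1 / seq_len(n - 1)) * L)
}
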