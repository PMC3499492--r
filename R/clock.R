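# Molecular-clock dating of the indica/japonica divergence from fixed
# (diagnostic) substitutions, using organelle rates scaled from the rice
# nuclear rate by the mitochondrial:chloroplast:nuclear ratio 1:3:12.

#' Clock parameters
#'
#' @param mu Nuclear substitution rate per site per year (default
#'   7.16e-9, the rice nuclear-gene estimate).
#' @param multiplier_cp,multiplier_mt Multipliers applied in the dating
#'   formula `T = multiplier * N / (L * mu)`: 3 for chloroplast and 12 for
#'   mitochondrial loci, reflecting the 1:3:12 mt:cp:nuclear rate ratio.
#' @return A `clock_params` list.
#' @export
clock_params <- function(mu = 7.16e-9, multiplier_cp = 3, multiplier_mt = 12) {
  if (mu <= 0 || multiplier_cp <= 0 || multiplier_mt <= 0) {
    abort("Rate and multipliers must be positive.")
  }
  structure(list(mu = mu, multiplier_cp = multiplier_cp,
                 multiplier_mt = multiplier_mt),
            class = "clock_params")
}

#' Count sites diagnostic between indica and japonica
#'
#' A masked column is diagnostic when every indica accession carries one
#' state and every japonica accession carries a different single state —
#' a fixed difference between the subspecies, with no frequency threshold.
#'
#' @param aln An [organelle_alignment()] (typically a [partition_view()]).
#' @param samples Validated sample metadata; both subspecies must be
#'   present.
#' @return Integer count of diagnostic columns, with the column indices as
#'   attribute `columns`.
#' @export
count_diagnostic_sites <- function(aln, samples) {
  ind <- samples$accession[samples$subspecies == "indica"]
  jap <- samples$accession[samples$subspecies == "japonica"]
  ind <- intersect(ind, accessions(aln))
  jap <- intersect(jap, accessions(aln))
  if (!length(ind) || !length(jap)) {
    abort("Both indica and japonica accessions are required.")
  }
  m_ind <- masked_seq(aln, ind)
  m_jap <- masked_seq(aln, jap)
  fixed_ind <- apply(m_ind, 2, function(x) if (length(unique(x)) == 1) x[1] else NA)
  fixed_jap <- apply(m_jap, 2, function(x) if (length(unique(x)) == 1) x[1] else NA)
  diag_cols <- which(!is.na(fixed_ind) & !is.na(fixed_jap) &
                       fixed_ind != fixed_jap)
  structure(length(diag_cols), columns = as.integer(aln$mask[diag_cols]))
}

#' Divergence time from diagnostic substitutions
#'
#' Applies the printed organelle clock formula exactly:
#' `T = 3 N / (L mu)` for chloroplast loci and `T = 12 N / (L mu)` for
#' mitochondrial loci, with `N` diagnostic substituted sites, `L` the
#' analyzed length and `mu` the nuclear rate. The result also carries, in
#' the `alternatives` attribute, the times implied by reading the 1:3:12
#' ratio as an organelle rate scaling (`T = N / (2 L r)` with
#' `r = mu * ratio / 12`), since the two readings differ.
#'
#' @param N Diagnostic site count (>= 0).
#' @param L Analyzed length in sites (> 0).
#' @param organelle `"chloroplast"` or `"mitochondrial"`.
#' @param params A [clock_params()].
#' @return A one-row tibble: `organelle`, `N`, `L`, `mu`, `multiplier`,
#'   `T_years`, `T_Myr` (2 d.p.).
#' @export
divergence_time <- function(N, L, organelle = c("chloroplast", "mitochondrial"),
                            params = clock_params()) {
  organelle <- match.arg(organelle)
  if (L <= 0) abort("L must be positive.")
  if (N < 0) abort("N must be non-negative.")
  m <- if (organelle == "chloroplast") params$multiplier_cp else params$multiplier_mt
  T_years <- m * N / (L * params$mu)
  ratio <- if (organelle == "chloroplast") 3 else 1  # of nuclear = 12
  r_org <- params$mu * ratio / 12
  alt <- tibble(
    interpretation = c("printed_formula", "rate_scaled_coalescent"),
    T_years = c(T_years, N / (2 * L * r_org))
  )
  out <- tibble(organelle = organelle, N = as.integer(N), L = as.integer(L),
                mu = params$mu, multiplier = m,
                T_years = T_years, T_Myr = round(T_years / 1e6, 2))
  attr(out, "alternatives") <- alt
  out
}

#' Organelle divergence-time table for a dataset
#'
#' Counts diagnostic sites on the chloroplast and mitochondrial views and
#' converts each to years with [divergence_time()].
#'
#' @param aln Combined [organelle_alignment()].
#' @param samples Validated sample metadata.
#' @param params A [clock_params()].
#' @return Two-row tibble (one per organelle).
#' @export
clock_table <- function(aln, samples, params = clock_params()) {
  purrr::map_dfr(c("chloroplast", "mitochondrial"), function(org) {
    v <- partition_view(aln, org)
    N <- count_diagnostic_sites(v, samples)
    divergence_time(as.integer(N), length(v$mask), org, params)
  })
}
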