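# Haplotype collapsing: identical masked sequences belong to one haplotype.

#' Collapse aligned sequences into haplotypes
#'
#' Two accessions share a haplotype exactly when their sequences are
#' identical at every analyzed (masked) column. Haplotype signatures are
#' restricted to the columns that are variable within the requested scope,
#' and haplotypes are labelled `H1`, `H2`, ... by decreasing member count,
#' ties broken by order of first occurrence, so labels are deterministic.
#'
#' @param aln An [organelle_alignment()].
#' @param scope Character vector of accessions to collapse (default: all).
#' @param remask Recompute complete-deletion masking within the scope
#'   instead of keeping the global analysis mask.
#'
#' @return A tibble of class `haplotype_tbl` with columns `haplotype_id`,
#'   `n_members`, `members` (list-column of accession vectors) and
#'   `signature` (string over the variable columns). Attributes:
#'   `variable_columns` (1-based concatenated column indices of the
#'   signature positions) and `scope`.
#' @export
collapse_haplotypes <- function(aln, scope = NULL, remask = FALSE) {
  scope <- scope %||% accessions(aln)
  if (!length(scope)) abort("Empty scope: no accessions to collapse.")
  sub <- subset_accessions(aln, scope, remask = remask)
  m <- masked_seq(sub)

  variable <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
  sig_mat <- m[, variable, drop = FALSE]
  sigs <- apply(sig_mat, 1, paste, collapse = "")
  if (!length(variable)) sigs <- rep("", nrow(m))

  first_seen <- !duplicated(sigs)
  key <- factor(sigs, levels = sigs[first_seen])
  counts <- as.integer(table(key))
  ord <- order(-counts, seq_along(counts))

  members <- split(scope, key)[ord]  # split returns components in level order
  out <- tibble(
    haplotype_id = paste0("H", seq_along(ord)),
    n_members = counts[ord],
    members = unname(members),
    signature = levels(key)[ord]
  )
  structure(out,
            variable_columns = as.integer(sub$mask[variable]),
            scope = scope,
            class = c("haplotype_tbl", class(out)))
}

#' Variable columns backing a haplotype table's signatures
#' @param haps A `haplotype_tbl`.
#' @return Integer vector of 1-based concatenated column indices.
#' @export
variable_columns <- function(haps) attr(haps, "variable_columns")

#' Map accessions to their haplotype ids
#' @param haps A `haplotype_tbl`.
#' @return Named character vector, accession -> haplotype_id.
#' @export
haplotype_of <- function(haps) {
  setNames(
    rep(haps$haplotype_id, lengths(haps$members)),
    unlist(haps$members)
  )
}

#' Pairwise Hamming distances between haplotype signatures
#'
#' @param haps A `haplotype_tbl`, or a character vector of equal-length
#'   signature strings.
#' @return Symmetric integer matrix of differing-position counts, zero
#'   diagonal, dimnames set to haplotype ids.
#' @export
hamming_matrix <- function(haps) {
  if (inherits(haps, "haplotype_tbl")) {
    sigs <- setNames(haps$signature, haps$haplotype_id)
  } else {
    sigs <- haps
    if (is.null(names(sigs))) names(sigs) <- paste0("H", seq_along(sigs))
  }
  if (!length(sigs)) abort("Need at least one haplotype.")
  if (length(unique(nchar(sigs))) > 1L) {
    abort("Signatures have unequal lengths.")
  }
  chars <- do.call(rbind, strsplit(sigs, ""))
  if (nchar(sigs[1]) == 0L) chars <- matrix("", nrow = length(sigs), ncol = 0)
  n <- length(sigs)
  d <- matrix(0L, n, n, dimnames = list(names(sigs), names(sigs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
      }
    }
  }
  d
}

#' Write a haplotype table as TSV
#'
#' Members are flattened to a semicolon-separated list.
#'
#' @param haps A `haplotype_tbl`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(haps, path) {
  flat <- tibble(
    haplotype_id = haps$haplotype_id,
    n_members = haps$n_members,
    members = vapply(haps$members, paste, character(1), collapse = ";"),
    signature = haps$signature
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
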