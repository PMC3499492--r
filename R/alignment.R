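# Partitioned organelle alignment: per-locus aligned sequences concatenated
# into one accession x column character matrix, with a locus/partition table
# and a global analysis mask (complete deletion of gap/missing/ambiguous
# columns).

VALID_CHARS <- c("A", "C", "G", "T", "-", "N",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?")
CLEAN_CHARS <- c("A", "C", "G", "T")
ORGANELLES <- c("chloroplast", "mitochondrial")

#' Assemble a partitioned organelle alignment
#'
#' Concatenates per-locus aligned sequence matrices into a single alignment,
#' records the partition (locus boundaries and organelle of each locus), and
#' computes the global analysis mask: the set of concatenated columns at
#' which every accession carries an unambiguous base (A/C/G/T). Columns
#' containing a gap, `N`, `?`, or any IUPAC ambiguity code in any accession
#' are excluded from all downstream statistics (complete deletion), which is
#' how indel and missing-data columns are dropped from the analysis.
#'
#' @param loci Named list of character matrices, one per locus, in partition
#'   order. Each matrix has one row per accession (rownames are accession
#'   ids) and one column per aligned position; entries are single upper-case
#'   characters from the IUPAC DNA alphabet plus `-`.
#' @param partition Data frame with columns `locus_id` and `organelle`
#'   (`"chloroplast"` or `"mitochondrial"`), one row per locus.
#'
#' @return An object of class `organelle_alignment`: a list with elements
#'   `seq` (accession x column character matrix), `loci` (tibble with
#'   `locus_id`, `organelle`, `start`, `end`, `length`; coordinates are
#'   1-based inclusive in the concatenation), `mask` (sorted integer vector
#'   of analysis columns) and `total_length`.
#' @export
organelle_alignment <- function(loci, partition) {
  partition <- as_tibble(partition)
  if (!all(c("locus_id", "organelle") %in% names(partition))) {
    abort("`partition` needs columns `locus_id` and `organelle`.")
  }
  bad_org <- setdiff(unique(partition$organelle), ORGANELLES)
  if (length(bad_org)) {
    abort(paste0("Unknown organelle tag(s): ", paste(bad_org, collapse = ", ")))
  }
  if (is.null(names(loci))) names(loci) <- partition$locus_id
  if (!setequal(names(loci), partition$locus_id) ||
      length(loci) != nrow(partition)) {
    abort("Locus names must match `partition$locus_id` one-to-one.")
  }
  loci <- loci[partition$locus_id]

  for (i in seq_along(loci)) {
    if (!is.matrix(loci[[i]]) || !is.character(loci[[i]])) {
      abort(paste0("Locus ", partition$locus_id[[i]],
                   ": sequences must form a character matrix ",
                   "(ragged alignment?)."))
    }
  }
  acc_ref <- rownames(loci[[1]])
  if (is.null(acc_ref) || anyDuplicated(acc_ref)) {
    abort("Each locus matrix needs unique accession rownames.")
  }
  for (i in seq_along(loci)) {
    m <- loci[[i]]
    id <- partition$locus_id[[i]]
    if (!setequal(rownames(m), acc_ref)) {
      diff <- union(setdiff(rownames(m), acc_ref), setdiff(acc_ref, rownames(m)))
      abort(paste0("Accession sets differ across loci; symmetric difference: ",
                   paste(diff, collapse = ", ")))
    }
    bad <- setdiff(unique(as.vector(m)), VALID_CHARS)
    if (length(bad)) {
      abort(paste0("Locus ", id, ": invalid characters: ",
                   paste(bad, collapse = ", ")))
    }
    loci[[i]] <- m[acc_ref, , drop = FALSE]
  }

  lens <- vapply(loci, ncol, integer(1))
  starts <- cumsum(c(1L, lens[-length(lens)]))
  loci_tbl <- tibble(
    locus_id = partition$locus_id,
    organelle = partition$organelle,
    start = as.integer(starts),
    end = as.integer(starts + lens - 1L),
    length = as.integer(lens)
  )
  seq <- do.call(cbind, loci)
  dimnames(seq) <- list(acc_ref, NULL)

  clean <- matrix(seq %in% CLEAN_CHARS, nrow = nrow(seq))
  mask <- which(matrixStats_colAll(clean))

  structure(
    list(seq = seq, loci = loci_tbl, mask = as.integer(mask),
         total_length = ncol(seq)),
    class = "organelle_alignment"
  )
}

# all() by column without matrixStats
matrixStats_colAll <- function(m) colSums(m) == nrow(m)

#' @export
print.organelle_alignment <- function(x, ...) {
  cat("<organelle_alignment> ", nrow(x$seq), " accessions, ",
      nrow(x$loci), " loci, ", x$total_length, " columns (",
      length(x$mask), " analyzed)\n", sep = "")
  print(x$loci)
  invisible(x)
}

#' Accessions of an alignment
#' @param aln An `organelle_alignment`.
#' @return Character vector of accession ids.
#' @export
accessions <- function(aln) rownames(aln$seq)

#' Read per-locus aligned FASTA files into a partitioned alignment
#'
#' @param paths Character vector of FASTA file paths, one per locus, in
#'   partition order (or named by `locus_id`).
#' @param partition Data frame with `locus_id` and `organelle`, or the path
#'   of a tab-separated file with those columns.
#'
#' @return An [organelle_alignment()].
#' @export
read_alignment_set <- function(paths, partition) {
  if (is.character(partition) && length(partition) == 1) {
    partition <- readr::read_tsv(partition, col_types = readr::cols(.default = "c"))
  }
  partition <- as_tibble(partition)
  if (is.null(names(paths))) names(paths) <- partition$locus_id
  loci <- lapply(names(paths), function(id) {
    d <- ape::read.dna(paths[[id]], format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
    if (is.null(d) || !is.matrix(d)) {
      abort(paste0("Locus ", id, ": could not parse an aligned FASTA ",
                   "(ragged alignment?)."))
    }
    toupper(d)
  })
  names(loci) <- names(paths)
  organelle_alignment(loci, partition)
}

#' Write a partitioned alignment as per-locus FASTA plus a partition map
#'
#' Inverse of [read_alignment_set()]: round-tripping reproduces identical
#' sequences, offsets and analysis mask.
#'
#' @param aln An `organelle_alignment`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list with the written file paths.
#' @export
write_alignment_set <- function(aln, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- character(nrow(aln$loci))
  for (i in seq_len(nrow(aln$loci))) {
    li <- aln$loci[i, ]
    m <- aln$seq[, li$start:li$end, drop = FALSE]
    path <- file.path(dir, paste0(li$locus_id, ".fasta"))
    writeLines(
      as.vector(rbind(paste0(">", rownames(m)), apply(m, 1, paste, collapse = ""))),
      path
    )
    fasta[i] <- path
  }
  part_path <- file.path(dir, "partition.tsv")
  readr::write_tsv(aln$loci[, c("locus_id", "organelle")], part_path)
  invisible(list(fasta = fasta, partition = part_path))
}

#' Restrict a partitioned alignment to one organelle
#'
#' Returns the view of the alignment containing only the loci of the given
#' organelle, with the analysis mask restricted accordingly. Column
#' coordinates are re-expressed in the view's own concatenation, so the view
#' is itself a valid `organelle_alignment`. The chloroplast and
#' mitochondrial masks partition the combined mask column-by-column, which
#' is why segregating sites are additive across organelles.
#'
#' @param aln An `organelle_alignment`.
#' @param organelle `"chloroplast"`, `"mitochondrial"` or `"combined"`
#'   (identity view).
#' @return An `organelle_alignment`.
#' @export
partition_view <- function(aln, organelle = c("combined", "chloroplast", "mitochondrial")) {
  organelle <- match.arg(organelle)
  if (organelle == "combined") return(aln)
  keep <- aln$loci$organelle == organelle
  if (!any(keep)) abort(paste0("No loci with organelle ", organelle, "."))
  loci <- lapply(which(keep), function(i) {
    li <- aln$loci[i, ]
    aln$seq[, li$start:li$end, drop = FALSE]
  })
  names(loci) <- aln$loci$locus_id[keep]
  out <- organelle_alignment(loci, aln$loci[keep, c("locus_id", "organelle")])
  # the global mask restricted to these loci, re-addressed in view coordinates
  old_cols <- unlist(lapply(which(keep), function(i) {
    seq.int(aln$loci$start[i], aln$loci$end[i])
  }))
  out$mask <- as.integer(which(old_cols %in% aln$mask))
  out
}

#' Subset an alignment to a set of accessions
#'
#' The global analysis mask is kept by default so that statistics computed
#' on different accession scopes stay comparable; set `remask = TRUE` to
#' recompute complete-deletion masking within the subset.
#'
#' @param aln An `organelle_alignment`.
#' @param keep Character vector of accessions to retain.
#' @param remask Recompute the analysis mask within the subset?
#' @return An `organelle_alignment`.
#' @export
subset_accessions <- function(aln, keep, remask = FALSE) {
  missing <- setdiff(keep, accessions(aln))
  if (length(missing)) {
    abort(paste0("Accessions not in alignment: ", paste(missing, collapse = ", ")))
  }
  out <- aln
  out$seq <- aln$seq[keep, , drop = FALSE]
  if (remask) {
    clean <- matrix(out$seq %in% CLEAN_CHARS, nrow = nrow(out$seq))
    out$mask <- as.integer(which(matrixStats_colAll(clean)))
  }
  out
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with columns `accession`, `species`
#' (`sativa`, `rufipogon` or `barthii`), `subspecies` (`indica`, `japonica`
#' or `none`), `group` (`tropical`, `subtropical` or `none`), `province`,
#' `latitude`, `longitude` (decimal degrees; may be blank for cultivated
#' accessions).
#'
#' @param path File path.
#' @return A tibble, validated by [validate_samples()].
#' @export
read_samples <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(
    accession = "c", species = "c", subspecies = "c", group = "c",
    province = "c", latitude = "d", longitude = "d"
  ))
  validate_samples(s)
}

#' Validate a sample metadata table
#'
#' Checks factor levels, uniqueness of accessions, the single-outgroup
#' design, and that `subspecies` is only set for cultivated accessions.
#' Optionally checks coverage of an alignment's accessions.
#'
#' @param samples Data frame of sample metadata.
#' @param aln Optional `organelle_alignment` whose accessions must all be
#'   present.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_samples <- function(samples, aln = NULL) {
  samples <- as_tibble(samples)
  need <- c("accession", "species", "subspecies", "group", "province",
            "latitude", "longitude")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(samples$accession)) abort("Duplicated accession ids.")
  if (!all(samples$species %in% c("sativa", "rufipogon", "barthii"))) {
    abort("species must be sativa, rufipogon or barthii.")
  }
  if (!all(samples$subspecies %in% c("indica", "japonica", "none"))) {
    abort("subspecies must be indica, japonica or none.")
  }
  if (!all(samples$group %in% c("tropical", "subtropical", "none"))) {
    abort("group must be tropical, subtropical or none.")
  }
  if (any(samples$subspecies != "none" & samples$species != "sativa")) {
    abort("subspecies can only be set for O. sativa accessions.")
  }
  if (sum(samples$species == "barthii") != 1) {
    abort("Exactly one outgroup (barthii) accession is expected.")
  }
  if (!is.null(aln)) {
    miss <- setdiff(accessions(aln), samples$accession)
    if (length(miss)) {
      abort(paste0("Alignment accessions missing from metadata: ",
                   paste(miss, collapse = ", ")))
    }
  }
  samples
}

# masked view of the sequence matrix for a set of accessions
masked_seq <- function(aln, acc = NULL) {
  acc <- acc %||% accessions(aln)
  aln$seq[acc, aln$mask, drop = FALSE]
}
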