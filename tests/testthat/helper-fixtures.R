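# fixture builders shared across the suite

# one-locus alignment from named sequence strings
aln_from_strings <- function(seqs, organelle = "chloroplast",
                             locus_id = "loc1") {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  organelle_alignment(setNames(list(m), locus_id),
                      tibble::tibble(locus_id = locus_id, organelle = organelle))
}

# multi-locus alignment: `loci` is a named list of named sequence-string
# vectors; organelles recycled in order
aln_multi <- function(loci, organelles) {
  mats <- lapply(loci, function(seqs) {
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
    m
  })
  organelle_alignment(
    mats, tibble::tibble(locus_id = names(loci), organelle = organelles))
}

# minimal metadata covering the given accessions
samples_for <- function(acc, species = NULL, subspecies = NULL,
                        group = NULL, province = NULL, latitude = NULL) {
  n <- length(acc)
  tibble::tibble(
    accession = acc,
    species = species %||% rep("rufipogon", n),
    subspecies = subspecies %||% rep("none", n),
    group = group %||% rep("none", n),
    province = province %||% rep("Guangdong", n),
    latitude = latitude %||% rep(NA_real_, n),
    longitude = rep(NA_real_, n)
  )
}

# random clean alignment (no gaps) for oracle-equivalence loops
random_aln <- function(n_seq, n_col, seed, p_mut = 0.15) {
  withr::with_seed(seed, {
    root <- sample(c("A", "C", "G", "T"), n_col, replace = TRUE)
    m <- matrix(rep(root, each = n_seq), n_seq, n_col)
    hits <- which(matrix(runif(n_seq * n_col) < p_mut, n_seq, n_col))
    for (h in hits) {
      m[h] <- sample(setdiff(c("A", "C", "G", "T"), m[h]), 1)
    }
    rownames(m) <- sprintf("S%02d", seq_len(n_seq))
    organelle_alignment(list(loc1 = m),
                        tibble::tibble(locus_id = "loc1",
                                       organelle = "chloroplast"))
  })
}

# marker table where each population is fixed for its own allele
fixed_pop_markers <- function(n_pops, per_pop, n_markers) {
  X <- do.call(rbind, lapply(seq_len(n_pops), function(p) {
    matrix(as.integer(p), per_pop, n_markers)
  }))
  rownames(X) <- sprintf("i%03d", seq_len(nrow(X)))
  attr(X, "n_alleles") <- rep(n_pops, n_markers)
  class(X) <- c("marker_table", "matrix")
  X
}

# study-scale fixture, computed once per test run
paper_sim_cache <- new.env(parent = emptyenv())
paper_sim <- function() {
  if (is.null(paper_sim_cache$sim)) {
    paper_sim_cache$sim <- simulate_organelle(paper_scenario())
  }
  paper_sim_cache$sim
}

`%||%` <- function(x, y) if (is.null(x)) y else x
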