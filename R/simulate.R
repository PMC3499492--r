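# Seeded generator of organelle alignments + metadata with the structure
# the analysis assumes: two diverged wild clades (indica-like and
# japonica-like) separated by forced diagnostic substitutions, wild
# haplotypes produced by dropping infinite-sites mutations on per-clade
# coalescent genealogies, cultivars created by a haplotype bottleneck from
# designated wild founder haplotypes, an outgroup on its own stem, and
# clade-correlated provinces/latitudes around the Tropic of Cancer.

# illustrative bounding boxes of the seven wild-rice provinces (decimal
# degrees); used to draw collection coordinates, not sourced survey data
PROVINCE_BOXES <- tibble::tribble(
  ~province,    ~lat_min, ~lat_max, ~lon_min, ~lon_max,
  "Fujian",         23.6,     27.5,    116.0,    119.5,
  "Hunan",          24.7,     29.5,    109.5,    113.5,
  "Jiangxi",        24.5,     29.5,    114.0,    117.5,
  "Yunnan",         21.2,     27.5,     98.0,    105.5,
  "Guangdong",      20.3,     25.3,    110.0,    116.5,
  "Guangxi",        20.9,     25.8,    105.0,    112.0,
  "Hainan",         18.2,     20.1,    108.6,    111.0
)

CULTIVAR_PROVINCES <- c(
  "Guangdong", "Guangxi", "Hainan", "Yunnan", "Hunan", "Jiangxi", "Fujian",
  "Guizhou", "Sichuan", "Chongqing", "Hubei", "Anhui", "Jiangsu", "Zhejiang",
  "Shanghai", "Henan", "Shaanxi", "Shanxi", "Shandong", "Hebei", "Beijing",
  "Tianjin", "Liaoning", "Jilin", "Heilongjiang"
)

#' Default per-haplotype wild sampling design
#'
#' One row per (wild haplotype, province) cell: the japonica-like clade
#' (J1-J6) is mostly subtropical with J1 also reaching tropical sites near
#' the Tropic of Cancer; the indica-like clade (I1-I9) is tropical. J6 is
#' the single haplotype confined outside Southern China (Guangdong,
#' Guangxi, Hainan). Totals: 73 tropical + 46 subtropical accessions over
#' 15 haplotypes.
#'
#' @return A tibble: `haplotype`, `clade`, `group`, `province`, `n`.
#' @export
default_wild_design <- function() {
  tibble::tribble(
    ~haplotype, ~clade,          ~group,        ~province,   ~n,
    "J1", "japonica_like", "subtropical", "Guangdong",  6L,
    "J1", "japonica_like", "subtropical", "Guangxi",    5L,
    "J1", "japonica_like", "subtropical", "Fujian",     4L,
    "J1", "japonica_like", "subtropical", "Hunan",      3L,
    "J1", "japonica_like", "tropical",    "Guangdong",  3L,
    "J1", "japonica_like", "tropical",    "Guangxi",    2L,
    "J2", "japonica_like", "subtropical", "Guangdong",  5L,
    "J2", "japonica_like", "subtropical", "Guangxi",    5L,
    "J3", "japonica_like", "subtropical", "Fujian",     4L,
    "J3", "japonica_like", "subtropical", "Guangdong",  3L,
    "J4", "japonica_like", "subtropical", "Hunan",      3L,
    "J4", "japonica_like", "subtropical", "Guangdong",  2L,
    "J5", "japonica_like", "subtropical", "Guangxi",    3L,
    "J6", "japonica_like", "subtropical", "Yunnan",     2L,
    "J6", "japonica_like", "subtropical", "Jiangxi",    1L,
    "I1", "indica_like",   "tropical",    "Guangxi",    8L,
    "I1", "indica_like",   "tropical",    "Hainan",     6L,
    "I2", "indica_like",   "tropical",    "Guangdong",  7L,
    "I2", "indica_like",   "tropical",    "Hainan",     5L,
    "I3", "indica_like",   "tropical",    "Hainan",     9L,
    "I4", "indica_like",   "tropical",    "Guangdong",  8L,
    "I5", "indica_like",   "tropical",    "Guangxi",    8L,
    "I6", "indica_like",   "tropical",    "Yunnan",     3L,
    "I6", "indica_like",   "tropical",    "Guangxi",    3L,
    "I7", "indica_like",   "tropical",    "Hainan",     5L,
    "I8", "indica_like",   "tropical",    "Guangdong",  4L,
    "I9", "indica_like",   "tropical",    "Guangxi",    2L
  )
}

#' Default locus partition (six chloroplast + four mitochondrial loci)
#'
#' Lengths sum to 9161 bp (5420 chloroplast + 3741 mitochondrial), inside
#' the study's printed 9089-9233 total range; individual lengths are
#' plausible reconstructions, configurable per scenario.
#'
#' @return A tibble: `locus_id`, `organelle`, `length`.
#' @export
default_loci <- function() {
  tibble::tribble(
    ~locus_id,     ~organelle,      ~length,
    "trnG_trnfM",  "chloroplast",   1042L,
    "atp1",        "chloroplast",    934L,
    "trnT_trnL",   "chloroplast",    811L,
    "trnC_ycf6",   "chloroplast",    896L,
    "nhdC_trnV",   "chloroplast",    922L,
    "rps16",       "chloroplast",    815L,
    "cox3",        "mitochondrial",  806L,
    "cox1",        "mitochondrial", 1212L,
    "rps2_trnfM",  "mitochondrial",  903L,
    "nhd4",        "mitochondrial",  820L
  )
}

#' Simulation scenario
#'
#' Defaults reproduce the study's design: 27 indica + 23 japonica
#' cultivars from three founder haplotypes (a ~20% retention bottleneck
#' over 15 wild haplotypes), 73 tropical + 46 subtropical wild accessions,
#' one outgroup, ten loci totalling 9161 bp, 10 chloroplast + 3
#' mitochondrial diagnostic substitutions between the clades, and one
#' chloroplast substitution separating the two indica founder haplotypes
#' (so the two indica haplotypes are mitochondrially identical and the
#' cultivated mitochondrial partition splits 27/23).
#'
#' @param loci Locus table as in [default_loci()].
#' @param wild_design Wild sampling design as in [default_wild_design()].
#' @param cultivar_design Named list mapping founder wild haplotypes to
#'   cultivated counts, per subspecies.
#' @param theta_cp,theta_mt Population-scaled mutation rates per site for
#'   each organelle (3:1 chloroplast:mitochondrial by default), driving the
#'   Poisson mutation process on within-clade coalescent branches.
#' @param clade_divergence Stem length separating the two wild clades
#'   (bookkeeping only: stem substitutions are specified exactly by the
#'   diagnostic counts so the study's printed counts are reproduced).
#' @param n_diagnostic_cp,n_diagnostic_mt Fixed inter-clade differences
#'   forced onto the stems, per organelle.
#' @param h3_offset_cp Chloroplast substitutions separating the second
#'   indica founder from the first.
#' @param outgroup_extra Substitutions on the outgroup stem.
#' @param distinct_haplotypes Force at least one private mutation on every
#'   derived wild haplotype's pendant branch, so the realized wild
#'   haplotype count equals the design (zero-truncated Poisson pendants).
#' @param seed Mandatory integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(loci = default_loci(),
                         wild_design = default_wild_design(),
                         cultivar_design = list(
                           japonica = c(J1 = 23L),
                           indica = c(I1 = 25L, I2 = 2L)
                         ),
                         theta_cp = 1.5e-4, theta_mt = 5e-5,
                         clade_divergence = 1,
                         n_diagnostic_cp = 10L, n_diagnostic_mt = 3L,
                         h3_offset_cp = 1L,
                         outgroup_extra = 25L,
                         distinct_haplotypes = TRUE,
                         seed = 2012L) {
  if (is.null(seed)) abort("A seed is mandatory for reproducibility.")
  stopifnot(all(loci$length >= 1), n_diagnostic_cp >= 0, n_diagnostic_mt >= 0,
            outgroup_extra >= 0, theta_cp >= 0, theta_mt >= 0)
  structure(list(
    loci = as_tibble(loci), wild_design = as_tibble(wild_design),
    cultivar_design = cultivar_design,
    theta_cp = theta_cp, theta_mt = theta_mt,
    clade_divergence = clade_divergence,
    n_diagnostic_cp = as.integer(n_diagnostic_cp),
    n_diagnostic_mt = as.integer(n_diagnostic_mt),
    h3_offset_cp = as.integer(h3_offset_cp),
    outgroup_extra = as.integer(outgroup_extra),
    distinct_haplotypes = isTRUE(distinct_haplotypes),
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

#' The canonical study-scale fixture scenario
#' @param seed Integer seed (default 2012).
#' @return A [sim_scenario()] with all defaults.
#' @export
paper_scenario <- function(seed = 2012L) sim_scenario(seed = seed)

BASES <- c("A", "C", "G", "T")

#' Simulate an organelle phylogeography dataset
#'
#' Executes the generative model described in [sim_scenario()] and returns
#' the dataset in the exact containers the analysis consumes, together
#' with a machine-readable truth record.
#'
#' @param scenario A [sim_scenario()].
#' @return A `sim_result`: list with `alignment`
#'   ([organelle_alignment()]), `samples` (validated metadata tibble),
#'   `truth` (list: `accessions` tibble with generator labels and
#'   progenitor flags, `columns` tibble with every mutation's placement,
#'   `haplotype_members` expected member counts, `founders`), and
#'   `scenario`.
#' @export
simulate_organelle <- function(scenario = paper_scenario()) {
  sc <- scenario
  loci <- sc$loci
  total_len <- sum(loci$length)
  ends <- cumsum(loci$length)
  starts <- ends - loci$length + 1L
  col_org <- rep(loci$organelle, loci$length)
  col_locus <- rep(loci$locus_id, loci$length)
  founders <- unlist(lapply(sc$cultivar_design, names))

  withr::with_seed(sc$seed, {
    root <- sample(BASES, total_len, replace = TRUE)
    avail <- list(chloroplast = which(col_org == "chloroplast"),
                  mitochondrial = which(col_org == "mitochondrial"))
    take_cols <- function(org, k) {
      if (k > length(avail[[org]])) abort("Mutation columns exhausted.")
      cols <- sort(sample(avail[[org]], k))
      avail[[org]] <<- setdiff(avail[[org]], cols)
      cols
    }
    mut_log <- list()
    new_mutations <- function(org, k, origin) {
      cols <- take_cols(org, k)
      to <- vapply(cols, function(cc) sample(setdiff(BASES, root[cc]), 1),
                   character(1))
      mut_log[[length(mut_log) + 1]] <<- tibble(
        column = cols, locus = col_locus[cols], organelle = org,
        origin = origin, derived = to)
      list(cols = cols, to = to)
    }

    # inter-clade diagnostics: alternate which clade's stem carries the
    # derived state, so the outgroup root sits between the clades
    clade_muts <- list(japonica_like = list(cols = integer(0), to = character(0)),
                       indica_like = list(cols = integer(0), to = character(0)))
    add_diag <- function(org, k) {
      if (k == 0) return()
      m <- new_mutations(org, k, paste0("diagnostic_", substr(org, 1, 2)))
      side <- rep(c("japonica_like", "indica_like"), length.out = k)
      for (s in unique(side)) {
        pick <- side == s
        clade_muts[[s]]$cols <<- c(clade_muts[[s]]$cols, m$cols[pick])
        clade_muts[[s]]$to <<- c(clade_muts[[s]]$to, m$to[pick])
      }
    }
    add_diag("chloroplast", sc$n_diagnostic_cp)
    add_diag("mitochondrial", sc$n_diagnostic_mt)

    # clade founder (ancestral) haplotypes
    apply_muts <- function(seq, m) { seq[m$cols] <- m$to; seq }
    anc <- list(
      japonica_like = apply_muts(root, clade_muts$japonica_like),
      indica_like = apply_muts(root, clade_muts$indica_like)
    )

    hap_design <- sc$wild_design |>
      group_by(.data$haplotype, .data$clade) |>
      summarise(n = sum(.data$n), .groups = "drop")
    hap_seqs <- list()
    L_cp <- sum(loci$length[loci$organelle == "chloroplast"])
    L_mt <- sum(loci$length[loci$organelle == "mitochondrial"])
    rate_total <- sc$theta_cp * L_cp + sc$theta_mt * L_mt
    w_cp <- if (rate_total > 0) sc$theta_cp * L_cp / rate_total else
      L_cp / (L_cp + L_mt)  # mutation-free scenarios: length-proportional
    rate_seq <- (sc$theta_cp * L_cp + sc$theta_mt * L_mt) / 2

    for (cl in c("japonica_like", "indica_like")) {
      labs <- hap_design$haplotype[hap_design$clade == cl]
      founder_labs <- intersect(unique(founders), labs)
      derived <- setdiff(labs, founder_labs)
      # founders sit at the clade ancestor; the secondary indica founder is
      # offset by chloroplast-only substitutions
      for (f in founder_labs) hap_seqs[[f]] <- anc[[cl]]
      if (cl == "indica_like" && length(founder_labs) > 1 && sc$h3_offset_cp > 0) {
        m <- new_mutations("chloroplast", sc$h3_offset_cp, "h3_offset")
        hap_seqs[[founder_labs[2]]] <- apply_muts(anc[[cl]], m)
      }
      if (!length(derived)) next
      if (length(derived) == 1) {
        k <- max(rpois(1, rate_seq), if (sc$distinct_haplotypes) 1L else 0L)
        orgs <- sample(c("chloroplast", "mitochondrial"), k, replace = TRUE,
                       prob = c(w_cp, 1 - w_cp))
        s <- anc[[cl]]
        for (org in unique(orgs)) {
          s <- apply_muts(s, new_mutations(org, sum(orgs == org),
                                           paste0("random_", cl)))
        }
        hap_seqs[[derived]] <- s
        next
      }
      tr <- ape::reorder.phylo(ape::rcoal(length(derived), tip.label = derived),
                               "cladewise")
      node_seq <- vector("list", max(tr$edge))
      node_seq[[length(derived) + 1L]] <- anc[[cl]]
      is_pendant <- tr$edge[, 2] <= length(derived)
      for (e in seq_len(nrow(tr$edge))) {  # cladewise: parents precede children
        parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
        k <- rpois(1, tr$edge.length[e] * rate_seq)
        if (sc$distinct_haplotypes && is_pendant[e]) k <- max(k, 1L)
        s <- node_seq[[parent]]
        if (k > 0) {
          orgs <- sample(c("chloroplast", "mitochondrial"), k, replace = TRUE,
                         prob = c(w_cp, 1 - w_cp))
          for (org in unique(orgs)) {
            m <- new_mutations(org, sum(orgs == org), paste0("random_", cl))
            s <- apply_muts(s, m)
          }
        }
        node_seq[[child]] <- s
      }
      for (i in seq_along(derived)) {
        hap_seqs[[tr$tip.label[i]]] <- node_seq[[i]]
      }
    }

    # outgroup on its own stem from the root
    og_cp <- stats::rbinom(1, sc$outgroup_extra, w_cp)
    og_seq <- root
    if (og_cp > 0) og_seq <- apply_muts(og_seq, new_mutations("chloroplast", og_cp, "outgroup"))
    if (sc$outgroup_extra - og_cp > 0) {
      og_seq <- apply_muts(og_seq, new_mutations("mitochondrial",
                                                 sc$outgroup_extra - og_cp,
                                                 "outgroup"))
    }

    n_wild_real <- length(unique(vapply(hap_seqs, paste, character(1), collapse = "")))
    founder_labels <- unique(founders)
    n_founder_real <- length(unique(vapply(hap_seqs[founder_labels], paste,
                                           character(1), collapse = "")))
    if (n_founder_real < length(founder_labels)) {
      abort(paste0(
        "Impossible scenario: ", length(founder_labels),
        " founder haplotypes requested but only ", n_founder_real,
        " distinct wild haplotypes realized among them."))
    }

    # accessions: wild (design order), cultivars, outgroup
    wild_rows <- sc$wild_design[rep(seq_len(nrow(sc$wild_design)),
                                    sc$wild_design$n), ]
    wild_rows$accession <- sprintf("W%03d", seq_len(nrow(wild_rows)))
    wild_rows$latitude <- draw_latitudes(wild_rows)
    wild_rows$longitude <- draw_longitudes(wild_rows)

    cult <- purrr::map_dfr(names(sc$cultivar_design), function(ssp) {
      des <- sc$cultivar_design[[ssp]]
      purrr::map_dfr(names(des), function(hap) {
        tibble(haplotype = hap, subspecies = ssp, n = des[[hap]])
      })
    })
    cult_rows <- cult[rep(seq_len(nrow(cult)), cult$n), c("haplotype", "subspecies")]
    cult_rows$accession <- sprintf(
      "%s%02d", toupper(substr(cult_rows$subspecies, 1, 3)),
      stats::ave(seq_len(nrow(cult_rows)), cult_rows$subspecies, FUN = seq_along))
    cult_rows$province <- rep(CULTIVAR_PROVINCES,
                              length.out = nrow(cult_rows))

    acc <- c(wild_rows$accession, cult_rows$accession, "BAR01")
    seqs <- matrix("", length(acc), total_len, dimnames = list(acc, NULL))
    for (i in seq_len(nrow(wild_rows))) {
      seqs[wild_rows$accession[i], ] <- hap_seqs[[wild_rows$haplotype[i]]]
    }
    for (i in seq_len(nrow(cult_rows))) {
      seqs[cult_rows$accession[i], ] <- hap_seqs[[cult_rows$haplotype[i]]]
    }
    seqs["BAR01", ] <- og_seq

    loci_mats <- lapply(seq_len(nrow(loci)), function(i) {
      seqs[, starts[i]:ends[i], drop = FALSE]
    })
    names(loci_mats) <- loci$locus_id
    aln <- organelle_alignment(loci_mats, loci[, c("locus_id", "organelle")])

    samples <- bind_rows(
      tibble(accession = wild_rows$accession, species = "rufipogon",
             subspecies = "none", group = wild_rows$group,
             province = wild_rows$province, latitude = wild_rows$latitude,
             longitude = wild_rows$longitude),
      tibble(accession = cult_rows$accession, species = "sativa",
             subspecies = cult_rows$subspecies, group = "none",
             province = cult_rows$province,
             latitude = NA_real_, longitude = NA_real_),
      tibble(accession = "BAR01", species = "barthii", subspecies = "none",
             group = "none", province = "outgroup",
             latitude = NA_real_, longitude = NA_real_)
    )
    samples <- validate_samples(samples, aln)

    truth_acc <- bind_rows(
      tibble(accession = wild_rows$accession, role = "wild",
             clade = wild_rows$clade, haplotype = wild_rows$haplotype,
             progenitor = wild_rows$haplotype %in% founders),
      tibble(accession = cult_rows$accession, role = cult_rows$subspecies,
             clade = ifelse(cult_rows$subspecies == "japonica",
                            "japonica_like", "indica_like"),
             haplotype = cult_rows$haplotype, progenitor = FALSE),
      tibble(accession = "BAR01", role = "outgroup", clade = "outgroup",
             haplotype = "OG", progenitor = FALSE)
    )
    truth <- list(
      accessions = truth_acc,
      columns = bind_rows(mut_log) |> arrange(.data$column),
      haplotype_members = wild_rows |> count(.data$haplotype, name = "n_wild"),
      founders = founders,
      n_wild_haplotypes = n_wild_real
    )
    structure(list(alignment = aln, samples = samples, truth = truth,
                   scenario = sc),
              class = "sim_result")
  })
}

# latitude draws honoring province boxes, latitude groups, and the forced
# endpoint latitudes of the founder haplotypes (the progenitor latitude
# ranges 22.25-26.8 N for the japonica founder and 18.25-23.3 N for the
# indica founders)
draw_latitudes <- function(rows) {
  boxes <- PROVINCE_BOXES
  lat <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    b <- boxes[boxes$province == rows$province[i], ]
    lo <- b$lat_min; hi <- b$lat_max
    if (rows$group[i] == "tropical") hi <- min(hi, 23.3) else lo <- max(lo, 23.6)
    if (rows$haplotype[i] == "J1") {
      if (rows$group[i] == "subtropical") hi <- min(hi, 26.8) else lo <- max(lo, 22.25)
    }
    if (rows$haplotype[i] %in% c("I1", "I2")) lo <- max(lo, 18.25)
    lat[i] <- runif(1, lo, hi)
  }
  # pin the documented range endpoints on founder members
  pin <- function(hap, group, value) {
    idx <- which(rows$haplotype == hap & rows$group == group)
    if (length(idx)) lat[idx[1]] <<- value
  }
  pin("J1", "subtropical", 26.8)
  pin("J1", "tropical", 22.25)
  pin("I1", "tropical", 18.25)
  pin("I2", "tropical", 23.3)
  round(lat, 4)
}

draw_longitudes <- function(rows) {
  boxes <- PROVINCE_BOXES
  lon <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    b <- boxes[boxes$province == rows$province[i], ]
    lon[i] <- runif(1, b$lon_min, b$lon_max)
  }
  round(lon, 4)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", nrow(x$samples), " accessions (",
      sum(x$samples$species == "rufipogon"), " wild, ",
      sum(x$samples$species == "sativa"), " cultivated), ",
      x$alignment$total_length, " bp, seed ", x$scenario$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as analysis-ready files
#'
#' Emits the per-locus FASTA set plus partition map (via
#' [write_alignment_set()]), the metadata TSV, the truth tables, and the
#' scenario as YAML. Outputs are byte-identical for identical scenarios.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment_set(sim$alignment, dir)
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$truth$accessions, file.path(dir, "truth_accessions.tsv"))
  readr::write_tsv(sim$truth$columns, file.path(dir, "truth_columns.tsv"))
  sc <- sim$scenario
  yaml::write_yaml(list(
    seed = sc$seed, theta_cp = sc$theta_cp, theta_mt = sc$theta_mt,
    n_diagnostic_cp = sc$n_diagnostic_cp, n_diagnostic_mt = sc$n_diagnostic_mt,
    h3_offset_cp = sc$h3_offset_cp, outgroup_extra = sc$outgroup_extra,
    clade_divergence = sc$clade_divergence,
    distinct_haplotypes = sc$distinct_haplotypes
  ), file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Simulate a single-population coalescent alignment (infinite sites)
#'
#' One panmictic sample: a Kingman coalescent genealogy (`ape::rcoal`,
#' branch lengths in coalescent units) with mutations dropped as a Poisson
#' process of rate `theta_site * L / 2` per branch-length unit, each on a
#' unique column. Under this process the expected segregating-site count
#' is `theta_site * L * sum_{k<n} 1/k`, i.e. Watterson's estimator is
#' unbiased for `theta_site` — the calibration link used in the tests.
#'
#' @param n Number of sequences.
#' @param L Alignment length.
#' @param theta_site Population-scaled mutation rate per site.
#' @param seed Integer seed.
#' @return Character matrix `n x L` with rownames `S1..Sn`.
#' @export
simulate_coalescent <- function(n, L, theta_site, seed) {
  withr::with_seed(seed, {
    root <- sample(BASES, L, replace = TRUE)
    seqs <- matrix(rep(root, each = n), n, L,
                   dimnames = list(sprintf("S%d", seq_len(n)), NULL))
    if (n == 1) return(seqs)
    tr <- ape::reorder.phylo(ape::rcoal(n), "cladewise")
    rate <- theta_site * L / 2
    k_per_edge <- rpois(nrow(tr$edge), tr$edge.length * rate)
    total <- sum(k_per_edge)
    if (total > L) abort("More mutations than columns; lower theta or raise L.")
    cols <- sample(L, total)
    node_muts <- vector("list", max(tr$edge))
    used <- 0L
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      k <- k_per_edge[e]
      mine <- if (k > 0) cols[used + seq_len(k)] else integer(0)
      used <- used + k
      node_muts[[child]] <- c(node_muts[[parent]], mine)
    }
    for (tip in seq_len(n)) {
      for (cc in node_muts[[tip]]) {
        seqs[tip, cc] <- setdiff(BASES, root[cc])[1]
      }
    }
    seqs
  })
}
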