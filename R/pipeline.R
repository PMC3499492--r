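# Config-driven end-to-end runner: data model -> diversity -> FST ->
# network -> NJ tree -> clustering -> dating -> geography, with TSV
# outputs and a deterministic manifest.

#' Pipeline configuration
#'
#' Either `input` (a directory produced by [write_fixture()] /
#' [write_alignment_set()], holding per-locus FASTA files, `partition.tsv`
#' and `samples.tsv`) or `scenario` (a [sim_scenario()]) must be given.
#' One base seed fans out to the stochastic stages through fixed offsets
#' (bootstrap: seed + 1; clustering: seed + 2; simulation: the scenario's
#' own seed), so toggling one stage never shifts another stage's random
#' stream.
#'
#' @param input Input directory, or `NULL`.
#' @param scenario A [sim_scenario()], or `NULL`.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run; any of `"stats"`,
#'   `"fst"`, `"network"`, `"tree"`, `"structure"`, `"date"`, `"geo"`.
#' @param epsilon Network relaxation parameter.
#' @param bootstrap_reps NJ bootstrap replicates.
#' @param k_range Cluster numbers to sweep.
#' @param mcmc_steps,burn_in,thinning Gibbs sampler sizes.
#' @param mu Nuclear substitution rate for dating.
#' @param assign_threshold Hard-assignment membership threshold.
#' @param seed Base seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL,
                            out_dir = tempfile("haplorigin_run_"),
                            stages = c("stats", "fst", "network", "tree",
                                       "structure", "date", "geo"),
                            epsilon = 0L, bootstrap_reps = 1000L,
                            k_range = 2:10, mcmc_steps = 100000L,
                            burn_in = 100000L, thinning = 10L,
                            mu = 7.16e-9, assign_threshold = 0.6,
                            seed = 1L) {
  if (is.null(input) && is.null(scenario)) {
    abort("Provide either an input directory or a simulation scenario.")
  }
  if (!is.null(input) && !dir.exists(input)) {
    abort(paste0("Input directory does not exist: ", input))
  }
  bad <- setdiff(stages, c("stats", "fst", "network", "tree", "structure",
                           "date", "geo"))
  if (length(bad)) abort(paste0("Unknown stages: ", paste(bad, collapse = ", ")))
  structure(list(input = input, scenario = scenario, out_dir = out_dir,
                 stages = stages, epsilon = epsilon,
                 bootstrap_reps = bootstrap_reps, k_range = k_range,
                 mcmc_steps = mcmc_steps, burn_in = burn_in,
                 thinning = thinning, mu = mu,
                 assign_threshold = assign_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writes every result table under
#' `out_dir`, and returns the results as a bundle. Any stage failure
#' aborts with the stage name; partial outputs are retained alongside a
#' `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_bundle`: list of stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config, stages = list())

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # data stage always runs
  data <- run_stage("data", {
    if (!is.null(config$scenario)) {
      sim <- simulate_organelle(config$scenario)
      list(aln = sim$alignment, samples = sim$samples, sim = sim)
    } else {
      part <- readr::read_tsv(file.path(config$input, "partition.tsv"),
                              col_types = readr::cols(.default = "c"))
      paths <- file.path(config$input, paste0(part$locus_id, ".fasta"))
      names(paths) <- part$locus_id
      aln <- read_alignment_set(paths, part)
      samples <- read_samples(file.path(config$input, "samples.tsv"))
      list(aln = aln, samples = validate_samples(samples, aln))
    }
  })
  aln <- data$aln; samples <- data$samples
  haps_all <- collapse_haplotypes(aln)
  write_haplotypes(haps_all, file.path(out, "haplotypes.tsv"))
  bundle$stages$data <- list(
    n_accessions = nrow(samples), total_length = aln$total_length,
    analyzed_length = length(aln$mask), n_haplotypes = nrow(haps_all))
  bundle$haplotypes <- haps_all

  ancestry <- NULL
  if ("geo" %in% config$stages || "fst" %in% config$stages) {
    ancestry <- run_stage("geo", identify_ancestors(haps_all, samples))
  }

  if ("stats" %in% config$stages) {
    bundle$diversity <- run_stage("stats", diversity_table(aln, samples))
    write_diversity_table(bundle$diversity, file.path(out, "table1.tsv"))
    bundle$stages$stats <- TRUE
  }
  if ("fst" %in% config$stages) {
    groups <- standard_groups(samples, ancestry)
    bundle$fst <- run_stage("fst", fst_matrix(aln, groups))
    readr::write_tsv(bundle$fst, file.path(out, "fst.tsv"))
    bundle$stages$fst <- TRUE
  }
  if ("network" %in% config$stages) {
    bundle$network <- run_stage("network", {
      net <- build_mj_network(haps_all, epsilon = config$epsilon)
      annotate_network(net, haps_all, samples)
    })
    write_network_graphml(bundle$network, file.path(out, "network.graphml"))
    write_network_edges(bundle$network, file.path(out, "network_edges.tsv"))
    bundle$stages$network <- TRUE
  }
  if ("tree" %in% config$stages) {
    bundle$tree <- run_stage("tree", {
      outgroup <- haplotype_of(haps_all)[
        samples$accession[samples$species == "barthii"][1]]
      bootstrap_support(aln, haps_all, replicates = config$bootstrap_reps,
                        seed = config$seed + 1L, outgroup = unname(outgroup))
    })
    write_tree_newick(bundle$tree, file.path(out, "tree.nwk"))
    bundle$stages$tree <- TRUE
  }
  if ("structure" %in% config$stages) {
    bundle$structure <- run_stage("structure", {
      markers <- encode_markers(
        aln, scope = samples$accession[samples$species != "barthii"])
      cfg <- structure_config(mcmc_steps = config$mcmc_steps,
                              burn_in = config$burn_in,
                              thinning = config$thinning,
                              seed = config$seed + 2L)
      run_structure(markers, k_range = config$k_range, config = cfg,
                    threshold = config$assign_threshold)
    })
    write_structure(bundle$structure, file.path(out, "structure_q.tsv"),
                    file.path(out, "lnpd.tsv"))
    bundle$stages$structure <- TRUE
  }
  if ("date" %in% config$stages) {
    bundle$dating <- run_stage("date",
      clock_table(aln, samples, clock_params(mu = config$mu)))
    readr::write_tsv(bundle$dating, file.path(out, "dating.tsv"))
    bundle$stages$date <- TRUE
  }
  if ("geo" %in% config$stages) {
    bundle$ancestry <- ancestry
    readr::write_tsv(ancestry, file.path(out, "ancestors.tsv"))
    bundle$region <- run_stage("geo", region_distribution(haps_all, samples))
    readr::write_tsv(bundle$region$counts, file.path(out, "region_counts.tsv"))
    bundle$lat_ranges <- run_stage("geo", latitude_ranges(ancestry, samples))
    readr::write_tsv(bundle$lat_ranges, file.path(out, "latitude_ranges.tsv"))
    bundle$stages$geo <- TRUE
  }

  manifest <- list(
    package = "haplorigin",
    version = as.character(utils::packageVersion("haplorigin")),
    seed = config$seed,
    stages = config$stages,
    parameter_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  class(bundle) <- "pipeline_bundle"
  invisible(bundle)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle> stages:",
      paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Collates the diversity and differentiation tables, the best cluster
#' number, dating results, progenitor counts and latitude ranges into one
#' plain-text report. Regenerating the report from the same bundle gives
#' identical text.
#'
#' @param bundle A `pipeline_bundle` (possibly partial).
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly if `path` given.
#' @export
pipeline_report <- function(bundle, path = NULL) {
  fmt_tab <- function(df) utils::capture.output(print(as.data.frame(df),
                                                      row.names = FALSE))
  lines <- c("haplorigin pipeline report",
             paste0("seed: ", bundle$config$seed),
             paste0("stages: ", paste(names(bundle$stages), collapse = ", ")),
             "")
  d <- bundle$stages$data
  lines <- c(lines, sprintf(
    "Data: %d accessions, %d bp (%d analyzed), %d haplotypes",
    d$n_accessions, d$total_length, d$analyzed_length, d$n_haplotypes), "")
  if (!is.null(bundle$diversity)) {
    lines <- c(lines, "Diversity summary:", fmt_tab(
      mutate(bundle$diversity, pi = round(.data$pi * 1e3, 2),
             theta_w = round(.data$theta_w * 1e3, 2),
             Hd = round(.data$Hd, 3))), "")
  }
  if (!is.null(bundle$fst)) {
    lines <- c(lines, "Pairwise Phi-ST:", fmt_tab(
      mutate(bundle$fst, phi_st = round(.data$phi_st, 4))[
        , c("group_a", "group_b", "phi_st")]), "")
  }
  if (!is.null(bundle$structure)) {
    lines <- c(lines, paste0("Best K: ", bundle$structure$best_k),
               fmt_tab(mutate(bundle$structure$lnpd,
                              lnpd = round(.data$lnpd, 2))), "")
  }
  if (!is.null(bundle$dating)) {
    lines <- c(lines, "Diagnostic-site dating:", fmt_tab(
      bundle$dating[, c("organelle", "N", "L", "T_years", "T_Myr")]), "")
  }
  if (!is.null(bundle$ancestry)) {
    n_prog <- sum(bundle$ancestry$progenitor_of != "none")
    lines <- c(lines, sprintf("Wild progenitor accessions: %d", n_prog))
  }
  if (!is.null(bundle$lat_ranges)) {
    lines <- c(lines, "Progenitor latitude ranges:", fmt_tab(
      mutate(bundle$lat_ranges, lat_min = round(.data$lat_min, 2),
             lat_max = round(.data$lat_max, 2))), "")
  }
  if (!is.null(bundle$region)) {
    lines <- c(lines, sprintf(
      "Southern-China haplotypes: %d of %d (%d%%); cultivated retention: %d%%",
      bundle$region$regional_h, bundle$region$total_h,
      bundle$region$regional_share_pct, bundle$region$retention_pct))
  }
  missing <- setdiff(c("stats", "fst", "network", "tree", "structure",
                       "date", "geo"),
                     names(bundle$stages))
  if (length(missing)) {
    lines <- c(lines, "", paste0("Stages not run: ",
                                 paste(missing, collapse = ", ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
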