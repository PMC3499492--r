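# Progenitor identification by haplotype sharing, and the geographic
# summaries: Tropic-of-Cancer classification, haplotype-by-province
# distributions, Southern-China haplotype share, and latitude ranges of
# the progenitor classes.

#' Geographic parameters
#'
#' @param toc_latitude Tropic of Cancer, the tropical/subtropical boundary
#'   (default 23.5 degrees N).
#' @param southern_china Provinces jointly called Southern China.
#' @return A `geo_params` list.
#' @export
geo_params <- function(toc_latitude = 23.5,
                       southern_china = c("Guangdong", "Guangxi", "Hainan")) {
  structure(list(toc_latitude = toc_latitude, southern_china = southern_china),
            class = "geo_params")
}

#' Convert degree-minute coordinates to decimal degrees
#'
#' @param degrees Whole degrees.
#' @param minutes Minutes (0 <= minutes < 60).
#' @return `degrees + minutes / 60`.
#' @export
dms_to_decimal <- function(degrees, minutes) {
  if (any(minutes < 0 | minutes >= 60)) abort("minutes must be in [0, 60).")
  degrees + minutes / 60
}

#' Classify latitudes against the Tropic of Cancer
#'
#' Latitudes strictly south of the boundary are `"tropical"`; the boundary
#' itself and anything north of it is `"subtropical"`. Missing latitudes
#' give `"unclassified"`.
#'
#' @param latitude Numeric vector of decimal degrees in `[-90, 90]`.
#' @param params A [geo_params()].
#' @return Character vector.
#' @export
toc_classify <- function(latitude, params = geo_params()) {
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    abort("Latitudes must lie in [-90, 90].")
  }
  out <- ifelse(latitude < params$toc_latitude, "tropical", "subtropical")
  out[is.na(latitude)] <- "unclassified"
  out
}

#' Identify wild progenitors by haplotype sharing with cultivars
#'
#' A wild accession whose combined organelle haplotype is also carried by
#' cultivated accessions is flagged as a progenitor of the subspecies
#' carrying that haplotype. A haplotype carried by both subspecies raises
#' a conflict flag (none are expected when the subspecies are fully
#' separated in the data).
#'
#' @param haps A [collapse_haplotypes()] table over all accessions and the
#'   combined loci.
#' @param samples Validated sample metadata.
#' @return An `ancestry_summary`: tibble over wild accessions with
#'   `accession`, `haplotype_id`, `shared` (logical), `progenitor_of`
#'   (`"indica"`, `"japonica"`, `"conflict"` or `"none"`). The per-haplotype
#'   view (which subspecies, if any, each haplotype is shared with) is in
#'   the `haplotype_sharing` attribute.
#' @export
identify_ancestors <- function(haps, samples) {
  subsp <- setNames(samples$subspecies, samples$accession)
  species <- setNames(samples$species, samples$accession)

  sharing <- purrr::map_dfr(seq_len(nrow(haps)), function(i) {
    members <- haps$members[[i]]
    cult <- unique(subsp[members][species[members] == "sativa"])
    cult <- setdiff(cult, "none")
    tibble(
      haplotype_id = haps$haplotype_id[[i]],
      shared_with = if (!length(cult)) "none"
                    else if (length(cult) > 1) "conflict"
                    else cult,
      n_wild = sum(species[members] == "rufipogon"),
      n_cultivated = sum(species[members] == "sativa")
    )
  })

  hap_of <- haplotype_of(haps)
  wild <- samples$accession[samples$species == "rufipogon"]
  wild <- intersect(wild, names(hap_of))
  out <- tibble(
    accession = wild,
    haplotype_id = unname(hap_of[wild])
  ) |>
    left_join(sharing[, c("haplotype_id", "shared_with")], by = "haplotype_id") |>
    mutate(shared = .data$shared_with != "none",
           progenitor_of = .data$shared_with) |>
    select("accession", "haplotype_id", "shared", "progenitor_of")
  structure(out, haplotype_sharing = sharing,
            class = c("ancestry_summary", class(out)))
}

#' Haplotype-by-province distribution and regional diversity shares
#'
#' Counts wild accessions per (haplotype, province); a haplotype belongs to
#' a region when at least one of its wild members was collected there
#' (presence, not frequency). Also reports the regional share of the total
#' wild haplotype number and the bottleneck retention ratio
#' `h(cultivated) / h(wild)`.
#'
#' @param haps A [collapse_haplotypes()] table over all accessions.
#' @param samples Validated sample metadata.
#' @param params A [geo_params()]; defines the Southern-China province set.
#' @return A list: `counts` (tibble haplotype x province), `regional_h`,
#'   `total_h` (wild haplotype numbers), `regional_share_pct` (integer
#'   percent), `retention_pct` (integer percent), plus the raw ratios.
#' @export
region_distribution <- function(haps, samples, params = geo_params()) {
  species <- setNames(samples$species, samples$accession)
  prov <- setNames(samples$province, samples$accession)
  hap_of <- haplotype_of(haps)

  wild <- samples$accession[samples$species == "rufipogon"]
  wild <- intersect(wild, names(hap_of))
  counts <- tibble(
    accession = wild,
    haplotype_id = unname(hap_of[wild]),
    province = unname(prov[wild])
  ) |>
    count(.data$haplotype_id, .data$province, name = "n")

  wild_haps <- unique(counts$haplotype_id)
  regional_haps <- unique(
    counts$haplotype_id[counts$province %in% params$southern_china])
  cult <- samples$accession[samples$species == "sativa"]
  cult_haps <- unique(hap_of[intersect(cult, names(hap_of))])

  total_h <- length(wild_haps)
  regional_h <- length(regional_haps)
  retention <- length(intersect(cult_haps, wild_haps)) / total_h
  # haplotype-count bottleneck: cultivated vs wild haplotype numbers
  retention_counts <- length(cult_haps) / total_h

  list(
    counts = counts,
    regional_h = regional_h,
    total_h = total_h,
    regional_share = regional_h / total_h,
    regional_share_pct = as.integer(round(100 * regional_h / total_h)),
    retention = retention_counts,
    retention_pct = as.integer(round(100 * retention_counts)),
    shared_retention = retention
  )
}

#' Latitude ranges of the progenitor classes
#'
#' Inclusive (min, max) collection latitudes of the wild progenitors of
#' each cultivated subspecies. The `indica_lower` attribute flags whether
#' the indica-progenitor range sits at lower latitudes than the
#' japonica-progenitor range (both its minimum and its maximum are lower —
#' the ranges may still overlap).
#'
#' @param ancestry An [identify_ancestors()] summary.
#' @param samples Validated sample metadata with latitudes.
#' @return Tibble: `progenitor_of`, `n`, `lat_min`, `lat_max`.
#' @export
latitude_ranges <- function(ancestry, samples) {
  lat <- setNames(samples$latitude, samples$accession)
  d <- ancestry |>
    filter(.data$progenitor_of %in% c("indica", "japonica")) |>
    mutate(latitude = unname(lat[.data$accession])) |>
    filter(!is.na(.data$latitude))
  if (!nrow(d)) {
    warn("No located progenitor accessions.")
    out <- tibble(progenitor_of = character(0), n = integer(0),
                  lat_min = numeric(0), lat_max = numeric(0))
    attr(out, "indica_lower") <- NA
    return(out)
  }
  out <- d |>
    group_by(.data$progenitor_of) |>
    summarise(n = n(), lat_min = min(.data$latitude),
              lat_max = max(.data$latitude), .groups = "drop")
  if (all(c("indica", "japonica") %in% out$progenitor_of)) {
    i <- out[out$progenitor_of == "indica", ]
    j <- out[out$progenitor_of == "japonica", ]
    attr(out, "indica_lower") <-
      i$lat_min < j$lat_min && i$lat_max < j$lat_max
  } else {
    attr(out, "indica_lower") <- NA
  }
  out
}

#' Plot progenitor collection sites around the Tropic of Cancer
#'
#' @param object An `ancestry_summary`.
#' @param samples Validated sample metadata with coordinates.
#' @param params A [geo_params()].
#' @param ... Unused.
#' @return A ggplot object (longitude x latitude scatter, TOC dashed).
#' @export
autoplot.ancestry_summary <- function(object, samples, params = geo_params(),
                                      ...) {
  d <- object |>
    filter(.data$progenitor_of %in% c("indica", "japonica")) |>
    left_join(samples[, c("accession", "latitude", "longitude")],
              by = "accession") |>
    filter(!is.na(.data$latitude))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$longitude, y = .data$latitude,
                                  colour = .data$progenitor_of,
                                  shape = .data$progenitor_of)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = params$toc_latitude, linetype = 2) +
    ggplot2::annotate("text", x = Inf, y = params$toc_latitude,
                      label = "Tropic of Cancer", hjust = 1.05, vjust = -0.5,
                      size = 3) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "longitude (E)", y = "latitude (N)",
                  colour = "progenitor of", shape = "progenitor of")
}
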