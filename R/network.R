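# Median-joining haplotype network (Bandelt-style): epsilon-relaxed
# minimum spanning network over haplotype signatures, augmented with median
# (Steiner) vectors from mutually-linked triplets until a fixed point, then
# pruned of obsolete medians.

#' Build a median-joining haplotype network
#'
#' The algorithm alternates two phases until no new node arises:
#' \enumerate{
#'   \item Build the epsilon-relaxed minimum spanning network: an edge
#'     `(u, v)` is included when its Hamming weight is at most the minimal
#'     weight at which the components of `u` and `v` merge during Kruskal
#'     agglomeration, plus `epsilon`. At `epsilon = 0` this is the union of
#'     all minimum spanning trees.
#'   \item For every triplet of mutually linked nodes, form the column-wise
#'     majority consensus of the three signatures; if any column has three
#'     distinct states the triplet contributes no median (the conservative
#'     multistate treatment). Novel consensus signatures are added as
#'     median vectors (`mv1`, `mv2`, ...).
#' }
#' Finally, median vectors of degree <= 2 whose removal does not increase
#' the minimum spanning cost of the remaining nodes are deleted
#' iteratively, and the network is rebuilt.
#'
#' Every edge is labelled with the mutational steps (Hamming distance)
#' between its endpoint signatures. Tie-breaking in the Kruskal stages is
#' by (weight, lexicographic node pair), so the result is deterministic for
#' a fixed input ordering.
#'
#' @param haps A [collapse_haplotypes()] table (or any `haplotype_tbl`).
#' @param epsilon Non-negative integer relaxation; larger values admit more
#'   alternative links. Default 0. Over a fixed node set the admitted link
#'   set is monotone in `epsilon`.
#' @param medians Add median vectors (default). With `medians = FALSE` the
#'   result is the plain epsilon-relaxed minimum spanning network over the
#'   sampled haplotypes.
#' @param max_iter Safety cap on median-addition and pruning rounds.
#' @return An object of class `haplo_network`: list with `nodes` (tibble:
#'   `id`, `kind` = sampled|median, `signature`, `n_members`), `edges`
#'   (tibble: `from`, `to`, `steps`), and `graph` (igraph).
#' @export
build_mj_network <- function(haps, epsilon = 0L, medians = TRUE,
                             max_iter = 100L) {
  if (!nrow(haps)) abort("Need at least one haplotype.")
  if (epsilon < 0) abort("epsilon must be a non-negative integer.")
  sigs <- setNames(haps$signature, haps$haplotype_id)
  kind <- setNames(rep("sampled", length(sigs)), names(sigs))
  n_mv <- 0L

  for (iter in seq_len(if (medians) max_iter else 0L)) {
    edges <- msn_edges(sigs, epsilon)
    new_sigs <- character(0)
    trips <- linked_triplets(names(sigs), edges)
    for (t in trips) {
      med <- triplet_median(sigs[t])
      if (!is.null(med) && !(med %in% sigs) && !(med %in% new_sigs)) {
        new_sigs <- c(new_sigs, med)
      }
    }
    if (!length(new_sigs)) break
    ids <- paste0("mv", n_mv + seq_along(new_sigs))
    n_mv <- n_mv + length(new_sigs)
    sigs <- c(sigs, setNames(new_sigs, ids))
    kind <- c(kind, setNames(rep("median", length(ids)), ids))
    if (iter == max_iter) abort("Median addition did not converge.")
  }

  # prune obsolete medians: degree <= 2 and removable without raising the
  # spanning cost of the remaining nodes
  for (iter in seq_len(max_iter)) {
    edges <- msn_edges(sigs, epsilon)
    deg <- degree_count(names(sigs), edges)
    cand <- names(sigs)[kind[names(sigs)] == "median" & deg <= 2]
    removed <- FALSE
    base_cost <- mst_cost(hamming_matrix(sigs))
    for (id in cand) {
      rest <- sigs[names(sigs) != id]
      if (length(rest) && mst_cost(hamming_matrix(rest)) <= base_cost) {
        sigs <- rest
        removed <- TRUE
        break
      }
    }
    if (!removed) break
    if (iter == max_iter) abort("Median pruning did not converge.")
  }

  edges <- msn_edges(sigs, epsilon)
  nodes <- tibble(
    id = names(sigs),
    kind = unname(kind[names(sigs)]),
    signature = unname(sigs),
    n_members = unname(ifelse(
      names(sigs) %in% haps$haplotype_id,
      haps$n_members[match(names(sigs), haps$haplotype_id)], 0L))
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "haplo_network")
}

# epsilon-relaxed minimum spanning network: edge (i,j) kept iff
# d(i,j) <= minimax(i,j) + epsilon, where minimax is the Kruskal merge
# weight of the two endpoints' components
msn_edges <- function(sigs, epsilon) {
  ids <- names(sigs)
  n <- length(ids)
  if (n < 2) {
    return(tibble(from = character(0), to = character(0), steps = integer(0)))
  }
  d <- hamming_matrix(sigs)
  mm <- minimax_merge_weights(d)
  keep <- which(upper.tri(d) & d <= mm + epsilon, arr.ind = TRUE)
  edges <- tibble(
    from = ids[keep[, 1]],
    to = ids[keep[, 2]],
    steps = d[keep]
  )
  # deterministic ordering: weight, then lexicographic pair
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges[order(edges$steps, edges$from, edges$to), ]
}

# Kruskal component-merge weights for all pairs (minimax path weights)
minimax_merge_weights <- function(d) {
  n <- nrow(d)
  comp <- seq_len(n)
  mm <- matrix(0, n, n)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)], ut[, 1], ut[, 2])
  for (e in ord) {
    i <- ut[e, 1]; j <- ut[e, 2]; w <- d[i, j]
    if (comp[i] != comp[j]) {
      merging <- comp %in% c(comp[i], comp[j])
      a <- which(comp == comp[i]); b <- which(comp == comp[j])
      mm[a, b] <- w; mm[b, a] <- w
      comp[merging] <- min(comp[i], comp[j])
    }
  }
  mm
}

# minimum spanning tree cost over a distance matrix (Prim)
mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  cost <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    cost <- cost + best[nxt]
    in_tree[nxt] <- TRUE
    best <- pmin(best, d[nxt, ])
  }
  unname(cost)
}

# all triplets of mutually linked nodes in the current edge set
linked_triplets <- function(ids, edges) {
  if (!nrow(edges)) return(list())
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  adj[cbind(edges$from, edges$to)] <- TRUE
  adj[cbind(edges$to, edges$from)] <- TRUE
  out <- list()
  n <- length(ids)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || !adj[i, j]) next
      for (k in seq_len(n)) {
        if (k <= j || !adj[i, k] || !adj[j, k]) next
        out[[length(out) + 1]] <- ids[c(i, j, k)]
      }
    }
  }
  out
}

# column-wise majority of three signatures; NULL when any column carries
# three distinct states (conservative multistate treatment)
triplet_median <- function(three) {
  chars <- do.call(rbind, strsplit(three, ""))
  if (ncol(chars) == 0) return(NULL)
  med <- character(ncol(chars))
  for (c in seq_len(ncol(chars))) {
    states <- chars[, c]
    tab <- table(states)
    if (length(tab) == 3) return(NULL)
    med[c] <- names(tab)[which.max(tab)]
  }
  paste(med, collapse = "")
}

degree_count <- function(ids, edges) {
  deg <- setNames(rep(0L, length(ids)), ids)
  if (nrow(edges)) {
    t1 <- table(edges$from); t2 <- table(edges$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Spanning cost of a haplotype network's node set
#'
#' Minimum spanning cost (total mutational steps) over all nodes, sampled
#' and median, under Hamming distances. Adding median vectors can only keep
#' this at or below the spanning cost over the sampled haplotypes alone.
#'
#' @param net A `haplo_network`.
#' @return Numeric cost.
#' @export
network_cost <- function(net) {
  sigs <- setNames(net$nodes$signature, net$nodes$id)
  mst_cost(hamming_matrix(sigs))
}

#' Annotate network nodes with member counts per category
#'
#' Each sampled node receives the count of its members per species
#' (wild *O. rufipogon*, outgroup *O. barthii*) or cultivated subspecies
#' (indica, japonica); median vectors carry zero counts.
#'
#' @param net A `haplo_network`.
#' @param haps The `haplotype_tbl` the network was built from.
#' @param samples Validated sample metadata covering all members.
#' @return The network with count columns added to `nodes` (and as igraph
#'   vertex attributes).
#' @export
annotate_network <- function(net, haps, samples) {
  cats <- c("rufipogon", "indica", "japonica", "barthii")
  cat_of <- setNames(
    ifelse(samples$species == "sativa", samples$subspecies, samples$species),
    samples$accession
  )
  counts <- matrix(0L, nrow(net$nodes), length(cats),
                   dimnames = list(net$nodes$id, cats))
  for (i in seq_len(nrow(haps))) {
    members <- haps$members[[i]]
    missing <- setdiff(members, names(cat_of))
    if (length(missing)) {
      abort(paste0("Members not in sample table: ",
                   paste(missing, collapse = ", ")))
    }
    id <- haps$haplotype_id[[i]]
    if (!id %in% rownames(counts)) next
    tab <- table(factor(cat_of[members], levels = cats))
    counts[id, ] <- as.integer(tab)
  }
  for (cc in cats) {
    net$nodes[[paste0("n_", cc)]] <- as.integer(counts[net$nodes$id, cc])
    net$graph <- igraph::set_vertex_attr(
      net$graph, paste0("n_", cc),
      value = as.integer(counts[igraph::V(net$graph)$name, cc]))
  }
  net
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> ", sum(x$nodes$kind == "sampled"), " haplotypes, ",
      sum(x$nodes$kind == "median"), " median vectors, ",
      nrow(x$edges), " links\n", sep = "")
  invisible(x)
}

#' @describeIn build_mj_network Tidy the network into an edge tibble with
#'   endpoint kinds.
#' @param x A `haplo_network`.
#' @param ... Unused.
#' @export
tidy.haplo_network <- function(x, ...) {
  kinds <- setNames(x$nodes$kind, x$nodes$id)
  x$edges |>
    mutate(from_kind = unname(kinds[.data$from]),
           to_kind = unname(kinds[.data$to]))
}

#' Write a haplotype network to GraphML
#'
#' Node attributes: `kind`, `signature`, `n_members`, and per-category
#' counts when the network has been annotated; edge attribute `steps`.
#'
#' @param net A `haplo_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_dot <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "dot")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' Plot a haplotype network
#'
#' Circles are sampled haplotypes (area proportional to member count),
#' small squares are inferred median vectors; edges are labelled with their
#' mutational steps when greater than one.
#'
#' @param object A `haplo_network`.
#' @param seed Layout seed (Fruchterman-Reingold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplo_network <- function(object, seed = 42, ...) {
  lay <- withr::with_seed(seed, igraph::layout_with_fr(object$graph))
  nodes <- object$nodes |>
    mutate(x = lay[, 1], y = lay[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "id", xf = "x", yf = "y"), by = c(from = "id")) |>
    left_join(select(nodes, "id", xt = "x", yt = "y"), by = c(to = "id")) |>
    mutate(mx = (.data$xf + .data$xt) / 2, my = (.data$yf + .data$yt) / 2)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xf, y = .data$yf, xend = .data$xt, yend = .data$yt),
      colour = "grey50") +
    ggplot2::geom_text(
      data = filter(edges, .data$steps > 1),
      ggplot2::aes(x = .data$mx, y = .data$my, label = .data$steps),
      size = 3, colour = "grey30") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = pmax(.data$n_members, 1),
                   shape = .data$kind, colour = .data$kind)) +
    ggplot2::geom_text(
      data = filter(nodes, .data$kind == "sampled"),
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1.2, size = 3) +
    ggplot2::scale_shape_manual(values = c(sampled = 16, median = 15)) +
    ggplot2::scale_size_area(max_size = 12, guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(shape = NULL, colour = NULL)
}
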