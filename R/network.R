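#' Jaccard similarity of two terms' parent sets
#'
#' Intersection over union of the parent GO terms of two gene sets, per
#' the supplied parent table. Terms absent from the table have no parents,
#' and an empty union yields 0 by convention.
#'
#' @param term_a,term_b Gene-set (GO term) ids.
#' @param parents Parent table (`term`, `parent`), see
#'   [read_parent_table()].
#' @return A value in \[0, 1\].
#' @export
parent_jaccard <- function(term_a, term_b, parents) {
  pa <- parents$parent[parents$term == term_a]
  pb <- parents$parent[parents$term == term_b]
  u <- length(union(pa, pb))
  if (u == 0) return(0)
  length(intersect(pa, pb)) / u
}

#' Build and cluster the gene-set similarity network
#'
#' Connects signature-hit gene sets whose parent-term Jaccard similarity
#' is strictly greater than `jaccard_min`, takes connected components of
#' the thresholded graph as clusters, and retains only sets in components
#' strictly larger than `min_cluster_size` members. Cluster ids are
#' deterministic: each cluster is named after its lexicographically
#' smallest member.
#'
#' @param hits Character vector of gene-set ids (e.g. the hit components
#'   from [select_signatures()]).
#' @param parents Parent table (`term`, `parent`).
#' @param jaccard_min Strict lower bound for an edge.
#' @param min_cluster_size Strict lower bound on retained cluster size.
#' @return A list of class `set_network` with tibbles `nodes` (`node`,
#'   `cluster`, `cluster_size`, `retained`) and `edges` (`from`, `to`,
#'   `jaccard`).
#' @export
build_set_network <- function(hits, parents, jaccard_min = 0.5,
                              min_cluster_size = 9) {
  hits <- unique(as.character(hits))
  if (length(hits) == 0) abort("hits must be non-empty")
  check_fraction(jaccard_min, "jaccard_min")
  plist <- split(parents$parent, parents$term)
  plist <- lapply(plist, unique)
  psets <- lapply(hits, function(h) plist[[h]] %||% character())
  names(psets) <- hits

  # sparse pairwise Jaccard via a parent -> sets incidence
  n <- length(hits)
  sizes <- lengths(psets)
  inc <- tibble(
    set = rep(seq_len(n), sizes),
    parent = unlist(psets, use.names = FALSE)
  )
  pairs <- dplyr::inner_join(inc, inc, by = "parent",
                             relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$set.x < .data$set.y)
  pairs <- dplyr::count(pairs, .data$set.x, .data$set.y, name = "inter")
  if (nrow(pairs) > 0) {
    pairs$jaccard <- pairs$inter /
      (sizes[pairs$set.x] + sizes[pairs$set.y] - pairs$inter)
    pairs <- dplyr::filter(pairs, .data$jaccard > jaccard_min)
  }
  edges <- tibble(from = hits[pairs$set.x], to = hits[pairs$set.y],
                  jaccard = pairs$jaccard %||% numeric())

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = hits))
  comp <- igraph::components(g)
  member <- split(hits, comp$membership[hits])
  cluster_id <- vapply(member, function(v) min(v), character(1))
  nodes <- tibble(
    node = hits,
    cluster = unname(cluster_id[as.character(comp$membership[hits])]),
    cluster_size = as.integer(comp$csize[comp$membership[hits]])
  )
  nodes$retained <- nodes$cluster_size > min_cluster_size
  structure(list(nodes = nodes, edges = edges),
            class = "set_network",
            jaccard_min = jaccard_min, min_cluster_size = min_cluster_size)
}

#' @export
print.set_network <- function(x, ...) {
  cat(sprintf(
    "<set_network> %d node(s), %d edge(s), %d cluster(s), %d retained node(s)\n",
    nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$cluster)),
    sum(x$nodes$retained)))
  invisible(x)
}
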