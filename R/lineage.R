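#' Build lineage trees from a link graph
#'
#' Traces every track start (a linked position with no incoming link) forward
#' through the links, producing one genealogical tree per founder cell. A
#' division (out-degree 2) creates a binary branch point. Merges (in-degree
#' greater than 1) violate the link-graph invariants and raise an error.
#'
#' @param exp A [tracking_experiment()], or a links tibble.
#' @param include_singletons Also emit single-node trees for positions that
#'   have no links at all (default `FALSE`: trees partition the linked
#'   positions).
#' @param positions Required when `exp` is a bare links tibble and
#'   `include_singletons` is `TRUE`.
#' @return A tibble of class `lineage_forest` with one row per position in a
#'   tree: columns `tree_id`, `t`, `i`, `parent_t`, `parent_i` (`NA` at
#'   roots) and `divisions`, the number of branch points on the path from the
#'   root to (but excluding) the position.
#' @examples
#' lk <- links_tbl(t = c(0, 0), from = c(1, 1), to = c(1, 2))  # one division
#' build_lineage_trees(lk)
#' @export
build_lineage_trees <- function(exp, include_singletons = FALSE, positions = NULL) {
  if (inherits(exp, "tracking_experiment")) {
    links <- exp$links
    positions <- exp$positions
  } else {
    links <- exp
    check_links(links)
  }
  child_key <- pos_key(links$t + 1L, links$to)
  if (anyDuplicated(child_key)) {
    dup <- child_key[duplicated(child_key)][1]
    stop(sprintf("build_lineage_trees: merge detected (two parents link to position %s)", dup),
         call. = FALSE)
  }
  nodes <- unique(rbind(
    data.frame(t = links$t, i = links$from),
    data.frame(t = links$t + 1L, i = links$to)
  ))
  if (include_singletons && !is.null(positions)) {
    all_nodes <- data.frame(t = positions$t, i = positions$i)
    nodes <- unique(rbind(nodes, all_nodes))
  }
  if (!nrow(nodes)) {
    return(structure(tibble::tibble(tree_id = integer(), t = integer(), i = integer(),
                                    parent_t = integer(), parent_i = integer(),
                                    divisions = integer()),
                     class = c("lineage_forest", "tbl_df", "tbl", "data.frame")))
  }
  nodes <- nodes[order(nodes$t, nodes$i), ]
  key <- pos_key(nodes$t, nodes$i)
  idx <- stats::setNames(seq_len(nrow(nodes)), key)

  parent <- rep(NA_integer_, nrow(nodes))
  parent[idx[child_key]] <- idx[pos_key(links$t, links$from)]
  outdeg <- tabulate(idx[pos_key(links$t, links$from)], nbins = nrow(nodes))

  tree_id <- rep(NA_integer_, nrow(nodes))
  divisions <- rep(0L, nrow(nodes))
  roots <- which(is.na(parent))
  tree_id[roots] <- seq_along(roots)
  # nodes are sorted by frame, so parents are always processed first
  for (k in seq_len(nrow(nodes))) {
    p <- parent[k]
    if (!is.na(p)) {
      tree_id[k] <- tree_id[p]
      divisions[k] <- divisions[p] + (outdeg[p] == 2L)
    }
  }
  structure(tibble::tibble(tree_id = tree_id, t = nodes$t, i = nodes$i,
                           parent_t = nodes$t[parent], parent_i = nodes$i[parent],
                           divisions = divisions),
            class = c("lineage_forest", "tbl_df", "tbl", "data.frame"))
}

#' Count divisions on the path from a lineage root to a position
#'
#' @param forest A [build_lineage_trees()] result.
#' @param t,i The position (frame index and within-frame index).
#' @return Integer: the number of branch points between the root of the
#'   position's tree and the position.
#' @examples
#' lk <- links_tbl(t = c(0, 0), from = c(1, 1), to = c(1, 2))
#' fr <- build_lineage_trees(lk)
#' count_divisions(fr, 1, 2)  # 1: below one division
#' @export
count_divisions <- function(forest, t, i) {
  stopifnot(inherits(forest, "lineage_forest"))
  hit <- forest$t == t & forest$i == i
  if (!any(hit)) {
    stop(sprintf("count_divisions: position (t=%s, i=%s) not found in any tree", t, i),
         call. = FALSE)
  }
  forest$divisions[which(hit)[1]]
}
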