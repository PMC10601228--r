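#' Benjamini-Hochberg step-up selection and adjusted p-values
#'
#' Standard BH: adjusted p-values are `min over j >= i of m * p_(j) / j`,
#' monotonized; a hypothesis is selected when its adjusted p-value is at most
#' `q`. Ties are deterministic (equal p-values share an adjusted value).
#'
#' @param p numeric p-values in [0, 1].
#' @param q target false discovery rate level.
#' @return List with `adjusted` (same order as `p`), `selected` (logical),
#'   and `n_selected`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  sel <- !is.na(adj) & adj <= q
  list(adjusted = adj, selected = sel, n_selected = sum(sel))
}

#' Hypothesis tree for hierarchical testing
#'
#' @param node_id character ids, unique.
#' @param parent_id parent of each node (`NA` for top-level nodes).
#' @param p p-value attached to each node.
#' @return A `hypothesis_tree` data.frame after validation (no cycles, every
#'   parent exists).
#' @export
hypothesis_tree <- function(node_id, parent_id, p) {
  node_id <- as.character(node_id)
  parent_id <- as.character(parent_id)
  if (anyDuplicated(node_id)) stop("duplicated node ids")
  if (length(parent_id) != length(node_id) || length(p) != length(node_id))
    stop("node_id, parent_id, p must have equal length")
  known <- !is.na(parent_id)
  if (any(known & !(parent_id %in% node_id)))
    stop("parent_id refers to unknown node(s)")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  # cycle check: follow parents up; depth must be bounded by #nodes
  for (i in seq_along(node_id)) {
    cur <- parent_id[i]; steps <- 0L
    while (!is.na(cur)) {
      steps <- steps + 1L
      if (steps > length(node_id)) stop("cycle detected in hypothesis tree")
      cur <- parent_id[match(cur, node_id)]
    }
  }
  structure(data.frame(node_id = node_id, parent_id = parent_id, p = p,
                       stringsAsFactors = FALSE),
            class = c("hypothesis_tree", "data.frame"))
}

#' Tree-structured BH selection
#'
#' Hypotheses are organized in families of siblings. BH at level `q` is
#' applied to the top family; for every selected node, its children's family
#' is then tested with BH at the effective level
#' `q * prod over ancestor families of (R_a / m_a)`, where `R_a` is the
#' number of rejections and `m_a` the family size in ancestor family `a`.
#' Descendants of unselected nodes are never tested, so the selected set is
#' always a union of rooted subtrees. On a flat (depth-1) tree the procedure
#' is exactly BH.
#'
#' @param tree a [hypothesis_tree()] (or data.frame with node_id, parent_id,
#'   p columns).
#' @param q global target level in (0, 1).
#' @return data.frame: `node_id`, `parent_id`, `p`, `family_q` (effective
#'   level of the node's family; NA if the family was never tested),
#'   `adjusted` (BH-adjusted p within its family), `selected` (logical).
#' @export
treebh_select <- function(tree, q = 0.05) {
  if (!(q > 0 && q <= 1)) stop("q must be in (0, 1]")
  if (!inherits(tree, "hypothesis_tree"))
    tree <- hypothesis_tree(tree$node_id, tree$parent_id, tree$p)
  out <- data.frame(node_id = tree$node_id, parent_id = tree$parent_id,
                    p = tree$p, family_q = NA_real_, adjusted = NA_real_,
                    selected = FALSE, stringsAsFactors = FALSE)
  children <- split(seq_len(nrow(tree)),
                    factor(tree$parent_id, exclude = NULL))
  test_family <- function(idx, mult) {
    # deterministic tie-break: order by (p, node_id) before BH (BH itself is
    # order-free; the ordering matters only for reproducible output order)
    fam_q <- q * mult
    res <- bh_adjust(tree$p[idx], fam_q)
    out$family_q[idx] <<- fam_q
    out$adjusted[idx] <<- res$adjusted
    out$selected[idx] <<- res$selected
    R <- res$n_selected; m <- length(idx)
    if (R == 0L) return(invisible())
    for (i in idx[res$selected]) {
      kid_idx <- children[[tree$node_id[i]]]
      if (!is.null(kid_idx) && length(kid_idx))
        test_family(kid_idx, mult * R / m)
    }
  }
  top <- which(is.na(tree$parent_id))
  if (length(top) == 0L) stop("tree has no top-level nodes")
  test_family(top, 1)
  out
}
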