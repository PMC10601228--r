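#' Hierarchically cluster subjects in the embedding
#'
#' Agglomerative clustering with Ward linkage (Ward.D2 convention: each merge
#' minimizes the increase in total within-cluster sum of squares) on Euclidean
#' distances between embedding score rows. The resulting tree is the object
#' every later stage consumes: cuts of it define the partitions that are
#' tested, and the nesting of cuts defines the hypothesis hierarchy for the
#' tree-structured BH correction.
#'
#' @param embedding a `tk_embedding` (or a plain numeric matrix of scores).
#' @return A `tk_partition_tree` with elements `hclust` (the merge history),
#'   `scores`, `subject_id`, and (after [select_k()]) `selected_k`.
#' @export
hierarchical_cluster <- function(embedding) {
  scores <- if (inherits(embedding, "tk_embedding")) embedding$scores
            else as.matrix(embedding)
  if (nrow(scores) < 2L) stop("need at least 2 subjects to cluster")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  ids <- if (inherits(embedding, "tk_embedding")) embedding$subject_id
         else as.character(seq_len(nrow(scores)))
  structure(list(hclust = hc, scores = scores, subject_id = ids,
                 selected_k = NULL),
            class = "tk_partition_tree")
}

#' Cluster labels at a given cut
#'
#' @param tree a `tk_partition_tree`.
#' @param k number of clusters.
#' @return Integer labels in `1..k`, one per subject.
#' @export
labels_at <- function(tree, k) {
  as.integer(stats::cutree(tree$hclust, k = k))
}

#' Within-partition inertia of a labeling
#'
#' Total within-cluster sum of squared Euclidean distances to cluster
#' centroids, computed on the embedding scores.
#'
#' @param scores numeric matrix of coordinates.
#' @param labels integer cluster labels.
#' @return Nonnegative scalar.
#' @export
within_inertia <- function(scores, labels) {
  scores <- as.matrix(scores)
  tot <- 0
  for (g in unique(labels)) {
    Xg <- scores[labels == g, , drop = FALSE]
    ctr <- colMeans(Xg)
    tot <- tot + sum(sweep(Xg, 2, ctr)^2)
  }
  tot
}

#' Select the number of clusters by highest relative loss of inertia
#'
#' Let W(k) be the within-partition inertia of the cut at k clusters and
#' D(k) = W(k-1) - W(k) the inertia absorbed by moving from k-1 to k clusters.
#' The selected k maximizes D(k)/D(k+1) over k = 2..k_max: the cut after which
#' further splits stop paying. The criterion never returns k = 1 (the method
#' presumes at least two partitions); when D(k+1) is numerically zero the
#' ratio is treated as +Inf if D(k) > 0, otherwise that k is skipped.
#'
#' @param tree a `tk_partition_tree`.
#' @param k_max largest cluster count considered (default 6).
#' @return The input tree with `selected_k` set (invisibly also a plain
#'   integer via `$selected_k`).
#' @export
select_k <- function(tree, k_max = 6) {
  n <- length(tree$subject_id)
  if (k_max < 2L || k_max > n - 1L)
    stop("k_max must be in [2, n-1]")
  W <- vapply(seq_len(k_max + 1L), function(k)
    within_inertia(tree$scores, labels_at(tree, k)), numeric(1))
  D <- -diff(W)              # D[k] = W(k) - W(k+1) absorbed going to k+1
  # ratio(k) = D(k)/D(k+1) with D(k) = W(k-1) - W(k)
  eps <- 1e-12 * max(W[1], 1)
  best_k <- NA_integer_
  best_ratio <- -Inf
  for (k in 2:k_max) {
    dk <- D[k - 1L]          # W(k-1) - W(k)
    dk1 <- D[k]              # W(k) - W(k+1)
    if (dk1 <= eps) {
      if (dk > eps) ratio <- Inf else next
    } else ratio <- dk / dk1
    if (ratio > best_ratio) {
      best_ratio <- ratio
      best_k <- k
    }
  }
  if (is.na(best_k)) best_k <- 2L
  tree$selected_k <- as.integer(best_k)
  tree
}

#' Nested testing hierarchy from a partition tree
#'
#' Returns the cuts used as the hypothesis hierarchy: the root (all subjects)
#' plus the selected cut by default, or every intermediate cut 2..selected_k
#' when `intermediate = TRUE`.
#'
#' @param tree a `tk_partition_tree` with `selected_k` set.
#' @param intermediate include intermediate cuts between root and selected cut.
#' @return Integer vector of cut sizes, starting with 1 (the root).
#' @export
hierarchy_cuts <- function(tree, intermediate = FALSE) {
  k <- tree$selected_k
  if (is.null(k)) stop("run select_k() first")
  if (intermediate && k > 2L) c(1L, 2:k) else c(1L, k)
}

#' @export
print.tk_partition_tree <- function(x, ...) {
  cat("tk_partition_tree: ", length(x$subject_id), " subjects",
      if (!is.null(x$selected_k))
        paste0(", selected k = ", x$selected_k,
               " (sizes ", paste(table(labels_at(x, x$selected_k)),
                                 collapse = "/"), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Matched-pair F1 score between two labelings
#'
#' Clusters are matched one-to-one to true classes by maximum-weight
#' assignment on the contingency table (exhaustive search, intended for at
#' most ~8 clusters a side), and the micro-averaged F1 over the matched pairs
#' is returned: 2 * (matched overlap) / (n + n), i.e. the share of subjects
#' landing in the cluster matched to their true class. Relabelings and
#' permutations of cluster names therefore score 1.
#'
#' @param true_labels,est_labels equal-length label vectors (any atomic type).
#' @return F1 in [0, 1].
#' @export
partition_f1 <- function(true_labels, est_labels) {
  if (length(true_labels) != length(est_labels))
    stop("label vectors must have equal length")
  n <- length(true_labels)
  tab <- table(true_labels, est_labels)
  2 * max_assignment(tab) / (2 * n)
}

#' Maximum one-to-one matching of estimated clusters to true classes
#'
#' @param tab contingency table (true x estimated).
#' @return Total overlap of the best assignment.
#' @keywords internal
max_assignment <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) > ncol(tab)) tab <- t(tab)
  r <- nrow(tab); c <- ncol(tab)
  if (r > 9L) stop("exhaustive matching supports at most 9 clusters")
  best <- -1
  rec <- function(i, used, acc) {
    if (i > r) {
      if (acc > best) best <<- acc
      return()
    }
    if (acc + sum(apply(tab[i:r, , drop = FALSE], 1, max)) <= best)
      return()
    for (j in seq_len(c)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + tab[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, c), 0)
  best
}

#' Match estimated clusters to true classes
#'
#' Returns, for each true class, the estimated cluster assigned to it by the
#' maximum-weight one-to-one matching (NA when there are fewer estimated
#' clusters than classes and the class went unmatched).
#'
#' @param true_labels,est_labels equal-length label vectors.
#' @return Named integer vector: for each true class (names), the matched
#'   estimated cluster label.
#' @export
match_clusters <- function(true_labels, est_labels) {
  tab <- as.matrix(table(true_labels, est_labels))
  r <- nrow(tab); c <- ncol(tab)
  k <- min(r, c)
  if (max(r, c) > 9L) stop("exhaustive matching supports at most 9 clusters")
  # enumerate injective assignments of the smaller side into the larger
  best <- -1; best_map <- NULL
  rows <- seq_len(r); cols <- seq_len(c)
  rec <- function(i, used, acc, map) {
    if (i > r) {
      if (acc > best) { best <<- acc; best_map <<- map }
      return()
    }
    # allow leaving a row unmatched only if rows outnumber columns
    if (r > c) rec(i + 1L, used, acc, c(map, NA_integer_))
    for (j in cols) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + tab[i, j], c(map, j))
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, c), 0, integer(0))
  est_levels <- colnames(tab)
  out <- stats::setNames(est_levels[best_map], rownames(tab))
  out
}
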