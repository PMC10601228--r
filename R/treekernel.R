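#' Kernel association tests within clinical covariate partitions
#'
#' The main fitting function. Subjects are embedded from their clinical
#' covariates (principal components for all-continuous tables, FAMD for mixed
#' tables), hierarchically clustered with Ward linkage, and the number of
#' partitions is chosen by the highest relative loss of inertia. A kernel
#' machine score test of the omics features against the outcome, adjusted for
#' the clinical covariates, is then run on the all-subjects root and within
#' each partition — per pathway when pathways are supplied — and the
#' hierarchy of p-values is corrected with tree-structured BH at level `q`.
#'
#' @param outcome numeric outcome vector, or an [outcome()] object.
#' @param clinical a [clinical_table()] (or plain data.frame of covariates).
#' @param omics an [omics_matrix()] (or numeric matrix, rows aligned to the
#'   clinical table; if both carry subject ids they are aligned by id).
#' @param pathways optional named list of [pathway_graph()]s; each pathway is
#'   tested on its own feature subset. `NULL` tests the whole matrix.
#' @param kernel a [kernel_spec()] or kernel name (default linear).
#' @param k_embed embedding components (default 5, capped at rank).
#' @param k_max largest cluster count offered to the cut selection.
#' @param q TreeBH target level.
#' @param family `"gaussian"` or `"binomial"` (ignored when `outcome` is an
#'   [outcome()] object).
#' @param partition test within the selected partitions (the default). With
#'   `partition = FALSE` only the global all-subjects test is run per
#'   pathway, and TreeBH reduces to plain BH across pathways.
#' @param min_size minimum partition size (smaller partitions are skipped)
#'   and minimum pathway feature count after intersection with the omics
#'   columns (smaller pathways are skipped).
#' @param include_root test the all-subjects root node.
#' @param intermediate include intermediate tree cuts as extra hierarchy
#'   levels.
#' @param tree_orientation with pathways, `"pathway_major"` puts the pathway
#'   root tests in the top TreeBH family with their partitions as children;
#'   `"partition_major"` puts the partition nodes (pooled across pathways at
#'   the root level) on top.
#' @return An object of class `treekernel` with components `results` (long
#'   table: pathway, node_id, parent_id, level, label, n, Q, p_value,
#'   family_q, adjusted, selected, skipped), `embedding`, `tree`,
#'   `partition_summary`, `skipped_pathways`, and the call.
#' @export
treekernel <- function(outcome, clinical, omics, pathways = NULL,
                       kernel = kernel_spec("linear"), k_embed = 5,
                       k_max = 6, q = 0.05, family = "gaussian",
                       partition = TRUE, min_size = 10, include_root = TRUE,
                       intermediate = FALSE,
                       tree_orientation = c("pathway_major",
                                            "partition_major")) {
  tree_orientation <- match.arg(tree_orientation)
  if (inherits(outcome, "outcome")) {
    family <- outcome$family
    Y <- outcome$values
  } else Y <- as.numeric(outcome)
  if (!inherits(clinical, "clinical_table"))
    clinical <- clinical_table(as.data.frame(clinical))
  if (!inherits(omics, "omics_matrix")) omics <- omics_matrix(omics)
  if (!is.null(attr(clinical, "subject_id")) &&
      !is.null(attr(omics, "subject_id")) &&
      !identical(attr(clinical, "subject_id"), attr(omics, "subject_id")))
    omics <- align_subjects(clinical, omics)
  if (length(Y) != nrow(clinical)) stop("outcome length != subject count")
  if (is.character(kernel)) kernel <- kernel_spec(kernel)

  emb <- embed_clinical(clinical, k = k_embed)
  tree <- select_k(hierarchical_cluster(emb), k_max = k_max)
  labs <- labels_at(tree, tree$selected_k)

  run_one <- function(Zsub, graph) {
    test_within_partitions(Y, clinical, Zsub, tree, spec = kernel,
                           family = family, min_size = min_size,
                           include_root = if (partition) include_root else TRUE,
                           include_leaves = partition,
                           intermediate = intermediate, graph = graph)
  }

  skipped_pathways <- character(0)
  if (is.null(pathways)) {
    tab <- run_one(omics, NULL)
    tab$pathway <- "(all features)"
    tested <- tab[!tab$skipped, , drop = FALSE]
    sel <- treebh_select(hypothesis_tree(tested$node_id, tested$parent_id,
                                         tested$p_value), q = q)
    results <- merge(tab, sel[, c("node_id", "family_q", "adjusted",
                                  "selected")],
                     by = "node_id", all.x = TRUE, sort = FALSE)
  } else {
    per_pw <- list()
    for (nm in names(pathways)) {
      pw <- pathways[[nm]]
      feats <- intersect(pw$nodes, colnames(omics))
      if (length(feats) < min_size) {
        skipped_pathways <- c(skipped_pathways, nm)
        next
      }
      Zsub <- unclass(omics)[, feats, drop = FALSE]
      gsub <- restrict_graph(pw, feats)
      tab <- run_one(Zsub, if (is.null(kernel$graph_tau)) NULL else gsub)
      tab$pathway <- nm
      per_pw[[nm]] <- tab
    }
    if (!length(per_pw)) stop("no pathway passed the size filter")
    if (tree_orientation == "pathway_major") {
      # top family: per-pathway root tests; children: that pathway's
      # partition tests
      per_pw <- lapply(per_pw, function(tab) {
        tab$node_id <- paste0(tab$pathway, "::", tab$node_id)
        tab$parent_id <- ifelse(is.na(tab$parent_id), NA,
                                paste0(tab$pathway, "::", tab$parent_id))
        tab
      })
      tab <- do.call(rbind, per_pw)
    } else {
      # partition-major: whole-matrix tests form the upper tree (root, then
      # partitions), and each pathway's within-partition test hangs under
      # its partition node; every internal node carries a real test
      whole <- run_one(omics, NULL)
      whole$pathway <- "(all features)"
      whole$node_id <- paste0("ALL::", whole$node_id)
      whole$parent_id <- ifelse(is.na(whole$parent_id), NA,
                                paste0("ALL::", whole$parent_id))
      per_pw <- lapply(per_pw, function(tab) {
        tab <- tab[tab$level == max(tab$level), , drop = FALSE]
        tab$parent_id <- paste0("ALL::k", tree$selected_k, ".g", tab$label)
        tab$node_id <- paste0(tab$pathway, "::", tab$node_id)
        tab$level <- tab$level + 1L
        tab
      })
      tab <- rbind(whole, do.call(rbind, per_pw))
    }
    tested <- tab[!tab$skipped, , drop = FALSE]
    sel <- treebh_select(hypothesis_tree(tested$node_id, tested$parent_id,
                                         tested$p_value), q = q)
    results <- merge(tab, sel[, c("node_id", "family_q", "adjusted",
                                  "selected")],
                     by = "node_id", all.x = TRUE, sort = FALSE)
  }
  results$selected[is.na(results$selected) & !results$skipped] <- FALSE
  results <- results[order(results$pathway, results$level, results$label), ]
  rownames(results) <- NULL

  psum <- partition_summary(clinical, labs)
  structure(list(results = results, embedding = emb, tree = tree,
                 labels = labs, partition_summary = psum,
                 skipped_pathways = skipped_pathways, q = q,
                 kernel = kernel, family = family, call = match.call()),
            class = "treekernel")
}

restrict_graph <- function(pw, feats) {
  ed <- pw$edges
  if (nrow(ed))
    ed <- ed[ed[, 1] %in% feats & ed[, 2] %in% feats, , drop = FALSE]
  pathway_graph(feats, ed, name = pw$name)
}

partition_summary <- function(clinical, labs) {
  df <- as.data.frame(clinical)
  out <- data.frame(partition = sort(unique(labs)),
                    n = as.integer(table(labs)))
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]))
      out[[paste0("mean_", nm)]] <-
        as.numeric(tapply(df[[nm]], labs, mean))
  }
  out
}

#' @export
print.treekernel <- function(x, ...) {
  cat("TreeKernel: kernel association tests within clinical partitions\n")
  cat("  kernel:", x$kernel$name, " family:", x$family,
      " q =", x$q, "\n")
  cat("  embedding:", x$embedding$method, "with k =", x$embedding$k,
      "components\n")
  cat("  selected partitions:", x$tree$selected_k,
      "(sizes", paste(table(x$labels), collapse = "/"), ")\n")
  nsel <- sum(x$results$selected, na.rm = TRUE)
  cat("  tested nodes:", sum(!x$results$skipped), " selected:", nsel, "\n")
  invisible(x)
}

#' @export
summary.treekernel <- function(object, ...) {
  res <- object$results
  res <- res[order(res$p_value), ]
  structure(list(results = res,
                 partition_summary = object$partition_summary,
                 inertia = object$embedding$explained_inertia,
                 selected_k = object$tree$selected_k,
                 skipped_pathways = object$skipped_pathways,
                 q = object$q),
            class = "summary.treekernel")
}

#' @export
print.summary.treekernel <- function(x, ...) {
  cat("TreeKernel summary\n")
  cat("embedding inertia:",
      paste(sprintf("%.3f", x$inertia), collapse = " "), "\n")
  cat("selected k:", x$selected_k, "\n\nPartition summary:\n")
  print(x$partition_summary, row.names = FALSE)
  cat("\nTest results (ordered by p):\n")
  cols <- intersect(c("pathway", "node_id", "n", "Q", "p_value", "adjusted",
                      "selected"), names(x$results))
  print(utils::head(x$results[, cols], 20), row.names = FALSE, digits = 4)
  if (length(x$skipped_pathways))
    cat("\nskipped pathways (too few features):",
        paste(x$skipped_pathways, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a fitted treekernel object
#'
#' Draws the clustering dendrogram with the selected cut and, alongside it,
#' the per-node p-values with TreeBH selections marked.
#'
#' @param x a `treekernel` object.
#' @param ... passed to `plot.hclust`.
#' @export
plot.treekernel <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  plot(x$tree$hclust, labels = FALSE, hang = -1,
       main = "Clinical partition tree", xlab = "", sub = "", ...)
  stats::rect.hclust(x$tree$hclust, k = x$tree$selected_k, border = 2)
  res <- x$results[!x$results$skipped, ]
  graphics::plot(seq_len(nrow(res)), -log10(res$p_value),
                 pch = ifelse(res$selected, 19, 1),
                 col = ifelse(res$selected, 2, 1),
                 xlab = "tested node", ylab = "-log10 p",
                 main = "Per-node tests (filled = selected)")
  graphics::abline(h = -log10(x$q), lty = 2)
  invisible(x)
}

#' Write the results table of a fit to TSV
#'
#' @param x a `treekernel` object.
#' @param path output file.
#' @export
write_results <- function(x, path) {
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
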