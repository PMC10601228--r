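#' Kernel specification
#'
#' Bundles a kernel name with its hyperparameters. The kernel turns the n x m
#' omics matrix into an n x n similarity matrix h(Z) entering the outcome
#' model g(Y) = C beta + h(Z) + eps.
#'
#' @param name `"linear"`, `"polynomial"`, or `"gaussian"`.
#' @param degree polynomial degree d >= 1.
#' @param offset polynomial offset rho (rho < 0 can break positive
#'   semidefiniteness and triggers a warning at evaluation).
#' @param bandwidth Gaussian precision rho > 0, or `"median"` for the median
#'   heuristic.
#' @param squared_median use the median of squared pairwise distances for the
#'   heuristic instead of unsquared distances (both conventions circulate;
#'   unsquared is the default).
#' @param graph_tau optional nonnegative graph-smoothing strength; see
#'   [graph_smoothed_input()].
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(name = c("linear", "polynomial", "gaussian"),
                        degree = 2, offset = 0, bandwidth = "median",
                        squared_median = FALSE, graph_tau = NULL) {
  name <- match.arg(name)
  if (name == "polynomial" && degree < 1) stop("degree must be >= 1")
  if (name == "gaussian" && !identical(bandwidth, "median")) {
    if (!is.numeric(bandwidth) || bandwidth <= 0)
      stop("gaussian bandwidth must be positive or 'median'")
  }
  if (!is.null(graph_tau) && graph_tau < 0) stop("graph_tau must be >= 0")
  structure(list(name = name, degree = degree, offset = offset,
                 bandwidth = bandwidth, squared_median = squared_median,
                 graph_tau = graph_tau),
            class = "kernel_spec")
}

#' Evaluate a kernel on an omics matrix
#'
#' @param Z numeric n x m matrix (or [omics_matrix()]).
#' @param spec a [kernel_spec()], or a kernel name string.
#' @param graph optional [pathway_graph()]; when `spec$graph_tau` is set the
#'   columns of Z are graph-smoothed before the kernel is computed.
#' @return Symmetric n x n `kernel_matrix`.
#' @export
kernel_matrix <- function(Z, spec = kernel_spec("linear"), graph = NULL) {
  if (is.character(spec)) spec <- kernel_spec(spec)
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("non-finite entries in Z")
  if (!is.null(spec$graph_tau) && !is.null(graph))
    Z <- graph_smoothed_input(Z, graph, spec$graph_tau)
  K <- switch(spec$name,
    linear = linear_kernel(Z),
    polynomial = polynomial_kernel(Z, rho = spec$offset, d = spec$degree),
    gaussian = gaussian_kernel(Z, rho = spec$bandwidth,
                               squared_median = spec$squared_median))
  K
}

#' Linear kernel: K = Z Z^T
#' @param Z numeric n x m matrix.
#' @return n x n `kernel_matrix`.
#' @export
linear_kernel <- function(Z) {
  Z <- as.matrix(Z)
  new_kernel_matrix(tcrossprod(Z))
}

#' Polynomial kernel: K_ij = (z_i' z_j + rho)^d
#' @param Z numeric n x m matrix.
#' @param rho offset; negative values can break positive semidefiniteness.
#' @param d degree, a positive integer.
#' @return n x n `kernel_matrix`.
#' @export
polynomial_kernel <- function(Z, rho = 0, d = 2) {
  if (d < 1) stop("d must be >= 1")
  if (rho < 0) warning("rho < 0 may yield an indefinite kernel matrix")
  Z <- as.matrix(Z)
  new_kernel_matrix((tcrossprod(Z) + rho)^d)
}

#' Gaussian kernel: K_ij = exp(-||z_i - z_j||^2 / rho)
#'
#' With `rho = "median"` the precision is set by the median heuristic: the
#' median of all n(n-1)/2 pairwise Euclidean distances between rows of Z
#' (unsquared by default; set `squared_median = TRUE` for the median of
#' squared distances, the other convention in circulation).
#'
#' @param Z numeric n x m matrix.
#' @param rho positive precision, or `"median"`.
#' @param squared_median use squared distances in the median heuristic.
#' @return n x n `kernel_matrix` with unit diagonal.
#' @export
gaussian_kernel <- function(Z, rho = "median", squared_median = FALSE) {
  Z <- as.matrix(Z)
  d2 <- sq_dist(Z)
  if (identical(rho, "median")) {
    pd <- d2[upper.tri(d2)]
    rho <- if (squared_median) stats::median(pd)
           else stats::median(sqrt(pd))
    if (!is.finite(rho) || rho <= 0)
      stop("median pairwise distance is 0 (identical rows?); ",
           "supply a numeric bandwidth")
  }
  if (rho <= 0) stop("rho must be positive")
  new_kernel_matrix(exp(-d2 / rho))
}

sq_dist <- function(Z) {
  s <- rowSums(Z^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(Z)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

new_kernel_matrix <- function(K) {
  K <- (K + t(K)) / 2   # kill numerical asymmetry
  structure(K, class = c("kernel_matrix", "matrix", "array"))
}

#' Graph-smooth an omics matrix with a pathway Laplacian
#'
#' Returns `Z (I + tau L)^-1`, where L is the symmetric normalized Laplacian
#' of the pathway graph restricted to the features present in Z (rows/columns
#' for degree-0 nodes are zero, so isolated features pass through untouched).
#' Smoothing shrinks each feature toward its graph neighbours before a kernel
#' is computed, so pathway topology informs the similarity. This is a
#' topology-aware preprocessing hook; verify its regularization convention
#' against the pathway-kernel method you intend to reproduce before
#' scientific use.
#'
#' @param Z numeric n x m matrix with named columns.
#' @param graph a [pathway_graph()] whose nodes are a subset of `colnames(Z)`.
#' @param tau nonnegative smoothing strength; `tau = 0` returns Z unchanged.
#' @return Matrix of the same shape as Z.
#' @export
graph_smoothed_input <- function(Z, graph, tau = 1) {
  if (tau < 0) stop("tau must be >= 0")
  Z <- as.matrix(Z)
  feats <- colnames(Z)
  if (is.null(feats)) stop("Z must have column names to match graph nodes")
  if (!all(graph$nodes %in% feats))
    stop("graph nodes not present in Z: ",
         paste(setdiff(graph$nodes, feats), collapse = ", "))
  if (tau == 0 || nrow(graph$edges) == 0L) return(Z)
  L <- normalized_laplacian(graph)
  idx <- match(graph$nodes, feats)
  M <- diag(length(idx)) + tau * L
  Z[, idx] <- t(solve(M, t(Z[, idx, drop = FALSE])))
  Z
}

#' Symmetric normalized Laplacian of a pathway graph
#'
#' `L = I - D^{-1/2} A D^{-1/2}` on nodes with positive degree; rows and
#' columns of degree-0 nodes are zero.
#'
#' @param graph a [pathway_graph()].
#' @return Symmetric m x m matrix ordered as `graph$nodes`.
#' @export
normalized_laplacian <- function(graph) {
  m <- length(graph$nodes)
  A <- matrix(0, m, m, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges[, 1], graph$nodes)
    j <- match(graph$edges[, 2], graph$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  d <- rowSums(A)
  L <- matrix(0, m, m, dimnames = dimnames(A))
  pos <- d > 0
  if (any(pos)) {
    dinv <- 1 / sqrt(d[pos])
    L[pos, pos] <- diag(sum(pos)) -
      (dinv * A[pos, pos, drop = FALSE]) %*% diag(dinv, sum(pos))
  }
  L
}
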