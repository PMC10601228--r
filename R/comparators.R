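#' F-test on all principal components of Z (FPC)
#'
#' Nested-model F-test comparing `g(Y) ~ C` against `g(Y) ~ C + S`, where S
#' holds all principal-component scores of the column-centered Z up to
#' numerical rank (singular values above `1e-10 * max`). A simple omnibus
#' baseline for association between Y and Z after adjusting for C.
#'
#' @param Y numeric outcome.
#' @param C covariates (data.frame/matrix) or `NULL`.
#' @param Z omics matrix.
#' @return p-value of the F-test.
#' @export
fpc_test <- function(Y, C = NULL, Z) {
  Y <- as.numeric(Y)
  Z <- as.matrix(Z)
  n <- length(Y)
  X0 <- null_design(C, n)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  sv <- svd(Zc)
  r <- sum(sv$d > 1e-10 * max(sv$d, 0))
  if (r == 0L) stop("Z has numerical rank 0 after centering")
  S <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  p0 <- qr(X0)$rank
  df2 <- n - p0 - r
  if (df2 < 1L) stop("insufficient residual degrees of freedom for the FPC test")
  fit0 <- stats::lm.fit(X0, Y)
  fit1 <- stats::lm.fit(cbind(X0, S), Y)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  Fstat <- ((rss0 - rss1) / r) / (rss1 / df2)
  stats::pf(Fstat, r, df2, lower.tail = FALSE)
}

#' Minimum Simes-adjusted p-value over univariate feature tests
#'
#' Each feature j is tested by the coefficient t-test in `Y ~ C + Z_j`; the m
#' p-values are combined with the Simes procedure,
#' `min over i of m * p_(i) / i`, giving a single global p-value.
#'
#' @inheritParams fpc_test
#' @return Simes-combined p-value.
#' @export
univariate_simes <- function(Y, C = NULL, Z) {
  Y <- as.numeric(Y)
  Z <- as.matrix(Z)
  n <- length(Y)
  X0 <- null_design(C, n)
  m <- ncol(Z)
  pv <- numeric(m)
  for (j in seq_len(m)) {
    X <- cbind(X0, zj = Z[, j])
    fit <- stats::lm.fit(X, Y)
    df <- n - ncol(X)
    if (df < 1L) stop("insufficient degrees of freedom for univariate tests")
    s2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(s2 * XtXinv[ncol(X), ncol(X)])
    tstat <- fit$coefficients[ncol(X)] / se
    pv[j] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  simes_combine(pv)
}

#' Simes combination of p-values
#'
#' @param p numeric p-values.
#' @return `min over i of m * p_(i) / i` (capped at 1).
#' @export
simes_combine <- function(p) {
  m <- length(p)
  ps <- sort(p)
  min(1, min(m * ps / seq_len(m)))
}

#' Run a comparator within the partitions of a tree
#'
#' Evaluates [fpc_test()] or [univariate_simes()] on every node of the same
#' testing hierarchy used by [test_within_partitions()], so the baselines can
#' be pushed through the identical TreeBH harness.
#'
#' @inheritParams test_within_partitions
#' @param method `"fpc"` or `"simes"`.
#' @return data.frame with the same columns as [test_within_partitions()]
#'   (Q is NA for comparators).
#' @export
comparator_within_partitions <- function(Y, C, Z, tree,
                                         method = c("fpc", "simes"),
                                         min_size = 10, include_root = TRUE,
                                         intermediate = FALSE) {
  method <- match.arg(method)
  fun <- if (method == "fpc") fpc_test else univariate_simes
  Z <- as.matrix(Z)
  n <- length(Y)
  cuts <- hierarchy_cuts(tree, intermediate = intermediate)
  if (!include_root) cuts <- setdiff(cuts, 1L)
  rows <- list()
  prev_labels <- NULL; prev_ids <- NULL
  for (lev in seq_along(cuts)) {
    k <- cuts[lev]
    labs <- if (k == 1L) rep(1L, n) else labels_at(tree, k)
    for (g in sort(unique(labs))) {
      idx <- which(labs == g)
      node_id <- paste0("k", k, ".g", g)
      parent_id <- if (lev == 1L) NA_character_
                   else prev_ids[[as.character(prev_labels[idx[1]])]]
      skipped <- length(idx) < max(min_size, 3L) && k > 1L
      pv <- NA_real_
      if (!skipped) {
        Csub <- if (is.null(C)) NULL else as.data.frame(C)[idx, , drop = FALSE]
        pv <- tryCatch(fun(Y[idx], Csub, Z[idx, , drop = FALSE]),
                       error = function(e) NA_real_)
        if (is.na(pv)) skipped <- TRUE
      }
      rows[[node_id]] <- data.frame(node_id = node_id, parent_id = parent_id,
                                    level = lev, label = g, n = length(idx),
                                    Q = NA_real_, p_value = pv,
                                    method = method, skipped = skipped,
                                    stringsAsFactors = FALSE)
    }
    prev_labels <- labs
    prev_ids <- stats::setNames(
      as.list(paste0("k", k, ".g", sort(unique(labs)))),
      as.character(sort(unique(labs))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
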