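#' Fit the null model g(Y) = C beta + eps
#'
#' Gaussian outcomes use least squares; binomial outcomes use the usual IRLS
#' maximum-likelihood fit of a logistic regression. The design matrix is an
#' intercept plus the dummy-expanded covariate columns; columns that are
#' constant within the fitted subset are dropped (a partition can make a
#' covariate constant, e.g. the factor that defined it), and remaining exact
#' collinearity is an error naming the offending columns.
#'
#' @param Y numeric outcome vector (0/1 for binomial).
#' @param C covariate data.frame/matrix, or `NULL` for intercept-only.
#' @param family `"gaussian"` or `"binomial"`.
#' @return A `tk_null_fit`: coefficients, fitted means `mu`, design matrix
#'   `X`, `sigma2` (gaussian), IRLS `weights` (binomial), `converged`.
#' @export
fit_null <- function(Y, C = NULL, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  Y <- as.numeric(Y)
  n <- length(Y)
  X <- null_design(C, n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("collinear design columns within this subset: ",
         paste(drop, collapse = ", "))
  }
  if (family == "gaussian") {
    fit <- stats::lm.fit(X, Y)
    df <- n - ncol(X)
    if (df < 1L) stop("no residual degrees of freedom")
    sigma2 <- sum(fit$residuals^2) / df
    if (sigma2 <= .Machine$double.eps * mean(Y^2 + 1))
      stop("residual variance is zero: outcome is exactly linear in C")
    structure(list(coefficients = fit$coefficients, mu = fit$fitted.values,
                   resid = fit$residuals, X = X, sigma2 = sigma2,
                   weights = NULL, family = family, converged = TRUE),
              class = "tk_null_fit")
  } else {
    if (!all(Y %in% c(0, 1))) stop("binomial outcome must be coded 0/1")
    fit <- stats::glm.fit(X, Y, family = stats::binomial())
    mu <- fit$fitted.values
    structure(list(coefficients = fit$coefficients, mu = mu,
                   resid = Y - mu, X = X, sigma2 = NULL,
                   weights = mu * (1 - mu),
                   family = family, converged = fit$converged),
              class = "tk_null_fit")
  }
}

null_design <- function(C, n) {
  if (is.null(C) || (!is.null(ncol(C)) && ncol(C) == 0L))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  df <- as.data.frame(C)
  # drop columns constant in this subset (common after partitioning)
  keep <- vapply(df, function(x) length(unique(x)) > 1L, logical(1))
  df <- df[, keep, drop = FALSE]
  if (ncol(df) == 0L)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  # re-level factors to the levels present in the subset
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- droplevels(df[[nm]])
  stats::model.matrix(~ ., data = df)
}

#' Kernel machine score test against a fitted null
#'
#' Variance-component score test of h(Z) in g(Y) = C beta + h(Z) + eps.
#' Gaussian: Q = r' K r / (2 sigma2^) with r the null residuals; under the
#' null Q follows the weighted sum of independent 1-df chi-squares whose
#' weights are the eigenvalues of P0 K P0 / 2, P0 the projection off the
#' design. Binomial: Q = (Y - mu^)' K (Y - mu^) / 2 with weights from the
#' IRLS-weighted projection. Tail probabilities come from numerical inversion
#' of the characteristic function (Davies/Imhof), with a Liu-type
#' moment-matching approximation as fallback; eigenvalues below
#' 1e-10 * max(lambda) are dropped for numerical stability of the inversion.
#'
#' @param null_fit a [fit_null()] result.
#' @param K `kernel_matrix` aligned to the fitted subjects.
#' @return A `tk_test_result` data.frame row: `n`, `Q`, `p_value`, `method`
#'   (`"davies"` or `"liu"`), `converged`.
#' @export
score_test <- function(null_fit, K) {
  K <- as.matrix(K)
  n <- length(null_fit$mu)
  if (!all(dim(K) == n)) stop("kernel matrix not aligned to fitted subjects")
  score_test_engine(null_fit, K)
}

score_test_engine <- function(null_fit, K) {
  X <- null_fit$X
  n <- nrow(X)
  if (null_fit$family == "gaussian") {
    r <- null_fit$resid
    Q <- drop(crossprod(r, K %*% r)) / (2 * null_fit$sigma2)
    H <- qr_projection(X)
    PKP <- K - H %*% K - K %*% H + H %*% (K %*% H)
    lam <- eigen((PKP + t(PKP)) / 4, symmetric = TRUE,
                 only.values = TRUE)$values
  } else {
    r <- null_fit$resid
    Q <- drop(crossprod(r, K %*% r)) / 2
    W <- null_fit$weights
    XtW <- t(X * W)
    P <- diag(W) - (X * W) %*% solve(XtW %*% X, XtW)
    Ph <- sym_sqrt(P)
    M <- Ph %*% K %*% Ph / 2
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  if (length(lam) == 0L) {
    warning("all kernel eigenvalues vanish under the null projection; p = 1")
    return(tk_result(n, Q, 1, "degenerate", null_fit$converged))
  }
  pv <- davies_pvalue(Q, lam)
  method <- "davies"
  if (is.na(pv)) {
    pv <- liu_pvalue(Q, lam)
    method <- "liu"
  }
  tk_result(n, Q, min(max(pv, 0), 1), method, null_fit$converged)
}

tk_result <- function(n, Q, p, method, converged) {
  structure(data.frame(n = n, Q = Q, p_value = p, method = method,
                       converged = converged, stringsAsFactors = FALSE),
            class = c("tk_test_result", "data.frame"))
}

qr_projection <- function(X) {
  Qm <- qr.Q(qr(X))
  tcrossprod(Qm)
}

sym_sqrt <- function(P) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tail probability of a weighted sum of chi-squares (Davies/Imhof inversion)
#'
#' P(sum_l lambda_l chi2_1 > q) by numerical inversion of the characteristic
#' function (Imhof's integral). Returns `NA` when the quadrature fails or
#' reports unusable accuracy, in which case callers fall back to
#' [liu_pvalue()].
#'
#' @param q observed statistic.
#' @param lambda positive eigenvalue weights.
#' @return p-value in [0, 1], or NA on quadrature failure.
#' @export
davies_pvalue <- function(q, lambda) {
  if (q <= 0) return(1)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    sin(theta) / (u * exp(lrho))
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, subdivisions = 2000L,
                     rel.tol = 1e-9, abs.tol = 1e-12, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(val) || !is.finite(val$value)) return(NA_real_)
  p <- 0.5 + val$value / pi
  if (p < -1e-6 || p > 1 + 1e-6) return(NA_real_)
  # clip tiny overshoot from the oscillatory quadrature
  min(max(p, 1e-14), 1)
}

#' Liu-type moment-matching tail probability
#'
#' Four-moment match of the weighted chi-square mixture to a noncentral
#' chi-square (Liu-Tang-Zhang flavour); used as the fallback when the exact
#' inversion fails.
#'
#' @inheritParams davies_pvalue
#' @return p-value in [0, 1].
#' @export
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    delta <- 0
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + delta; sigmaX <- sqrt(2) * a
  tstar <- (q - muQ) / sigmaQ
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = delta, lower.tail = FALSE)
}

#' Kernel association tests within the partitions of a tree
#'
#' Runs the score test on every node of the testing hierarchy: the root
#' (all subjects) and each cluster of the selected cut (plus intermediate
#' cuts when requested). Kernels are computed on each partition's own rows of
#' Z, so the Gaussian median heuristic is re-estimated within each partition;
#' each null model is likewise refit within its partition.
#'
#' @param Y outcome vector, or an [outcome()] object.
#' @param C covariate table (or `NULL`).
#' @param Z omics matrix.
#' @param tree a `tk_partition_tree` with `selected_k` set.
#' @param spec a [kernel_spec()].
#' @param family outcome family (ignored when `Y` is an [outcome()]).
#' @param min_size partitions smaller than this are skipped with a warning
#'   recorded in the output (small partitions destabilize kernel tests).
#' @param include_root test the all-subjects root node.
#' @param include_leaves test the partitions of the selected cut; turning
#'   this off leaves only the global root test (no partitioning).
#' @param intermediate include intermediate cuts 2..selected_k as extra
#'   hierarchy levels.
#' @param graph optional [pathway_graph()] for graph-smoothed kernels.
#' @return data.frame with one row per node: `node_id`, `parent_id`, `level`,
#'   `label`, `n`, `Q`, `p_value`, `method`, `skipped`.
#' @export
test_within_partitions <- function(Y, C, Z, tree, spec = kernel_spec("linear"),
                                   family = "gaussian", min_size = 10,
                                   include_root = TRUE, include_leaves = TRUE,
                                   intermediate = FALSE, graph = NULL) {
  if (inherits(Y, "outcome")) { family <- Y$family; Y <- Y$values }
  Z <- as.matrix(Z)
  n <- length(Y)
  if (nrow(Z) != n) stop("Y and Z disagree on n")
  cuts <- hierarchy_cuts(tree, intermediate = intermediate)
  if (!include_root) cuts <- setdiff(cuts, 1L)
  if (!include_leaves) cuts <- 1L
  if (!length(cuts)) stop("nothing to test: root and leaves both excluded")
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
      if (length(idx) < max(min_size, 3L) && k > 1L) {
        warning("partition ", node_id, " has ", length(idx),
                " subjects (< ", min_size, "); skipped")
        rows[[node_id]] <- data.frame(node_id = node_id, parent_id = parent_id,
                                      level = lev, label = g, n = length(idx),
                                      Q = NA_real_, p_value = NA_real_,
                                      method = NA_character_, skipped = TRUE,
                                      stringsAsFactors = FALSE)
        next
      }
      Csub <- if (is.null(C)) NULL else as.data.frame(C)[idx, , drop = FALSE]
      nf <- fit_null_with_resid(Y[idx], Csub, family)
      Ksub <- kernel_matrix(Z[idx, , drop = FALSE], spec, graph = graph)
      res <- score_test_engine(nf, Ksub)
      rows[[node_id]] <- data.frame(node_id = node_id, parent_id = parent_id,
                                    level = lev, label = g, n = res$n,
                                    Q = res$Q, p_value = res$p_value,
                                    method = res$method, skipped = FALSE,
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

fit_null_with_resid <- function(Y, C, family) fit_null(Y, C, family)
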