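#' Low-dimensional embedding of clinical covariates
#'
#' Continuous-only tables are embedded with principal components; tables with
#' at least one categorical column use factor analysis of mixed data (FAMD).
#' In both cases the embedding is the SVD of a standardized design matrix and
#' the subject scores are the left singular vectors scaled by the singular
#' values, so Euclidean distances between score rows reflect the covariate
#' geometry that the downstream clustering partitions.
#'
#' Standardization uses the population (1/n) variance throughout, and the sign
#' of each component is fixed by forcing its largest-magnitude loading
#' positive, so repeated runs are bit-identical.
#'
#' @param clinical a [clinical_table()] (or plain data.frame).
#' @param k number of components to keep. Capped at the available rank with a
#'   message, since e.g. four standardized covariates can carry at most four
#'   components.
#' @return An object of class `tk_embedding` with elements `scores` (n x k),
#'   `explained_inertia` (length-k fractions, non-increasing), `k`, `method`
#'   (`"pca"` or `"famd"`), `loadings`, and `subject_id`.
#' @export
embed_clinical <- function(clinical, k = 5) {
  types <- attr(clinical, "types")
  if (is.null(types))
    clinical <- clinical_table(as.data.frame(clinical))
  types <- attr(clinical, "types")
  if (all(types == "continuous")) {
    embed_continuous(clinical, k)
  } else {
    embed_mixed(clinical, k)
  }
}

#' Principal-component embedding of continuous covariates
#'
#' @param C numeric data (clinical_table, data.frame, or matrix), all columns
#'   continuous.
#' @param k number of components.
#' @return A `tk_embedding`; see [embed_clinical()].
#' @export
embed_continuous <- function(C, k = 5) {
  ids <- attr(C, "subject_id")
  X <- as.matrix(as.data.frame(C))
  if (!is.numeric(X)) stop("embed_continuous requires all-numeric columns")
  n <- nrow(X)
  sds <- apply(X, 2, pop_sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X, center = TRUE, scale = sds)
  embedding_from_svd(Xs, k, method = "pca", subject_id = ids)
}

#' FAMD embedding of mixed continuous/categorical covariates
#'
#' Continuous columns are z-standardized (population variance); each
#' categorical column is expanded to 0/1 indicators, each indicator divided by
#' the square root of its category proportion and then centered. The combined
#' matrix is decomposed by SVD and the scores are the left singular vectors
#' scaled by the singular values. With no categorical columns this reduces
#' exactly to the principal-component embedding.
#'
#' @param C a [clinical_table()] or data.frame with at least one factor column.
#' @param k number of components.
#' @return A `tk_embedding`; see [embed_clinical()].
#' @export
embed_mixed <- function(C, k = 5) {
  ids <- attr(C, "subject_id")
  df <- as.data.frame(C)
  types <- attr(C, "types")
  if (is.null(types))
    types <- ifelse(vapply(df, function(x) is.factor(x) || is.character(x),
                           logical(1)), "categorical", "continuous")
  n <- nrow(df)
  blocks <- list()
  for (nm in names(df)) {
    if (types[[nm]] == "continuous") {
      x <- df[[nm]]
      s <- pop_sd(x)
      if (s == 0) stop("zero-variance column(s): ", nm)
      blocks[[nm]] <- matrix((x - mean(x)) / s, ncol = 1,
                             dimnames = list(NULL, nm))
    } else {
      f <- factor(df[[nm]])
      tab <- table(f)
      if (any(tab == 1L))
        warning("categorical column '", nm, "' has a level observed once; ",
                "its FAMD weight is unstable")
      ind <- stats::model.matrix(~ f - 1)
      colnames(ind) <- paste(nm, levels(f), sep = ".")
      prop <- colMeans(ind)
      indw <- sweep(ind, 2, sqrt(prop), "/")
      blocks[[nm]] <- scale(indw, center = TRUE, scale = FALSE)
    }
  }
  X <- do.call(cbind, blocks)
  embedding_from_svd(X, k, method = "famd", subject_id = ids)
}

embedding_from_svd <- function(X, k, method, subject_id = NULL) {
  n <- nrow(X)
  sv <- svd(X)
  tol <- 1e-10 * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r < 1L) stop("design matrix has rank 0")
  if (k > r) {
    message("k = ", k, " exceeds the available rank ", r, "; using k = ", r)
    k <- r
  }
  if (k < 1L) stop("k must be at least 1")
  # deterministic sign: largest-|.| loading of each component made positive
  for (j in seq_len(k)) {
    lj <- sv$v[, j]
    s <- sign(lj[which.max(abs(lj))])
    if (s < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("dim", seq_len(k))
  inertia <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores,
                 explained_inertia = inertia[seq_len(k)],
                 k = k, method = method,
                 loadings = sv$v[, seq_len(k), drop = FALSE],
                 subject_id = if (is.null(subject_id))
                   as.character(seq_len(n)) else subject_id),
            class = "tk_embedding")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.tk_embedding <- function(x, ...) {
  cat("tk_embedding (", x$method, "): ", nrow(x$scores), " subjects, k = ",
      x$k, "\nexplained inertia: ",
      paste(sprintf("%.3f", x$explained_inertia), collapse = " "), "\n",
      sep = "")
  invisible(x)
}
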