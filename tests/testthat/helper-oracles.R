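# Independent oracles used across the suite. These re-derive expected values
# by brute force and must stay independent of the package internals.

# step-up BH selection, evaluated literally from the definition
oracle_bh_select <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  sel <- logical(m)
  if (length(k)) sel[o[seq_len(max(k))]] <- TRUE
  sel
}

# Ward.D2 agglomeration via the Lance-Williams update on squared distances
oracle_ward_heights <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.matrix(dist(X))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    dd <- d
    dd[!active, ] <- Inf; dd[, !active] <- Inf
    diag(dd) <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    heights[s] <- d[i, j]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2 <- ((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
               nk * d[i, j]^2) / (ni + nj + nk)
      d[i, k] <- d[k, i] <- sqrt(max(d2, 0))
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
  }
  sort(heights)
}

# FAMD construction written out long-hand: z-standardize continuous columns
# (population variance), expand factors to indicators, divide each indicator
# by sqrt of its category proportion, center, then SVD
oracle_famd_scores <- function(df, k) {
  n <- nrow(df)
  cols <- list()
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    } else {
      f <- factor(x)
      for (lv in levels(f)) {
        ind <- as.numeric(f == lv)
        w <- ind / sqrt(mean(ind))
        cols[[paste(nm, lv)]] <- w - mean(w)
      }
    }
  }
  X <- do.call(cbind, cols)
  sv <- svd(X)
  sc <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k)
  # align signs by the largest-|.| loading convention
  for (j in 1:k) {
    lj <- sv$v[, j]
    if (lj[which.max(abs(lj))] < 0) sc[, j] <- -sc[, j]
  }
  sc
}

# naive double-loop kernels
oracle_loop_kernel <- function(Z, fun) {
  n <- nrow(Z)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- fun(Z[i, ], Z[j, ])
  K
}

# within-cluster inertia straight from the definition
oracle_inertia <- function(X, labels) {
  tot <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    tot <- tot + sum(scale(Xg, scale = FALSE)^2)
  }
  tot
}

# permutation p-value for the gaussian kernel score test: permute Y,
# refit the null, recompute the statistic
oracle_permutation_p <- function(Y, C, K, B = 10000) {
  stat <- function(y) {
    X <- cbind(1, as.matrix(C))
    f <- lm.fit(X, y)
    s2 <- sum(f$residuals^2) / (length(y) - ncol(X))
    drop(crossprod(f$residuals, K %*% f$residuals)) / (2 * s2)
  }
  q0 <- stat(Y)
  hits <- 0L
  for (b in seq_len(B)) {
    if (stat(sample(Y)) >= q0) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

make_blobs <- function(n_per, centers, sd = 0.1) {
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      rep(centers[g, ], each = n_per)))
  labels <- rep(seq_len(nrow(centers)), each = n_per)
  list(X = X, labels = labels)
}
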