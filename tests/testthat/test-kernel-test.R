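test_that("null fit recovers closed-form least squares", {
  set.seed(51)
  Y <- rnorm(12)
  nf <- fit_null(Y, NULL, "gaussian")
  expect_equal(unname(nf$coefficients), mean(Y))
  expect_equal(nf$sigma2, var(Y))
  C <- data.frame(a = rnorm(10), b = runif(10))
  Y2 <- 1 + 0.5 * C$a - 0.2 * C$b + rnorm(10)
  nf2 <- fit_null(Y2, C, "gaussian")
  X <- cbind(1, C$a, C$b)
  beta_o <- solve(crossprod(X), crossprod(X, Y2))   # normal equations
  expect_equal(unname(nf2$coefficients), drop(beta_o), tolerance = 1e-10)
  # exactly linear outcome: degenerate residual variance must error
  expect_error(fit_null(2 + 3 * C$a, C["a"], "gaussian"), "zero")
  # collinear design is reported by name
  C3 <- data.frame(a = C$a, b = 2 * C$a + 1)
  expect_error(fit_null(Y2, C3, "gaussian"), "collinear")
})

test_that("mixture-of-chi-square tail matches exact chi-square cases", {
  expect_lt(abs(davies_pvalue(3.84, 1) - pchisq(3.84, 1, lower.tail = FALSE)),
            5e-4)
  # 2*chi2_2: equal weights collapse to a scaled chi-square
  expect_lt(abs(davies_pvalue(7, c(2, 2)) - pchisq(3.5, 2, lower.tail = FALSE)),
            5e-4)
  expect_equal(davies_pvalue(0, c(1, 2)), 1)
  # Liu fallback is a sane approximation in the same cases
  expect_equal(liu_pvalue(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_lt(abs(liu_pvalue(7, c(2, 2)) - pchisq(3.5, 2, lower.tail = FALSE)),
            0.01)
})

test_that("a zero kernel yields Q = 0 and p = 1", {
  set.seed(52)
  nf <- fit_null(rnorm(15), data.frame(a = rnorm(15)), "gaussian")
  expect_warning(res <- score_test(nf, matrix(0, 15, 15)), "vanish")
  expect_equal(res$Q, 0)
  expect_equal(res$p_value, 1)
})

test_that("score test agrees with a 10,000-draw permutation oracle", {
  set.seed(53)
  n <- 30
  C <- data.frame(c1 = rnorm(n))
  Z <- matrix(rnorm(n), n, 1)
  Y <- 0.3 * C$c1 + 0.35 * Z[, 1] + rnorm(n)
  nf <- fit_null(Y, C, "gaussian")
  res <- score_test(nf, linear_kernel(Z))
  pp <- oracle_permutation_p(Y, C, unclass(linear_kernel(Z)), B = 10000)
  mc_se <- sqrt(pp * (1 - pp) / 10000)
  expect_lt(abs(res$p_value - pp), 3 * mc_se + 0.005)
})

test_that("the gaussian score test is calibrated under the null", {
  set.seed(54)
  n <- 100
  rej <- replicate(2000, {
    C <- data.frame(a = rnorm(n), b = runif(n))
    Z <- matrix(rnorm(n * 5), n, 5)
    Y <- 1 + 0.5 * C$a + rnorm(n)
    nf <- fit_null(Y, C, "gaussian")
    score_test(nf, linear_kernel(Z))$p_value <= 0.05
  })
  tol <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(rej) - 0.05), tol)
})

new_k <- function(M) structure(M, class = c("kernel_matrix", "matrix", "array"))

test_that("p-values are invariant to outcome shifts and kernel scaling", {
  set.seed(55)
  n <- 40
  C <- data.frame(a = rnorm(n))
  Z <- matrix(rnorm(n * 4), n, 4)
  Y <- rnorm(n)
  K <- linear_kernel(Z)
  p1 <- score_test(fit_null(Y, C), K)$p_value
  p2 <- score_test(fit_null(Y + 100, C), K)$p_value
  p3 <- score_test(fit_null(Y, C), new_k(unclass(K) * 7.3))$p_value
  expect_equal(p1, p2, tolerance = 1e-8)
  expect_equal(p1, p3, tolerance = 1e-8)
  # PSD kernel implies a nonnegative statistic
  expect_gte(score_test(fit_null(Y, C), K)$Q, 0)
})

test_that("the binomial branch agrees with a permutation oracle", {
  set.seed(56)
  n <- 60
  C <- data.frame(a = rnorm(n))
  Z <- matrix(rnorm(n * 3), n, 3)
  eta <- -0.2 + 0.4 * C$a + 0.25 * rowSums(Z)
  Y <- rbinom(n, 1, plogis(eta))
  nf <- fit_null(Y, C, "binomial")
  K <- linear_kernel(Z)
  res <- score_test(nf, K)
  B <- 4000
  stat <- function(y) {
    f <- suppressWarnings(glm.fit(cbind(1, C$a), y,
                                  family = binomial()))
    r <- y - f$fitted.values
    drop(crossprod(r, unclass(K) %*% r)) / 2
  }
  q0 <- stat(Y)
  perm <- replicate(B, stat(sample(Y)) >= q0)
  pp <- (sum(perm) + 1) / (B + 1)
  expect_lt(abs(res$p_value - pp), 3 * sqrt(pp * (1 - pp) / B) + 0.02)
})

test_that("one global partition reduces to a single score test", {
  set.seed(57)
  n <- 40
  C <- data.frame(a = rnorm(n))
  Z <- matrix(rnorm(n * 5), n, 5)
  Y <- rnorm(n)
  tree <- select_k(hierarchical_cluster(matrix(rnorm(2 * n), n, 2)), 4)
  tab <- suppressWarnings(
    test_within_partitions(Y, C, Z, tree, min_size = 3))
  direct <- score_test(fit_null(Y, C), linear_kernel(Z))
  expect_equal(tab$p_value[tab$level == 1], direct$p_value, tolerance = 1e-10)
  expect_equal(tab$Q[tab$level == 1], direct$Q, tolerance = 1e-10)
})

test_that("partitions below the size guard are skipped with a warning", {
  set.seed(58)
  X <- rbind(matrix(rnorm(8), 4, 2) + 10, matrix(rnorm(60), 30, 2))
  tree <- select_k(hierarchical_cluster(X), 4)
  Y <- rnorm(34)
  Z <- matrix(rnorm(34 * 3), 34, 3)
  expect_warning(
    tab <- test_within_partitions(Y, NULL, Z, tree, min_size = 10),
    "skipped")
  expect_true(any(tab$skipped))
  expect_true(all(is.na(tab$p_value[tab$skipped])))
})

test_that("an active partition shows smaller p-values than an idle one", {
  set.seed(59)
  cfg <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0.5, 0),
                         k_embed = 5)
  p_active <- p_idle <- numeric(40)
  for (i in 1:40) {
    dat <- simulate_study(cfg)
    emb <- suppressMessages(embed_clinical(dat$clinical, 5))
    tree <- select_k(hierarchical_cluster(emb), 6)
    tab <- suppressWarnings(
      test_within_partitions(dat$Y, dat$clinical, dat$omics, tree))
    leaf <- tab[tab$level == 2 & !tab$skipped, ]
    mp <- match_clusters(dat$true_labels,
                         labels_at(tree, tree$selected_k))
    pa <- leaf$p_value[leaf$label == as.integer(mp["1"])]
    pi_ <- leaf$p_value[leaf$label == as.integer(mp["2"])]
    p_active[i] <- if (length(pa)) pa else NA
    p_idle[i] <- if (length(pi_)) pi_ else NA
  }
  expect_lt(median(p_active, na.rm = TRUE), median(p_idle, na.rm = TRUE))
})

test_that("permuting the outcome within partitions removes the association", {
  set.seed(60)
  cfg <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0.5, 0),
                         k_embed = 5)
  rej <- replicate(120, {
    dat <- simulate_study(cfg)
    emb <- suppressMessages(embed_clinical(dat$clinical, 5))
    tree <- select_k(hierarchical_cluster(emb), 6)
    labs <- labels_at(tree, tree$selected_k)
    Yp <- dat$Y
    for (g in unique(labs)) {
      idx <- which(labs == g)
      # break the Y-Z link but keep the Y-C link within the partition
      nf <- fit_null(dat$Y[idx], as.data.frame(dat$clinical)[idx, ],
                     "gaussian")
      Yp[idx] <- nf$mu + sample(nf$resid)
    }
    tab <- suppressWarnings(
      test_within_partitions(Yp, dat$clinical, dat$omics, tree))
    any(tab$p_value[tab$level == 2] <= 0.05, na.rm = TRUE)
  })
  # two leaf tests at alpha = .05 each: family rate ~ <= 0.1 under the null
  expect_lt(mean(rej), 0.1 + 3 * sqrt(0.1 * 0.9 / 120))
})
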