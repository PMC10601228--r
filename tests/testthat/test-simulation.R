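test_that("MVN clinical blocks have the stated sizes and mean shifts", {
  set.seed(91)
  cfg2 <- scenario_config("mvn", n_partitions = 2, m = 15)
  cl <- simulate_clinical(cfg2)
  expect_equal(as.integer(table(cl$true_labels)), c(100L, 100L))
  X <- as.matrix(as.data.frame(cl$clinical))
  expect_lt(max(abs(colMeans(X[cl$true_labels == 1, ]) - 0)), 0.5)
  expect_lt(max(abs(colMeans(X[cl$true_labels == 2, ]) - 2)), 0.5)

  cfg4 <- scenario_config("mvn", n_partitions = 4, m = 15)
  expect_equal(cfg4$partition_sizes, rep(50L, 4))
  cfg3 <- scenario_config("mvn", n_partitions = 3, m = 15)
  expect_equal(cfg3$partition_sizes, c(66L, 66L, 68L))
  cl4 <- simulate_clinical(cfg4)
  X4 <- as.matrix(as.data.frame(cl4$clinical))
  expect_lt(max(abs(colMeans(X4[cl4$true_labels == 4, ]) - 8)), 0.7)
})

test_that("categorical scenarios carry the stated uniforms and factors", {
  set.seed(92)
  cfg <- scenario_config("categorical", n_partitions = 3, m = 15)
  cl <- simulate_clinical(cfg)
  df <- as.data.frame(cl$clinical)
  expect_true(all(df$u1 >= -0.15 & df$u1 <= 0.15))
  expect_true(all(df$u2 >= -1 & df$u2 <= 1))
  expect_true(all(df$u3 >= 0 & df$u3 <= 4))
  expect_equal(nlevels(df$grp), 3)
  cfg2f <- scenario_config("two_factor", m = 15)
  expect_equal(cfg2f$n_partitions, 4L)
  cl2 <- simulate_clinical(cfg2f)
  df2 <- as.data.frame(cl2$clinical)
  # the partitioning covariate is the 4-level interaction of two 2-level
  # factors; each level maps to exactly one true partition
  expect_equal(nlevels(df2$grp12), 4)
  expect_true(all(grepl("^[ab]\\.[xy]$", levels(df2$grp12))))
  expect_equal(length(unique(tapply(cl2$true_labels, df2$grp12,
                                    function(x) unique(x)))), 4)
})

test_that("graph-structured omics covariance follows (L + eps I)^-1", {
  set.seed(93)
  # edgeless graph: identity covariance
  om0 <- simulate_omics(50, 5, p_edge = 0)
  expect_equal(om0$Sigma, diag(5), tolerance = 1e-12)
  # 2-node single edge: closed-form correlation 1/1.1
  om2 <- simulate_omics(5000, 2, p_edge = 1)
  expect_equal(om2$Sigma[1, 2], 1 / 1.1, tolerance = 1e-12)
  expect_equal(unname(diag(om2$Sigma)), c(1, 1), tolerance = 1e-12)
  expect_equal(cor(unclass(om2$omics))[1, 2], 1 / 1.1, tolerance = 0.05)
  # connected features are positively correlated in the sample
  set.seed(93)
  om <- simulate_omics(4000, 10, p_edge = 0.3)
  if (nrow(om$graph$edges)) {
    i <- match(om$graph$edges[1, 1], colnames(om$omics))
    j <- match(om$graph$edges[1, 2], colnames(om$omics))
    expect_gt(cor(unclass(om$omics))[i, j], 0.1)
  }
})

test_that("the outcome model adds the kernel effect only in active groups", {
  set.seed(94)
  cfg <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0.5, 0))
  cl <- simulate_clinical(cfg)
  om <- simulate_omics(200, 15, p_edge = 2 / 15)
  # sigma = 0 and b = 0: Y deterministic in C
  cfg0 <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0, 0))
  cfg0$sigma <- 0
  Y0 <- simulate_outcome(cl$clinical, om$omics, cl$true_labels, cfg0)
  X <- cbind(1, as.matrix(as.data.frame(cl$clinical)))
  expect_equal(Y0, drop(X %*% cfg0$beta[1:5]), tolerance = 1e-12)
  # variance decomposition: active-group conditional variance is inflated by
  # b^2 * var(sum_j Z_j) = b^2 * sum(Sigma)
  draws <- replicate(3000, {
    omi <- matrix(rnorm(15), 1, 15) %*% chol(om$Sigma)
    0.5 * sum(omi) + rnorm(1, 0, cfg$sigma)
  })
  expect_equal(var(drop(draws)), 0.25 * sum(om$Sigma) + cfg$sigma^2,
               tolerance = 0.1)
})

test_that("generators and the experiment driver are seed-deterministic", {
  cfg <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0.5, 0))
  set.seed(95); d1 <- simulate_study(cfg)
  set.seed(95); d2 <- simulate_study(cfg)
  expect_identical(d1$Y, d2$Y)
  expect_identical(unclass(d1$omics), unclass(d2$omics))
  p1 <- run_experiment(cfg, n_reps = 5, methods = "treekernel", seed = 7)
  p2 <- run_experiment(cfg, n_reps = 5, methods = "treekernel", seed = 7)
  expect_identical(p1$estimate, p2$estimate)
})

test_that("power is ordered: b = 0.5 above b = 0.3 above the null size", {
  cfg5 <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0.5, 0))
  cfg3 <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0.3, 0))
  cfg0 <- scenario_config("mvn", n_partitions = 2, m = 15, b = c(0, 0))
  pow5 <- run_experiment(cfg5, 120, "treekernel", seed = 96)
  pow3 <- run_experiment(cfg3, 120, "treekernel", seed = 97)
  pow0 <- run_experiment(cfg0, 120, "treekernel", seed = 98)
  g1 <- function(pt) pt$estimate[pt$group == "group1"]
  expect_gte(g1(pow5), g1(pow3))
  expect_gt(g1(pow3), g1(pow0))
  expect_lt(g1(pow0), 0.15)
})
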