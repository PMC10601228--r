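test_that("linear kernel is the gram matrix of dot products", {
  Z <- rbind(c(1, 2), c(3, 4))
  K <- linear_kernel(Z)
  expect_equal(K[1, 2], 11)
  expect_equal(unclass(linear_kernel(diag(2))), diag(2), ignore_attr = TRUE)
  set.seed(41)
  Z <- matrix(rnorm(15), 5, 3)
  Ko <- oracle_loop_kernel(Z, function(a, b) sum(a * b))
  expect_equal(unclass(linear_kernel(Z)), Ko, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("polynomial kernel matches its closed form and reduces to linear", {
  set.seed(42)
  Z <- matrix(rnorm(8), 4, 2)
  expect_equal(unclass(polynomial_kernel(Z, rho = 0, d = 1)),
               unclass(linear_kernel(Z)), tolerance = 1e-12)
  expect_equal(polynomial_kernel(rbind(c(1, 0), c(1, 0)), rho = 1, d = 2)[1, 2],
               4)
  Ko <- oracle_loop_kernel(Z, function(a, b) (sum(a * b) + 0.5)^3)
  expect_equal(unclass(polynomial_kernel(Z, rho = 0.5, d = 3)), Ko,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(polynomial_kernel(Z, rho = -1, d = 2), "indefinite")
})

test_that("gaussian kernel has unit diagonal, saturates as rho grows, and
           matches a loop oracle with the median heuristic", {
  Z <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 1))
  K <- gaussian_kernel(Z, rho = "median")
  expect_equal(diag(K), rep(1, 4), ignore_attr = TRUE)
  # median of the 6 pairwise unsquared distances, computed by hand
  dists <- as.numeric(dist(Z))
  rho <- median(dists)
  Ko <- oracle_loop_kernel(Z, function(a, b) exp(-sum((a - b)^2) / rho))
  expect_equal(unclass(K), Ko, tolerance = 1e-12, ignore_attr = TRUE)
  # large rho: all similarities approach 1
  Kb <- gaussian_kernel(Z, rho = 1e8)
  expect_true(all(Kb > 0.999))
  # squared-median convention switch
  K2 <- gaussian_kernel(Z, rho = "median", squared_median = TRUE)
  Ko2 <- oracle_loop_kernel(Z, function(a, b)
    exp(-sum((a - b)^2) / median(dists^2)))
  expect_equal(unclass(K2), Ko2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(gaussian_kernel(rbind(c(1, 1), c(1, 1))), "identical rows")
})

test_that("kernel matrices are symmetric PSD and permutation-equivariant", {
  set.seed(43)
  Z <- matrix(rnorm(60), 12, 5)
  for (spec in list(kernel_spec("linear"),
                    kernel_spec("polynomial", degree = 2, offset = 1),
                    kernel_spec("gaussian"))) {
    K <- kernel_matrix(Z, spec)
    expect_lt(max(abs(K - t(K))), 1e-10)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
    if (spec$name == "gaussian") {
      expect_true(all(K > 0 & K <= 1 + 1e-12))
    }
    p <- sample(12)
    Kp <- kernel_matrix(Z[p, ], spec)
    expect_equal(unclass(Kp), unclass(K)[p, p], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("graph smoothing solves (I + tau L) and degenerates correctly", {
  set.seed(44)
  Z <- matrix(rnorm(12), 4, 3)
  colnames(Z) <- c("a", "b", "c")
  path <- pathway_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(graph_smoothed_input(Z, path, tau = 0), Z)
  edgeless <- pathway_graph(c("a", "b", "c"))
  expect_equal(graph_smoothed_input(Z, edgeless, tau = 2), Z)
  # 3-node path, tau = 1: direct dense solve as the oracle
  L <- normalized_laplacian(path)
  Zt <- graph_smoothed_input(Z, path, tau = 1)
  Zo <- Z %*% solve(diag(3) + L)
  expect_equal(Zt, Zo, tolerance = 1e-10, ignore_attr = TRUE)
  # normalized Laplacian of the path graph, by hand
  Lh <- rbind(c(1, -1 / sqrt(2), 0),
              c(-1 / sqrt(2), 1, -1 / sqrt(2)),
              c(0, -1 / sqrt(2), 1))
  expect_equal(unname(L), Lh, tolerance = 1e-12)
  # isolated node: zero Laplacian row, feature passes through
  iso <- pathway_graph(c("a", "b", "c"), rbind(c("a", "b")))
  Zi <- graph_smoothed_input(Z, iso, tau = 5)
  expect_equal(Zi[, "c"], Z[, "c"])
})
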