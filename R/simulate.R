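#' Simulation scenario configuration
#'
#' Encodes the synthetic study conditions: 200 subjects split into 2, 3 or 4
#' clinical partitions (100/100, 66/66/68, or 4 x 50), a clinical covariate
#' scenario, an omics pathway of m features with graph-structured correlation,
#' and the outcome model
#' `Y_i = x_i' beta + b_{p(i)} * sum_j Z_ij + eps_i`, `eps ~ N(0, sigma^2)`
#' with `beta = (1, 0.05, -0.26, 0.1, -0.1, 0.26, -0.02)` (applied to the
#' intercept + design columns, truncated to the first 1 + q entries) and
#' `sigma = 1.3688`. Clinical scenarios:
#' \describe{
#'   \item{mvn}{four continuous covariates, MVN(mu_g, I) per partition with
#'     mu_g a constant vector of 0, 2, 4 or 8;}
#'   \item{categorical}{three uniform covariates with ranges (-0.15, 0.15),
#'     (-1, 1), (0, 4) plus one partitioning factor with 2, 3 or 4 levels;}
#'   \item{two_factor}{the three uniforms plus one partitioning factor formed
#'     as the interaction of two 2-level factors, so its four levels define
#'     the partitions (4-partition only).}
#' }
#'
#' @param scenario `"mvn"`, `"categorical"` or `"two_factor"`.
#' @param n_partitions 2, 3 or 4 (`two_factor` forces 4).
#' @param m omics feature count (15, 30 or 45 in the study grid).
#' @param b per-partition kernel effect sizes, recycled/padded to
#'   `n_partitions`; e.g. `c(0.5, 0)` for one active group, `rep(0, 4)` for a
#'   null scenario.
#' @param k_embed embedding components used by the driver (3 or 5; capped at
#'   the embedding rank).
#' @param n_total total sample size.
#' @param beta outcome regression coefficients.
#' @param sigma residual standard deviation.
#' @param p_edge edge probability of the Erdos-Renyi pathway graph
#'   (default 2/m, giving mean degree ~2).
#' @param eps_reg ridge added to the graph Laplacian before inversion.
#' @return A `scenario_config` list including `partition_sizes`.
#' @export
scenario_config <- function(scenario = c("mvn", "categorical", "two_factor"),
                            n_partitions = 2, m = 15, b = c(0.5, 0),
                            k_embed = 5, n_total = 200,
                            beta = c(1, 0.05, -0.26, 0.1, -0.1, 0.26, -0.02),
                            sigma = 1.3688, p_edge = NULL, eps_reg = 0.1) {
  scenario <- match.arg(scenario)
  if (scenario == "two_factor") n_partitions <- 4L
  if (!n_partitions %in% 2:4) stop("n_partitions must be 2, 3 or 4")
  sizes <- switch(as.character(n_partitions),
                  "2" = c(100L, 100L),
                  "3" = c(66L, 66L, 68L),
                  "4" = rep(50L, 4L))
  if (n_total != 200L) {
    sizes <- rep(n_total %/% n_partitions, n_partitions)
    sizes[n_partitions] <- n_total - sum(sizes[-n_partitions])
  }
  b <- rep_len(as.numeric(b), n_partitions)
  if (is.null(p_edge)) p_edge <- 2 / m
  structure(list(scenario = scenario, n_partitions = as.integer(n_partitions),
                 partition_sizes = sizes, n_total = sum(sizes), m = as.integer(m),
                 b = b, k_embed = k_embed, beta = beta, sigma = sigma,
                 p_edge = p_edge, eps_reg = eps_reg),
            class = "scenario_config")
}

#' Simulate the clinical covariate table of a scenario
#'
#' @param config a [scenario_config()].
#' @return List with `clinical` (a [clinical_table()]) and `true_labels`
#'   (integer partition memberships).
#' @export
simulate_clinical <- function(config) {
  sizes <- config$partition_sizes
  n <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  if (config$scenario == "mvn") {
    mus <- c(0, 2, 4, 8)[seq_along(sizes)]
    X <- matrix(stats::rnorm(n * 4), n, 4) + mus[labels]
    colnames(X) <- paste0("c", 1:4)
    clin <- clinical_table(as.data.frame(X))
  } else {
    U <- cbind(u1 = stats::runif(n, -0.15, 0.15),
               u2 = stats::runif(n, -1, 1),
               u3 = stats::runif(n, 0, 4))
    df <- as.data.frame(U)
    if (config$scenario == "categorical") {
      df$grp <- factor(paste0("g", labels))
    } else {
      # the partitioning covariate is the interaction of two 2-level
      # factors: one 4-level factor labeled by the factor combinations
      f1 <- ifelse(labels %in% c(1, 2), "a", "b")
      f2 <- ifelse(labels %in% c(1, 3), "x", "y")
      df$grp12 <- factor(paste(f1, f2, sep = "."))
    }
    clin <- clinical_table(df)
  }
  list(clinical = clin, true_labels = labels)
}

#' Simulate a graph-structured omics matrix
#'
#' An Erdos-Renyi graph G(m, p_edge) is drawn, and rows of Z are i.i.d.
#' MVN(0, Sigma) with `Sigma` proportional to `(L + eps I)^-1` (L the graph
#' Laplacian), rescaled to unit diagonal, so features joined by an edge are
#' positively correlated — mimicking co-regulated metabolites in a pathway.
#'
#' @param n subject count.
#' @param m feature count.
#' @param p_edge edge probability (default 2/m).
#' @param eps_reg Laplacian ridge (default 0.1).
#' @return List with `omics` (an [omics_matrix()]), `graph`
#'   (a [pathway_graph()]), and `Sigma`.
#' @export
simulate_omics <- function(n, m, p_edge = 2 / m, eps_reg = 0.1) {
  if (m < 2L) stop("m must be >= 2")
  g <- igraph::sample_gnp(m, p_edge)
  el <- igraph::as_edgelist(g)
  feats <- paste0("f", seq_len(m))
  A <- matrix(0, m, m)
  if (nrow(el)) {
    A[el] <- 1
    A[el[, 2:1, drop = FALSE]] <- 1
  }
  L <- diag(rowSums(A)) - A
  Sig0 <- solve(L + eps_reg * diag(m))
  Dinv <- 1 / sqrt(diag(Sig0))
  Sigma <- Dinv * t(Dinv * Sig0)          # unit-diagonal rescale
  R <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * m), n, m) %*% R
  colnames(Z) <- feats
  edges <- if (nrow(el)) cbind(feats[el[, 1]], feats[el[, 2]]) else NULL
  list(omics = omics_matrix(Z), graph = pathway_graph(feats, edges),
       Sigma = Sigma)
}

#' Simulate the outcome of a scenario
#'
#' `Y_i = x_i' beta + b_{p(i)} * sum_j Z_ij + eps_i` with
#' `eps_i ~ N(0, sigma^2)`; `x_i` is the intercept + dummy-expanded covariate
#' row and `beta` is truncated to the first `1 + q` entries (it is a 7-vector
#' by construction, matching the widest design in the study grid).
#'
#' @param clinical a [clinical_table()].
#' @param omics an [omics_matrix()] (or plain matrix).
#' @param true_labels integer partition memberships.
#' @param config a [scenario_config()].
#' @return Numeric outcome vector.
#' @export
simulate_outcome <- function(clinical, omics, true_labels, config) {
  n <- nrow(clinical)
  if (length(true_labels) != n) stop("true_labels length mismatch")
  X <- null_design(as.data.frame(clinical), n)
  beta <- config$beta[seq_len(min(ncol(X), length(config$beta)))]
  if (ncol(X) > length(config$beta))
    stop("design has more columns than beta entries")
  eta <- drop(X[, seq_along(beta), drop = FALSE] %*% beta)
  bp <- config$b[true_labels]
  eta + bp * rowSums(as.matrix(omics)) + stats::rnorm(n, 0, config$sigma)
}

#' Simulate one complete replicate of a scenario
#'
#' @param config a [scenario_config()].
#' @return List: `clinical`, `omics`, `graph`, `Y`, `true_labels`.
#' @export
simulate_study <- function(config) {
  cl <- simulate_clinical(config)
  om <- simulate_omics(nrow(cl$clinical), config$m,
                       p_edge = config$p_edge, eps_reg = config$eps_reg)
  Y <- simulate_outcome(cl$clinical, om$omics, cl$true_labels, config)
  list(clinical = cl$clinical, omics = om$omics, graph = om$graph, Y = Y,
       true_labels = cl$true_labels)
}

#' Monte-Carlo power / Type I error experiment driver
#'
#' For each replicate: simulate the scenario, embed the clinical covariates
#' (`k_embed` components), Ward-cluster, select the cut by relative inertia
#' loss, test each method within the partitions (root + selected cut), and
#' apply TreeBH at level `q`. Estimated clusters are matched one-to-one to
#' the true partitions (maximum-overlap assignment), and a true group counts
#' as rejected in a replicate when its matched cluster is TreeBH-selected.
#'
#' @param config a [scenario_config()].
#' @param n_reps number of Monte-Carlo replicates.
#' @param methods subset of `c("treekernel", "fpc", "simes")`.
#' @param q TreeBH target level.
#' @param seed optional RNG seed for reproducibility.
#' @param k_max largest cluster count offered to [select_k()].
#' @param min_size partition size guard passed to the tests.
#' @return A `tk_power_table` data.frame: per method and true group, the
#'   rejection proportion (`estimate`) with Monte-Carlo standard error
#'   (`mc_se`), plus per-method `any_selection` rows (the global Type I /
#'   family rejection rate) and a `mean_f1` attribute; failed replicates are
#'   counted in the `failures` attribute.
#' @export
run_experiment <- function(config, n_reps = 200,
                           methods = c("treekernel", "fpc", "simes"),
                           q = 0.05, seed = NULL, k_max = 6, min_size = 10) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  G <- config$n_partitions
  rej <- array(0L, dim = c(length(methods), G),
               dimnames = list(methods, paste0("group", seq_len(G))))
  any_sel <- stats::setNames(integer(length(methods)), methods)
  f1s <- numeric(0)
  selected_ks <- integer(0)
  failures <- 0L
  done <- 0L
  for (rep_i in seq_len(n_reps)) {
    res <- tryCatch({
      dat <- simulate_study(config)
      emb <- suppressMessages(embed_clinical(dat$clinical, k = config$k_embed))
      tree <- select_k(hierarchical_cluster(emb), k_max = k_max)
      est <- labels_at(tree, tree$selected_k)
      f1 <- partition_f1(dat$true_labels, est)
      mapping <- match_clusters(dat$true_labels, est)
      per_method <- list()
      for (mth in methods) {
        tab <- if (mth == "treekernel") {
          suppressWarnings(test_within_partitions(
            dat$Y, dat$clinical, dat$omics, tree,
            spec = kernel_spec("linear"), min_size = min_size))
        } else {
          suppressWarnings(comparator_within_partitions(
            dat$Y, dat$clinical, dat$omics, tree, method = mth,
            min_size = min_size))
        }
        tested <- tab[!tab$skipped, , drop = FALSE]
        sel <- treebh_select(hypothesis_tree(tested$node_id,
                                             tested$parent_id, tested$p_value),
                             q = q)
        leaf <- merge(tested[tested$level == max(tested$level), ,
                             drop = FALSE],
                      sel[, c("node_id", "selected")], by = "node_id")
        grp_rej <- rep(FALSE, G)
        for (gtrue in seq_len(G)) {
          gm <- mapping[as.character(gtrue)]
          if (!is.na(gm)) {
            hit <- leaf$selected[leaf$label == as.integer(gm)]
            grp_rej[gtrue] <- length(hit) > 0 && any(hit)
          }
        }
        per_method[[mth]] <- list(grp = grp_rej, any = any(sel$selected))
      }
      list(f1 = f1, k = tree$selected_k, per_method = per_method)
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    done <- done + 1L
    f1s <- c(f1s, res$f1)
    selected_ks <- c(selected_ks, res$k)
    for (mth in methods) {
      rej[mth, ] <- rej[mth, ] + res$per_method[[mth]]$grp
      any_sel[mth] <- any_sel[mth] + res$per_method[[mth]]$any
    }
  }
  if (done == 0L) stop("all replicates failed")
  rows <- list()
  for (mth in methods) {
    for (g in seq_len(G)) {
      est <- rej[mth, g] / done
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = config$scenario, m = config$m,
        partitions = G, method = mth, group = paste0("group", g),
        estimate = est, mc_se = sqrt(est * (1 - est) / done),
        n_reps = done, stringsAsFactors = FALSE)
    }
    est <- any_sel[[mth]] / done
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = config$scenario, m = config$m, partitions = G,
      method = mth, group = "any_selection", estimate = est,
      mc_se = sqrt(est * (1 - est) / done), n_reps = done,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_f1") <- mean(f1s)
  attr(out, "selected_k") <- selected_ks
  attr(out, "failures") <- failures
  class(out) <- c("tk_power_table", "data.frame")
  out
}

#' Clustering-accuracy experiment (no testing stage)
#'
#' Runs only the simulate / embed / cluster / select-k / F1 part of the
#' pipeline, which is what the clustering-accuracy summaries need; kernel
#' tests are skipped for speed.
#'
#' @inheritParams run_experiment
#' @return List with `mean_f1`, `f1` (per replicate), `selected_k`.
#' @export
run_f1_experiment <- function(config, n_reps = 200, seed = NULL, k_max = 6) {
  if (!is.null(seed)) set.seed(seed)
  f1s <- numeric(n_reps)
  ks <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    cl <- simulate_clinical(config)
    emb <- suppressMessages(embed_clinical(cl$clinical, k = config$k_embed))
    tree <- select_k(hierarchical_cluster(emb), k_max = k_max)
    f1s[i] <- partition_f1(cl$true_labels, labels_at(tree, tree$selected_k))
    ks[i] <- tree$selected_k
  }
  list(mean_f1 = mean(f1s), f1 = f1s, selected_k = ks)
}
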