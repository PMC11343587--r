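# build a normalized_matrix with a linear lineage along one latent axis:
# cluster means drift along the first 40 genes
lineage_fixture <- function(n_per = 60, n_stages = 3, seed = 31, sep = 3) {
  withr::with_seed(seed, {
    n <- n_per * n_stages; g <- 120
    stage <- rep(seq_len(n_stages), each = n_per)
    latent <- stage * sep + rnorm(n, sd = 0.5)
    vals <- matrix(rnorm(n * g, 5), n, g)
    vals[, 1:40] <- vals[, 1:40] + latent        # drifting block
    dimnames(vals) <- list(sprintf("s%03d", 1:n), sprintf("g%03d", 1:g))
    norm <- structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                           section_id = "lineage", in_tissue = rep(TRUE, n),
                           metadata = data.frame(in_tissue = rep(TRUE, n))),
                      class = "normalized_matrix")
    list(norm = norm, stage = stage, latent = latent)
  })
}

test_that("three collinear stages order correctly from the root", {
  fx <- lineage_fixture()
  tj <- infer_trajectory(fx$norm, fx$stage, root_cluster = 1, hvg_n = 120)
  expect_equal(range(tj$pseudotime), c(0, 1))
  # MST tree over 3 nodes is acyclic/connected: 2 edges
  expect_equal(nrow(tj$mst_edges), 2)
  # stage means strictly increasing in pseudotime
  m <- tapply(tj$pseudotime, fx$stage, mean)
  expect_true(all(diff(m) > 0))
  expect_gte(cor(fx$latent, tj$pseudotime, method = "spearman"), 0.9)
})

test_that("opposite-terminus root reflects pseudotime", {
  fx <- lineage_fixture(seed = 32)
  t1 <- infer_trajectory(fx$norm, fx$stage, root_cluster = 1, hvg_n = 120)
  t3 <- infer_trajectory(fx$norm, fx$stage, root_cluster = 3, hvg_n = 120)
  expect_lte(cor(t1$pseudotime, t3$pseudotime, method = "spearman"), -0.9)
  expect_error(infer_trajectory(fx$norm, fx$stage, root_cluster = 99), "root")
})

test_that("pseudotime is invariant to spot order permutation", {
  fx <- lineage_fixture(seed = 33)
  t1 <- infer_trajectory(fx$norm, fx$stage, root_cluster = 1, hvg_n = 120)
  perm <- withr::with_seed(34, sample(length(fx$stage)))
  norm_p <- fx$norm
  norm_p$values <- norm_p$values[perm, ]
  norm_p$in_tissue <- norm_p$in_tissue[perm]
  norm_p$metadata <- norm_p$metadata[perm, , drop = FALSE]
  t2 <- infer_trajectory(norm_p, fx$stage[perm], root_cluster = 1, hvg_n = 120)
  expect_lt(max(abs(t2$pseudotime[names(t1$pseudotime)] - t1$pseudotime)), 1e-9)
})

test_that("bimodality detection separates clear mixtures from Gaussians", {
  uni <- withr::with_seed(35, rnorm(500))
  f1 <- detect_bimodality(uni, seed = 1)
  expect_equal(f1$n_components, 1L)
  bi <- withr::with_seed(36, c(rnorm(250), rnorm(250, 6)))
  f2 <- detect_bimodality(bi, seed = 1)
  expect_equal(f2$n_components, 2L)
  truth <- rep(c("pseudotime-low", "pseudotime-high"), each = 250)
  expect_gte(mean(as.character(f2$assignment) == truth), 0.98)
  # identical values: 1 component via the variance floor
  f3 <- detect_bimodality(rep(2, 50))
  expect_equal(f3$n_components, 1L)
  expect_error(detect_bimodality(rnorm(10)), "at least 20")
})

test_that("mixture EM agrees with a small-grid oracle on n = 50 fixtures", {
  # oracle: maximize the 2-component likelihood over an exhaustive coarse
  # grid of (mu1, mu2, w), sd fixed at the truth scale
  x <- withr::with_seed(37, c(rnorm(25, 0, 1), rnorm(25, 5, 1)))
  grid_mu <- seq(-1, 6, by = 0.25)
  best <- -Inf
  for (m1 in grid_mu) for (m2 in grid_mu[grid_mu > m1]) for (w in c(.3, .5, .7)) {
    ll <- sum(log(w * dnorm(x, m1, 1) + (1 - w) * dnorm(x, m2, 1)))
    if (ll > best) { best <- ll; bm <- c(m1, m2) }
  }
  fit <- detect_bimodality(x, seed = 2)
  expect_equal(fit$n_components, 2L)
  expect_lt(max(abs(fit$mu - bm)), 0.5)
  # EM likelihood must beat the coarse-grid oracle
  ll_em <- sum(log(fit$weights[1] * dnorm(x, fit$mu[1], sqrt(fit$sigma2[1])) +
                   fit$weights[2] * dnorm(x, fit$mu[2], sqrt(fit$sigma2[2]))))
  expect_gte(ll_em, best - 1e-6)
})

test_that("component SpatialTime comparison reports direction and flips labels", {
  sim <- generate_section(small_config(seed = 38), "control")
  st <- assign_spatialtime(sim$section, sim$truth$plane)
  # emulate woven bone splitting into near-plane and far-from-plane groups:
  # pseudotime-low spots lie at high s (far), pseudotime-high at low s
  far <- st$barcode[st$s > 0.6][1:80]
  near <- st$barcode[st$s < 0.3][1:80]
  fit <- structure(list(
    n_components = 2L,
    assignment = factor(rep(c("pseudotime-low", "pseudotime-high"), each = 80),
                        levels = c("pseudotime-low", "pseudotime-high"))),
    class = "mixture_fit")
  names(fit$assignment) <- c(far, near)
  res <- compare_groups_spatialtime(fit, st)
  expect_lt(res$p, 0.01)
  expect_equal(res$direction, "pseudotime-low higher s")
  # swapping labels flips direction, p unchanged
  fit2 <- fit
  fit2$assignment <- factor(rep(c("pseudotime-high", "pseudotime-low"), each = 80),
                            levels = levels(fit$assignment))
  names(fit2$assignment) <- names(fit$assignment)
  res2 <- compare_groups_spatialtime(fit2, st)
  expect_equal(res2$p, res$p, tolerance = 1e-12)
  expect_equal(res2$direction, "pseudotime-high higher s")
  # 1-component fit is rejected with instruction
  fit1 <- structure(list(n_components = 1L), class = "mixture_fit")
  expect_error(compare_groups_spatialtime(fit1, st), "1 component")
})
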