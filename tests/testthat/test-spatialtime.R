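make_section <- function(coords, counts = NULL, cluster = NULL) {
  n <- nrow(coords)
  if (is.null(counts)) counts <- matrix(1L, n, 2)
  md <- data.frame(in_tissue = rep(TRUE, n))
  if (!is.null(cluster)) md$cluster <- cluster
  spatial_section(counts, coords, sprintf("s%04d", seq_len(n)),
                  paste0("g", seq_len(ncol(counts))), metadata = md)
}

test_that("polyline distance matches hand geometry", {
  pl <- fracture_plane(rbind(c(0, 0), c(0, 10)))
  sec <- make_section(rbind(c(3, 4), c(3, 15), c(0, 5)))
  st <- suppressWarnings(assign_spatialtime(sec, pl))
  expect_equal(st$d[1], 3, tolerance = 1e-12)              # interior projection
  expect_equal(st$d[2], 5.830951894845301, tolerance = 1e-12) # nearest endpoint
  expect_equal(st$d[3], 0, tolerance = 1e-12)              # on the polyline
  expect_equal(st$s[3], 0)
  expect_equal(max(st$s), 1)
})

test_that("inclusion mask restricts normalization to named clusters", {
  pl <- fracture_plane(rbind(c(0, 0), c(0, 10)))
  sec <- make_section(rbind(c(1, 5), c(2, 5), c(4, 5), c(9, 5)),
                      cluster = c(1, 1, 1, 2))
  st <- suppressWarnings(assign_spatialtime(sec, pl, include_clusters = 1))
  expect_equal(st$included, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(st$s[1:3], c(0, 1/3, 1))
  expect_true(is.na(st$s[4]))
  expect_error(suppressWarnings(assign_spatialtime(sec, pl, include_clusters = 99)),
               "no included spots")
})

test_that("SpatialTime is invariant to rigid motion and rescaling", {
  sim <- generate_section(small_config(seed = 2), "control")
  st0 <- assign_spatialtime(sim$section, sim$truth$plane)
  th <- 0.7; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  shift <- c(123, -45)
  move <- function(m) sweep(m %*% t(R), 2, shift, "+")
  sec_r <- sim$section; sec_r$coords <- move(sim$section$coords)
  pl_r <- fracture_plane(move(sim$truth$plane$points))
  st_r <- suppressWarnings(assign_spatialtime(sec_r, pl_r))  # bbox warning
  expect_lt(max(abs(st_r$s - st0$s)), 1e-9)
  sec_s <- sim$section; sec_s$coords <- sim$section$coords * 7.3
  pl_s <- fracture_plane(sim$truth$plane$points * 7.3)
  st_s <- assign_spatialtime(sec_s, pl_s)
  expect_lt(max(abs(st_s$s - st0$s)), 1e-9)
})

test_that("assigned SpatialTime tracks the generative truth", {
  sim <- default_sim()
  st <- assign_spatialtime(sim$section, sim$truth$plane)
  expect_gte(cor(st$s, sim$truth$true_spatialtime, method = "spearman"), 0.99)
})

test_that("trend test finds planted gradients and not shuffled ones", {
  sim <- generate_section(small_config(seed = 3), "control")
  nm <- normalize_log_cpm(filter_genes(sim$section))
  st <- assign_spatialtime(sim$section, sim$truth$plane)
  tr <- fit_gene_trends(nm, st)
  cls <- sim$truth$class_of_gene[tr$table$gene]
  expect_gt(mean(tr$table$q[cls != "none"] < 0.05), 0.9)
  # shuffling s collapses power to ~alpha
  st_sh <- st
  st_sh$s <- withr::with_seed(4, sample(st$s))
  tr_sh <- fit_gene_trends(nm, st_sh)
  expect_lt(mean(tr_sh$table$q[cls != "none"] < 0.05), 0.1)
  # constant gene gets p = 1 by convention
  nm2 <- nm
  nm2$values[, 1] <- 1
  tr2 <- fit_gene_trends(nm2, st)
  expect_equal(tr2$table$p[1], 1)
})

test_that("classify_trends recovers the four planted classes", {
  sim <- default_sim()
  nm <- normalize_log_cpm(filter_genes(sim$section))
  st <- assign_spatialtime(sim$section, sim$truth$plane)
  tr <- classify_trends(fit_gene_trends(nm, st), k = 4)
  tb <- tr$table
  cls <- sim$truth$class_of_gene[tb$gene]
  hit <- cls != "none" & tb$significant
  expect_gte(mean(tb$class[hit] == cls[hit]), 0.9)
  # class label only on significant genes
  expect_true(all(tb$class[!tb$significant] == "none"))
})

test_that("classify_trends naming follows the argmax rule", {
  # synthetic monotone-increasing curve must land in the latest class
  grid <- seq(0, 1, length.out = 100)
  curves <- rbind(mono_up = grid,
                  early = exp(-(grid - 0.05)^2 / 0.02),
                  mid = exp(-(grid - 0.5)^2 / 0.02),
                  late2 = 0.8 * grid + 0.2 * grid^2)
  tr <- structure(list(
    table = data.frame(gene = rownames(curves), stat = 10, p = 0, q = 0,
                       significant = TRUE, class = NA_character_),
    curves = curves, grid = grid, df = 3, q_threshold = 0.05),
    class = "gene_trends")
  out <- classify_trends(tr, k = 3)
  tb <- out$table
  expect_equal(tb$class[tb$gene == "mono_up"], "class3")
  expect_equal(tb$class[tb$gene == "early"], "class1")
  # k = 1 gives the single spanning class
  out1 <- classify_trends(tr, k = 1)
  expect_true(all(out1$table$class == "early..late"))
})

test_that("summarize_over_spatialtime bins, CIs and peak behave", {
  sim <- generate_section(small_config(seed = 5), "control")
  st <- assign_spatialtime(sim$section, sim$truth$plane)
  n <- length(st$s)
  flat <- summarize_over_spatialtime(rep(2, n), st, n_bins = 10)
  expect_true(all(abs(flat$mean - 2) < 1e-12, na.rm = TRUE))
  expect_true(all(flat$hi - flat$lo < 1e-9, na.rm = TRUE))
  one <- summarize_over_spatialtime(rnorm(n), st, n_bins = 1)
  expect_equal(one$n, n)
  # planted bump at 0.6 recovered within one bin
  vals <- 1 + 2 * exp(-(st$s - 0.6)^2 / (2 * 0.12^2))
  curve <- summarize_over_spatialtime(vals, st, n_bins = 20)
  expect_lte(abs(attr(curve, "peak") - 0.6), 0.05 + 1e-9)
})

test_that("compare_genotypes is antisymmetric and calibrated-ish under the null", {
  sim <- generate_pair(small_config(seed = 6))
  st_c <- assign_spatialtime(sim$control$section, sim$control$truth$plane)
  st_m <- assign_spatialtime(sim$mutant$section, sim$mutant$truth$plane)
  n_c <- length(st_c$s); n_m <- length(st_m$s)
  v_c <- withr::with_seed(7, rnorm(n_c)); v_m <- withr::with_seed(8, rnorm(n_m))
  ab <- compare_genotypes(v_c, st_c, v_m, st_m, n_perm = 200, seed = 9)
  ba <- compare_genotypes(v_m, st_m, v_c, st_c, n_perm = 200, seed = 9)
  expect_equal(ab$delta_auc, -ba$delta_auc, tolerance = 1e-12)
  expect_gt(ab$p, 0.05)  # pure-noise values: no genotype effect
})
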