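test_that("run_pca orders components and fixes signs", {
  set.seed(1)
  # exactly 3 informative directions embedded in 10-dim noise-free data
  basis <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:3]
  x <- (matrix(rnorm(300), 100, 3) %*% diag(c(5, 2, 1))) %*% t(basis)
  emb <- suppressWarnings(run_pca(x, n_components = 6, scale. = FALSE))
  expect_true(all(diff(emb$sdev) <= 1e-8))
  expect_lt(emb$sdev[4] / emb$sdev[1], 1e-8)
  # sign convention: largest-|loading| positive
  for (j in 1:3) expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
  # top-k reconstruction error is nonincreasing in k
  xc <- scale(x, scale = FALSE)
  recon_err <- function(k) {
    hat <- emb$scores[, 1:k, drop = FALSE] %*% t(emb$loadings[, 1:k, drop = FALSE])
    sum((xc - hat)^2)
  }
  expect_lte(recon_err(3), recon_err(2))
  expect_lte(recon_err(2), recon_err(1))
})

test_that("integrate_sections removes per-gene section offsets", {
  set.seed(2)
  n <- 120; g <- 40
  base <- matrix(abs(rnorm(n * g, 5)), n, g,
                 dimnames = list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:g)))
  mk <- function(vals, id) {
    v <- Matrix::Matrix(vals, sparse = TRUE)
    structure(list(values = v, section_id = id, in_tissue = rep(TRUE, n),
                   metadata = data.frame(in_tissue = rep(TRUE, n))),
              class = "normalized_matrix")
  }
  offset <- matrix(3, n, g)
  emb <- integrate_sections(list(mk(base, "a"), mk(base + offset, "b")))
  # the two sections are identical after centering: paired spots coincide
  sa <- emb$scores[emb$section == "a", ]
  sb <- emb$scores[emb$section == "b", ]
  expect_lt(max(abs(sa - sb)), 1e-8)
  # gene-universe mismatch is a named error
  bad <- mk(base[, 1:39], "c")
  expect_error(integrate_sections(list(mk(base, "a"), bad)), "g40")
})

test_that("cluster_graph separates Gaussian blobs and is deterministic", {
  set.seed(3)
  blob <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 10), 100, 2))
  emb <- structure(list(scores = `rownames<-`(blob, sprintf("s%03d", 1:200))),
                   class = "pc_embedding")
  cl1 <- cluster_graph(emb, k_neighbors = 10, resolution = 0.1, seed = 4)
  expect_equal(length(unique(cl1$cluster)), 2)
  expect_equal(ari(cl1$cluster, rep(1:2, each = 100)), 1)
  cl2 <- cluster_graph(emb, k_neighbors = 10, resolution = 0.1, seed = 4)
  expect_identical(cl1$cluster, cl2$cluster)
  # labels contiguous from 0
  expect_setequal(unique(cl1$cluster), 0:1)
})

test_that("clustering recovers synthetic domains and is order-invariant", {
  sim <- generate_section(small_config(seed = 11), "control")
  nm <- normalize_log_cpm(filter_genes(sim$section))
  emb <- run_pca(nm, 20)
  cl <- cluster_graph(emb, seed = 1)
  expect_gte(ari(cl$cluster, sim$truth$domain_of_spot), 0.8)
  # permuting spot order only renames labels
  perm <- withr::with_seed(9, sample(nrow(emb$scores)))
  emb_p <- structure(list(scores = emb$scores[perm, ]), class = "pc_embedding")
  cl_p <- cluster_graph(emb_p, seed = 1)
  expect_equal(ari(cl$cluster[perm], cl_p$cluster), 1)
})

test_that("embed_2d is deterministic and preserves blob separation", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
  emb <- structure(list(scores = `rownames<-`(blob, sprintf("s%03d", 1:100))),
                   class = "pc_embedding")
  xy1 <- embed_2d(emb); xy2 <- embed_2d(emb)
  expect_identical(xy1, xy2)
  lab <- rep(1:2, each = 50)
  # mean silhouette on blob labels strictly positive
  d <- as.matrix(dist(xy1))
  sil <- vapply(1:100, function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
  # duplicated points land near-identically
  emb_dup <- structure(list(scores = rbind(blob, blob[1, , drop = FALSE])),
                       class = "pc_embedding")
  rownames(emb_dup$scores) <- c(sprintf("s%03d", 1:100), "dup")
  xyd <- embed_2d(emb_dup)
  expect_lt(sqrt(sum((xyd["dup", ] - xyd["s001", ])^2)), 1e-6)
})

test_that("find_markers recovers planted domain markers", {
  sim <- generate_section(small_config(seed = 12), "control")
  nm <- normalize_log_cpm(filter_genes(sim$section))
  dom <- factor(sim$truth$domain_of_spot)
  mk <- find_markers(nm, as.integer(dom))
  catg <- sim$truth$gene_catalog
  # for each domain, its planted markers should top the cluster's q ranking
  for (lev in seq_along(levels(dom))) {
    planted <- catg$gene[catg$role == "marker" & catg$domain == levels(dom)[lev]]
    planted <- intersect(planted, colnames(nm$values))
    sub <- mk[mk$cluster == lev & mk$logfc > 0, ]
    top <- sub$gene[order(sub$q, -sub$logfc)][seq_len(2 * length(planted))]
    expect_gt(mean(planted %in% top), 0.8)
    expect_true(all(mk$q[mk$cluster == lev & mk$gene %in% planted] < 0.05))
  }
  # identical in/out distributions -> logfc ~ 0
  x <- matrix(rep(c(1, 2), each = 30), 60, 5)
  lfc0 <- find_markers(x, rep(1:2, 30))
  expect_lt(max(abs(lfc0$logfc)), 1e-9)
})

test_that("marker test controls type I error under label permutation", {
  sim <- generate_section(small_config(seed = 13), "control")
  nm <- normalize_log_cpm(filter_genes(sim$section))
  n_in <- sum(nm$in_tissue)
  reject <- withr::with_seed(14, {
    unlist(lapply(1:5, function(r) {
      cl <- sample(rep(1:2, length.out = n_in))
      mk <- find_markers(nm, cl)
      mk$p < 0.05
    }))
  })
  # raw p at 0.05 under the null: binomial tolerance over ~17k tests
  expect_lt(mean(reject), 0.05 + 3 * sqrt(0.05 * 0.95 / length(reject)))
})
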