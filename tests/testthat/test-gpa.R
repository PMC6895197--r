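test_that("gpa aligns similarity-transformed copies of one shape exactly", {
  set.seed(3)
  p <- 7
  base <- floramod:::base_configuration(p, rep(1, p))
  arr <- array(0, c(10, p, 3))
  for (s in 1:10) {
    rot <- floramod:::random_rotation()
    scl <- exp(runif(1, log(0.5), log(2)))
    trn <- runif(3, -1, 1)
    arr[s, , ] <- sweep(scl * (base %*% rot), 2, trn, "+")
  }
  tbl <- floramod:::lm_table(arr, sprintf("s%d", 1:10), rep("sp", 10))
  fit <- gpa(tbl)
  expect_true(fit$converged)
  for (s in 2:10) {
    expect_lt(max(abs(fit$aligned[s, , ] - fit$aligned[1, , ])), 1e-8)
  }
  # consensus equals the shape up to rotation
  expect_lt(shape_distance(fit$consensus, base), 1e-8)
  # aligned configurations are centered with unit centroid size
  for (s in 1:10) {
    expect_lt(max(abs(colMeans(fit$aligned[s, , ]))), 1e-10)
    expect_equal(sum(fit$aligned[s, , ]^2), 1, tolerance = 1e-10)
  }
})

test_that("gpa consensus matches an independent SVD-based Procrustes mean", {
  set.seed(4)
  cfgs <- lapply(1:3, function(i) matrix(rnorm(12), 4, 3))  # three tetrahedra
  arr <- array(0, c(3, 4, 3))
  for (i in 1:3) arr[i, , ] <- cfgs[[i]]
  tbl <- floramod:::lm_table(arr, paste0("s", 1:3), rep("sp", 3))
  fit <- gpa(tbl, tol = 1e-20)
  mu <- procrustes_mean_oracle(cfgs)
  expect_lt(shape_distance(fit$consensus, mu), 1e-8)
})

test_that("gpa output is invariant to nuisance transforms of the input", {
  spec <- sim_spec(p = 9, hypothesis = two_module_hyp(9), n_species = 3,
                   group_sizes = c(g = 3), specimens_per_species = 4,
                   missing_fraction = 0, nuisance = FALSE)
  fl <- simulate_flowers(spec, seed = 6)
  fit0 <- gpa(fl$table)
  a <- floramod:::lm_array(fl$table)
  set.seed(7)
  for (s in seq_along(a$specimen_id)) {
    rot <- floramod:::random_rotation()
    scl <- exp(runif(1, log(0.5), log(2)))
    a$coords[s, , ] <- sweep(scl * (a$coords[s, , ] %*% rot), 2, runif(3), "+")
  }
  fit1 <- gpa(floramod:::lm_table(a$coords, a$specimen_id, a$species_id, a$group, a$labels))
  for (s in seq_along(a$specimen_id)) {
    expect_lt(shape_distance(fit0$aligned[s, , ], fit1$aligned[s, , ]), 1e-8)
  }
  expect_error(gpa(toy_table(1, 5)), "2 specimens")
})

test_that("species means average multi-specimen species and pass singletons through", {
  set.seed(8)
  base <- floramod:::base_configuration(5, rep(1, 5))
  d <- matrix(rnorm(15, 0, 0.01), 5, 3)
  arr <- array(0, c(3, 5, 3))
  arr[1, , ] <- base + d
  arr[2, , ] <- base - d
  arr[3, , ] <- base * 1.3 + 0.2    # singleton, arbitrary placement
  tbl <- floramod:::lm_table(arr, c("a1", "a2", "b1"), c("spA", "spA", "spB"))
  fit <- gpa(tbl)
  sm <- species_means(fit)
  am <- floramod:::lm_array(sm)
  expect_setequal(am$specimen_id, c("spA", "spB"))
  # mean of symmetric pair is the midpoint of the aligned pair
  mid <- (fit$aligned[1, , ] + fit$aligned[2, , ]) / 2
  expect_equal(am$coords[match("spA", am$specimen_id), , ], mid, tolerance = 1e-12)
  expect_equal(am$coords[match("spB", am$specimen_id), , ], fit$aligned[3, , ],
               tolerance = 1e-12)
})

test_that("shape_pca satisfies variance conservation, completeness and an eigen oracle", {
  set.seed(9)
  tbl <- toy_table(6, 4, sd = 0.1)
  fit <- gpa(tbl)
  pca <- shape_pca(fit)
  Y <- floramod:::flatten_coords(fit$aligned)
  # eigenvalue oracle: covariance eigendecomposition
  ev <- eigen(cov(Y), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pca$eigenvalues, ev[seq_along(pca$eigenvalues)], tolerance = 1e-10)
  # total variance conserved, pct sums to 100
  expect_equal(sum(pca$eigenvalues), sum(diag(cov(Y))), tolerance = 1e-10)
  expect_equal(sum(pca$pct_variance), 100, tolerance = 1e-8)
  # reconstruction from all PCs reproduces the data
  sc <- as.matrix(pca$scores[, grep("^PC", names(pca$scores))])
  rec <- sweep(sc %*% t(pca$loadings), 2, pca$center, "+")
  expect_lt(max(abs(rec - Y)), 1e-10)

  # rank-1 data: PC1 explains 100%
  v <- rnorm(12)
  Y1 <- outer(rnorm(5), v)
  rownames(Y1) <- paste0("r", 1:5)
  p1 <- shape_pca(Y1)
  expect_equal(p1$pct_variance[1], 100, tolerance = 1e-8)
})

test_that("protest statistic and null behave as specified", {
  set.seed(10)
  A <- matrix(rnorm(40), 20, 2)
  rot <- matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2)
  B <- 3 * A %*% rot + 5
  pr <- protest_scores(A, B, nperm = 99, seed = 1)
  expect_equal(pr$correlation, 1, tolerance = 1e-10)
  expect_equal(pr$p, 1 / 100)
  # reflection allowed
  Bref <- B %*% diag(c(-1, 1))
  expect_equal(protest_scores(A, Bref, nperm = 99, seed = 1)$correlation, 1,
               tolerance = 1e-10)
  # agreement with the vegan implementation on arbitrary data
  skip_if_not_installed("vegan")
  C <- matrix(rnorm(40), 20, 2)
  pv <- vegan::protest(A, C, permutations = 199)
  expect_equal(protest_scores(A, C, nperm = 99)$correlation, pv$t0, tolerance = 1e-10)
})

test_that("protest p-values are uniform under independence", {
  set.seed(11)
  ps <- replicate(200, {
    A <- matrix(rnorm(40), 20, 2); B <- matrix(rnorm(40), 20, 2)
    protest_scores(A, B, nperm = 199)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
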