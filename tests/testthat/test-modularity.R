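test_that("CR is zero without between-module covariance and matches theory for exchangeable S", {
  hyp <- two_module_hyp(6)
  midx <- rep(1:2, each = 3)
  # data whose between-block sample covariance is exactly zero: residualize
  # the second block on the first
  set.seed(1)
  X1 <- matrix(rnorm(20 * 9), 20, 9)
  X2 <- matrix(rnorm(20 * 9), 20, 9)
  X2 <- stats::resid(stats::lm(X2 ~ X1))
  X <- cbind(X1, X2)
  expect_equal(cr_coefficient(X, hyp)$cr, 0, tolerance = 1e-10)

  # exchangeable covariance (equal off-diagonals): closed form
  # sqrt(9 pA pB / sqrt((9 pA^2 - 3 pA)(9 pB^2 - 3 pB))), slightly above 1
  S <- matrix(0.4, 18, 18); diag(S) <- 1
  Tz <- floramod:::cr_block_matrix(S, 6)
  pw <- floramod:::cr_pairwise(Tz, midx, 2)
  pa <- pb <- 3
  closed <- sqrt(9 * pa * pb / sqrt((9 * pa^2 - 3 * pa) * (9 * pb^2 - 3 * pb)))
  expect_equal(pw[1, 2], closed, tolerance = 1e-10)
  expect_equal(closed, cr_oracle(S, midx), tolerance = 1e-10)
})

test_that("CR matches a brute-force oracle on toy data and m > 2 averages pairs", {
  set.seed(2)
  X <- matrix(rnorm(5 * 18), 5, 18)
  hyp2 <- two_module_hyp(6)
  expect_equal(cr_coefficient(X, hyp2)$cr, cr_oracle(cov(X), rep(1:2, each = 3)),
               tolerance = 1e-12)
  hyp3 <- module_hypothesis("m3", setNames(c("a", "a", "b", "b", "c", "c"),
                                           as.character(1:6)))
  res <- cr_coefficient(X, hyp3)
  expect_equal(res$cr, cr_oracle(cov(X), c(1, 1, 2, 2, 3, 3)), tolerance = 1e-12)
  expect_equal(res$cr, mean(res$pairwise[upper.tri(res$pairwise)]), tolerance = 1e-12)
})

test_that("CR is invariant to within-module landmark order and, through GPA, to rotation", {
  set.seed(3)
  hyp <- two_module_hyp(8)
  X <- block_mvn(25, 8, hyp, 0.6, 0.2)
  cr0 <- cr_coefficient(X, hyp)$cr
  # permute landmarks within modules (and permute the hypothesis accordingly)
  perm <- c(sample(1:4), sample(5:8))
  arr <- floramod:::unflatten_coords(X, 8)[, perm, , drop = FALSE]
  Xp <- floramod:::flatten_coords(arr)
  expect_equal(cr_coefficient(Xp, two_module_hyp(8))$cr, cr0, tolerance = 1e-10)

  # a global rotation of all raw specimens leaves the GPA-aligned coordinates,
  # and hence the CR, unchanged (gpa standardizes orientation by principal axes)
  tbl <- toy_table(10, 8, sd = 0.05)
  fit0 <- gpa(tbl)
  a <- floramod:::lm_array(tbl)
  rot <- floramod:::random_rotation()
  for (s in 1:10) a$coords[s, , ] <- a$coords[s, , ] %*% rot
  fit1 <- gpa(floramod:::lm_table(a$coords, a$specimen_id, a$species_id, a$group, a$labels))
  expect_lt(max(abs(fit1$aligned - fit0$aligned)), 1e-8)
  expect_equal(cr_coefficient(fit1, hyp)$cr, cr_coefficient(fit0, hyp)$cr,
               tolerance = 1e-10)
})

test_that("permutation p matches exhaustive enumeration on a 6-landmark toy", {
  set.seed(4)
  p <- 6
  hyp <- two_module_hyp(p)
  X <- matrix(rnorm(8 * 3 * p), 8)
  S <- cov(X)
  Tz <- floramod:::cr_block_matrix(S, p)
  cr_of <- function(mi) floramod:::cr_from_pairwise(floramod:::cr_pairwise(Tz, mi, 2))
  obs <- cr_of(rep(1:2, each = 3))
  all_cr <- apply(utils::combn(p, 3), 2, function(idx) {
    mi <- rep(2L, p); mi[idx] <- 1L
    cr_of(mi)
  })
  p_exact <- mean(all_cr <= obs + 1e-12)
  mt <- modularity_test(X, hyp, nperm = 10000, seed = 5)
  expect_equal(mt$cr, obs, tolerance = 1e-12)
  expect_lt(abs(mt$p - p_exact), 0.02)
})

test_that("modular data give small CR, p at the permutation floor and positive z", {
  set.seed(6)
  hyp <- two_module_hyp(12)
  X <- block_mvn(30, 12, hyp, 0.7, 0.1)
  mt <- modularity_test(X, hyp, nperm = 1000, seed = 7)
  expect_lt(mt$cr, 0.5)
  expect_lte(mt$p, 0.01)         # observed included: floor = 1/nperm
  expect_gt(mt$z, 2)
  expect_gte(mt$p, 1 / mt$nperm)
})

test_that("median z grows as between-module correlation drops", {
  set.seed(8)
  hyp <- two_module_hyp(10)
  med_z <- vapply(c(0.45, 0.3, 0.1), function(rb) {
    median(replicate(25, {
      modularity_test(block_mvn(25, 10, hyp, 0.5, rb), hyp, nperm = 300)$z
    }))
  }, numeric(1))
  expect_true(all(diff(med_z) > 0))
})

test_that("self-comparison of a group gives delta 0 and p 1", {
  set.seed(9)
  hyp <- two_module_hyp(6)
  t1 <- modularity_test(block_mvn(20, 6, hyp, 0.5, 0.2), hyp, nperm = 300, seed = 1)
  cmp <- compare_modularity(list(a = t1, b = t1))
  expect_equal(cmp$delta_z, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_modularity(list(t1)), "two")
})

test_that("phylogenetic CR on a star tree equals the ordinary test on species means", {
  set.seed(10)
  n_sp <- 8; p <- 6
  hyp <- two_module_hyp(p)
  star <- ape::stree(n_sp, "star")
  star$edge.length <- rep(1, n_sp)
  star$tip.label <- sprintf("sp%02d", 1:n_sp)
  Y <- block_mvn(n_sp, p, hyp, 0.6, 0.2)
  rownames(Y) <- star$tip.label
  arr <- floramod:::unflatten_coords(Y, p)
  means <- floramod:::lm_table(arr, star$tip.label, star$tip.label)
  pm <- phylo_modularity(means, star, hyp, nperm = 500, seed = 3)
  mt <- modularity_test(Y, hyp, nperm = 500, seed = 3)
  expect_equal(pm$cr, mt$cr, tolerance = 1e-10)
  expect_equal(pm$p, mt$p)
  expect_equal(pm$z, mt$z, tolerance = 1e-8)
})

test_that("phylogenetic CR detects modular evolution on a tree", {
  # species means evolve with modular *evolutionary* covariance: simulate
  # correlated Brownian deviations via a block covariance among coordinates
  set.seed(11)
  n_sp <- 30; p <- 10
  hyp <- two_module_hyp(p)
  tr <- simulate_tree(n_sp, seed = 12)
  C <- ape::vcv(tr)
  Lc <- t(chol(C))
  hits <- replicate(20, {
    E <- block_mvn(n_sp, p, hyp, 0.7, 0.1)
    Y <- Lc %*% E
    rownames(Y) <- rownames(C)
    arr <- floramod:::unflatten_coords(Y, p)
    means <- floramod:::lm_table(arr, rownames(C), rownames(C))
    phylo_modularity(means, tr, hyp, nperm = 200)$p <= 0.05
  })
  expect_gte(mean(hits), 0.8)
})
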