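test_that("kmult is scale-invariant, near 1 under BM, and matches Blomberg's K univariately", {
  tr <- simulate_tree(20, seed = 1)
  spec <- sim_spec(p = 6, hypothesis = two_module_hyp(6), n_species = 20,
                   group_sizes = c(g = 20))
  sm <- simulate_species_means(tr, spec, seed = 2)
  k1 <- kmult(sm$means, tr, nperm = 19, seed = 3)
  tr_scaled <- tr
  tr_scaled$edge.length <- tr$edge.length * 7.3
  k2 <- kmult(sm$means, tr_scaled, nperm = 19, seed = 3)
  expect_equal(k1$k_mult, k2$k_mult, tolerance = 1e-10)

  # univariate reduction equals Blomberg's K from phytools
  skip_if_not_installed("phytools")
  set.seed(4)
  y <- floramod:::simulate_ou_trait(tr, alpha = 0, sigma2 = 1, seed = 5)
  k_pkg <- kmult(matrix(y, ncol = 1, dimnames = list(names(y), "t")), tr, nperm = 9)
  k_ref <- phytools::phylosig(tr, y, method = "K")
  expect_equal(k_pkg$k_mult, unclass(k_ref)[[1]], tolerance = 1e-6)
})

test_that("kmult permutation p detects strong signal and star trees reduce to iid", {
  tr <- simulate_tree(25, seed = 6)
  spec <- sim_spec(p = 8, hypothesis = two_module_hyp(8), n_species = 25,
                   group_sizes = c(g = 25))
  sm <- simulate_species_means(tr, spec, seed = 7)
  km <- kmult(sm$means, tr, nperm = 199, seed = 8)
  expect_lte(km$p, 0.05)
  expect_gte(km$p, 1 / 200)

  # star tree: GLS root equals the arithmetic mean
  star <- ape::stree(10, "star"); star$edge.length <- rep(1, 10)
  star$tip.label <- paste0("t", 1:10)
  Y <- matrix(rnorm(30), 10, dimnames = list(star$tip.label, NULL))
  ctx <- phylo_context(star, star$tip.label)
  expect_equal(floramod:::gls_root(Y, ctx$Cinv), colMeans(Y), tolerance = 1e-10)
})

test_that("module rates are recovered nearly unbiasedly with a calibrated ratio test", {
  hyp <- two_module_hyp(8)
  spec <- sim_spec(p = 8, hypothesis = hyp, n_species = 30,
                   group_sizes = c(g = 30), sigma2 = c(A = 3e-3, B = 3e-3))
  set.seed(9)
  # suppressWarnings: a rare near-singular tree triggers the documented
  # phylo_context jitter notice
  est <- suppressWarnings(replicate(300, {
    tr <- simulate_tree(30)
    sm <- simulate_species_means(tr, spec)
    mr <- module_rates(sm$means, tr, hyp, nsim = 3)
    mr$rates$sigma2
  }))
  # mean estimated rate within 5% of the generating value (n-1)/n bias aside
  expect_lt(abs(mean(est) - 3e-3) / 3e-3, 0.05 + 1 / 30)

  # null calibration: equal rates give approximately uniform p
  spec20 <- sim_spec(p = 8, hypothesis = hyp, n_species = 20,
                     group_sizes = c(g = 20), sigma2 = c(A = 3e-3, B = 3e-3))
  set.seed(10)
  ps <- suppressWarnings(replicate(60, {
    tr <- simulate_tree(20)
    sm <- simulate_species_means(tr, spec20)
    module_rates(sm$means, tr, hyp, nsim = 99)$p
  }))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(mean(ps <= 0.05), 0.15)
})

test_that("discrete ancestral states: degenerate and closed-form cases", {
  tr <- simulate_tree(8, seed = 11)
  one <- setNames(rep("blue", 8), tr$tip.label)
  # a single observed state cannot be handled as a 2-state model; with the
  # state space collapsing the reconstruction is that state everywhere
  one[1] <- "red"
  fit <- asr_discrete(tr, one, model = "ER")
  expect_equal(nrow(fit$anc), tr$Nnode)
  expect_true(all(abs(rowSums(as.matrix(fit$anc[, c("blue", "red")])) - 1) < 1e-8))

  # two-tip closed form at the fitted rate: L(q) = sum over root states of the
  # product of 2-state ER transition probabilities
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  st <- setNames(c("x", "y"), c("A", "B"))
  f2 <- asr_discrete(tr2, st, model = "ER")
  q <- f2$rates
  pd <- 0.5 + 0.5 * exp(-2 * q); po <- 0.5 - 0.5 * exp(-2 * q)
  expect_equal(f2$logLik, log(pd * po + po * pd), tolerance = 1e-6)

  # ER preferred over ARD for a clustered binary character (fewer parameters)
  tr3 <- simulate_tree(12, seed = 12)
  grp <- floramod:::assign_groups(tr3, c(a = 6, b = 6))
  fit_er <- asr_discrete(tr3, grp, "ER")
  fit_ard <- asr_discrete(tr3, grp, "ARD")
  expect_lt(fit_er$AIC, fit_ard$AIC)
  expect_error(asr_discrete(tr3, grp[-1], "ER"), "without a state")
})

test_that("trait models nest correctly and are locally optimal at their MLEs", {
  tr <- simulate_tree(40, seed = 13)
  y <- floramod:::simulate_ou_trait(tr, alpha = 0, sigma2 = 1, seed = 14)
  fits <- fit_trait_models(tr, y)
  expect_setequal(fits$model, c("BM", "lambda", "OU", "EB"))
  expect_equal(sum(fits$weight), 1, tolerance = 1e-12)

  # lambda = 1 and EB exponent = 0 reproduce the BM likelihood
  C <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  yv <- y[tr$tip.label]
  logL_bm <- fits$logL[fits$model == "BM"]
  g_l1 <- floramod:::gls_profile_loglik(yv, floramod:::model_V0("lambda", C, 1))
  g_eb0 <- floramod:::gls_profile_loglik(yv, floramod:::model_V0("EB", C, 0))
  expect_equal(g_l1$logL, logL_bm, tolerance = 1e-8)
  expect_equal(g_eb0$logL, logL_bm, tolerance = 1e-8)
  # fitted models dominate BM's likelihood (nesting) ...
  expect_gte(fits$logL[fits$model == "lambda"], logL_bm - 1e-6)
  # ... and are local optima: nudging the parameter cannot improve the fit
  for (mn in c("lambda", "OU", "EB")) {
    par <- fits$par[fits$model == mn]
    ll <- fits$logL[fits$model == mn]
    for (eps in c(-1e-4, 1e-4)) {
      p2 <- par * (1 + eps) + eps * 1e-6
      if (mn == "lambda") p2 <- min(max(p2, 0), 1)
      if (mn == "EB") p2 <- min(p2, 0)
      if (mn == "OU") p2 <- max(p2, 1e-6)
      expect_lte(floramod:::gls_profile_loglik(yv, floramod:::model_V0(mn, C, p2))$logL,
                 ll + 1e-6)
    }
  }
})

test_that("OU simulations are recognized by model selection", {
  tr <- simulate_tree(80, seed = 15)
  set.seed(16)
  wins <- replicate(15, {
    y <- floramod:::simulate_ou_trait(tr, alpha = 3, sigma2 = 1, seed = sample.int(1e6, 1))
    f <- fit_trait_models(tr, y)
    f$AICc[f$model == "OU"] < f$AICc[f$model == "BM"]
  })
  expect_gte(mean(wins), 0.8)
})

test_that("shift search improves BIC by construction and localizes a planted shift", {
  tr <- simulate_tree(60, seed = 17)
  dt <- floramod:::descendant_tips(tr)
  sizes <- vapply(tr$edge[, 2], function(nd) length(dt[[nd]]), 0L)
  e_true <- which(sizes >= 8 & sizes <= 20)[1]
  y <- floramod:::simulate_ou_trait(tr, alpha = 2, sigma2 = 1, theta0 = 0,
                                    shifts = setNames(2.5, e_true), seed = 18)
  sc <- detect_shifts(tr, y)
  expect_lte(sc$bic, sc$bic_null)
  child <- tr$edge[e_true, 2]; par <- tr$edge[e_true, 1]
  nbr <- c(e_true, which(tr$edge[, 2] == par), which(tr$edge[, 1] == child))
  expect_true(any(sc$shifts$edge %in% nbr))
  expect_error(detect_shifts(tr, y, max_shifts = nrow(tr$edge)), "branch count")
})

test_that("convergent optima are merged when two clades share a shifted regime", {
  tr <- simulate_tree(80, seed = 30)
  dt <- floramod:::descendant_tips(tr)
  sizes <- vapply(tr$edge[, 2], function(nd) length(dt[[nd]]), 0L)
  depth <- ape::node.depth.edgelength(tr)
  # shifts must start deep enough that tips approach the new optimum
  cand <- which(sizes >= 8 & sizes <= 25 & depth[tr$edge[, 2]] <= 0.6)
  # two disjoint clades get the same new optimum
  pick <- c()
  for (e in cand) {
    if (length(pick) == 0) pick <- e
    else if (length(intersect(dt[[tr$edge[e, 2]]], unlist(dt[tr$edge[pick, 2]]))) == 0) {
      pick <- c(pick, e); break
    }
  }
  expect_gte(length(pick), 2)   # this tree has two disjoint mid-depth clades
  y <- floramod:::simulate_ou_trait(tr, alpha = 2, sigma2 = 1, theta0 = 0,
                                    shifts = setNames(c(4, 4), pick), seed = 20)
  sc <- detect_shifts(tr, y)
  expect_gte(sc$n_shifts, 2)
  expect_gte(length(sc$convergent), 1)
})
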