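#' Phylogenetic covariance context
#'
#' Builds the Brownian phylogenetic covariance `C` of a tip set (entries are
#' shared root-to-node path lengths; the diagonal holds root-to-tip depths)
#' with its inverse and Cholesky factor. An ill-conditioned `C` (condition
#' number above 1e12) is jittered by `1e-8 * mean(diag(C))` with a warning.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param species Character vector of tip labels defining row/column order.
#' @return List with `C`, `Cinv`, `L` (lower Cholesky of `C`), `species`.
#' @export
phylo_context <- function(tree, species = tree$tip.label) {
  check_tree(tree, species)
  C <- ape::vcv(tree)[species, species]
  kap <- kappa(C, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    warning("phylogenetic covariance ill-conditioned; adding 1e-8 * mean(diag) jitter")
    C <- C + diag(1e-8 * mean(diag(C)), nrow(C))
  }
  Lt <- tryCatch(chol(C), error = function(e) {
    abort_floramod("phylogenetic covariance is singular; consider jittering branch lengths")
  })
  list(C = C, Cinv = chol2inv(Lt), L = t(Lt), species = species)
}

# GLS root (phylogenetic mean) per trait column
gls_root <- function(Y, Cinv) {
  w <- Cinv %*% matrix(1, nrow(Y), 1)
  as.vector(crossprod(w, Y)) / sum(w)
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' Extension of Blomberg's K to multivariate data: the ratio of observed to
#' phylogenetically expected trait dispersion,
#' `K = [tr(D'D) / tr(D' C^-1 D)] / [(tr(C) - n / sum(C^-1)) / (n - 1)]`
#' with `D = Y - 1a` the deviations from the GLS root. `K` is about 1 for data
#' generated by Brownian motion on the tree. The permutation null shuffles
#' species across tips; the observed value is included, so
#' `p = #{K_perm >= K_obs} / (nperm + 1)`.
#'
#' @param means Species-mean [landmark_table()] or species x traits matrix
#'   with species rownames.
#' @param tree Rooted `phylo` covering the species.
#' @param nperm Number of random permutations (observed added on top).
#' @param seed Optional RNG seed.
#' @return Tibble with `k_mult`, `p`, `nperm`, `n`.
#' @export
kmult <- function(means, tree, nperm = 999, seed = NULL) {
  ym <- species_matrix_any(means, tree)
  Y <- ym$Y
  n <- nrow(Y)
  if (n < 4) abort_floramod("need at least 4 species")
  ctx <- phylo_context(tree, rownames(Y))
  denom_scale <- (sum(diag(ctx$C)) - n / sum(ctx$Cinv)) / (n - 1)
  kstat <- function(Ym) {
    D <- sweep(Ym, 2, gls_root(Ym, ctx$Cinv))
    (sum(D * D) / sum(D * (ctx$Cinv %*% D))) / denom_scale
  }
  k_obs <- kstat(Y)
  with_seed(seed, {
    k_perm <- vapply(seq_len(nperm), function(i) kstat(Y[sample.int(n), , drop = FALSE]),
                     numeric(1))
  })
  tibble::tibble(k_mult = k_obs, p = (1 + sum(k_perm >= k_obs)) / (nperm + 1),
                 nperm = nperm, n = n)
}

# like species_matrix() but accepts any trait matrix (not only 3p coordinates)
species_matrix_any <- function(means, tree) {
  if (inherits(means, "landmark_tbl")) return(species_matrix(means, tree))
  Y <- as.matrix(means)
  if (is.null(rownames(Y))) abort_floramod("trait matrix needs species rownames")
  if (!setequal(rownames(Y), tree$tip.label)) abort_floramod("species do not match tree tips")
  list(Y = Y[tree$tip.label, , drop = FALSE], labels = colnames(Y))
}

#' Per-module multivariate Brownian rates and rate-ratio test
#'
#' Estimates the net Brownian rate of each module as the mean, over the
#' module's 3 p_m coordinate dimensions, of the per-dimension rates
#' `sigma2_j = sum_i Z_ij^2 / n` computed from phylogenetically whitened
#' deviations `Z = L^-1 (Y - 1a)`. The ratio `R = max/min` is tested by
#' simulating `nsim` Brownian datasets with a common per-dimension rate equal
#' to the pooled mean rate (observed included):
#' `p = #{R_sim >= R_obs} / (nsim + 1)`.
#'
#' @param means Species-mean [landmark_table()] or species x 3p matrix.
#' @param tree Rooted `phylo`.
#' @param hypothesis A [module_hypothesis()] with >= 2 modules.
#' @param nsim Number of null simulations.
#' @param seed Optional RNG seed.
#' @return A `rate_comparison`: list with `rates` (tibble per module), `ratio`,
#'   `p`, `nsim`.
#' @export
module_rates <- function(means, tree, hypothesis, nsim = 999, seed = NULL) {
  ym <- species_matrix(means, tree)
  Y <- ym$Y
  n <- nrow(Y)
  if (n < 4) abort_floramod("need at least 4 species")
  midx <- module_index(hypothesis, ym$labels)
  mod_j <- rep(midx, each = 3)
  m <- length(hypothesis$module_names)
  ctx <- phylo_context(tree, rownames(Y))
  u <- forwardsolve(ctx$L, rep(1, n))

  rate_stats <- function(Z) {
    s2j <- colSums(Z^2) / n
    s2m <- vapply(seq_len(m), function(k) mean(s2j[mod_j == k]), numeric(1))
    list(s2m = s2m, ratio = max(s2m) / min(s2m))
  }
  W <- forwardsolve(ctx$L, Y)
  ahat <- crossprod(u, W) / sum(u^2)
  Z <- W - u %*% ahat
  obs <- rate_stats(Z)
  pooled <- mean(colSums(Z^2) / n)

  with_seed(seed, {
    r_sim <- vapply(seq_len(nsim), function(i) {
      E <- matrix(stats::rnorm(n * ncol(Y), sd = sqrt(pooled)), n, ncol(Y))
      Zs <- E - u %*% (crossprod(u, E) / sum(u^2))
      rate_stats(Zs)$ratio
    }, numeric(1))
  })
  structure(list(
    rates = tibble::tibble(module = hypothesis$module_names, sigma2 = obs$s2m,
                           n_landmarks = as.vector(table(factor(midx, levels = seq_len(m))))),
    ratio = obs$ratio,
    p = (1 + sum(r_sim >= obs$ratio)) / (nsim + 1),
    nsim = nsim, hypothesis = hypothesis$name
  ), class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("<rate_comparison %s: R = %.3f, p = %.4g>\n", x$hypothesis, x$ratio, x$p))
  print(x$rates)
  invisible(x)
}

#' Maximum-likelihood ancestral states for a discrete character
#'
#' Fits an Mk model (`"ER"` equal rates or `"ARD"` all rates different) by
#' maximum likelihood via [ape::ace()] and returns marginal ancestral state
#' probabilities, rate estimates and AIC.
#'
#' @param tree Rooted `phylo`.
#' @param states Named character vector of tip states (names = tip labels).
#' @param model `"ER"` or `"ARD"`.
#' @return List with `anc` (tibble of node marginal probabilities), `rates`,
#'   `logLik`, `AIC`, `model`.
#' @export
asr_discrete <- function(tree, states, model = c("ER", "ARD")) {
  model <- match.arg(model)
  if (is.null(names(states))) abort_floramod("states must be named by tip label")
  absent <- setdiff(tree$tip.label, names(states))
  if (length(absent) > 0) {
    abort_floramod(paste0("tips without a state: ", paste(absent, collapse = ", ")))
  }
  x <- factor(states[tree$tip.label])
  fit <- ape::ace(x, tree, type = "discrete", model = model)
  anc <- tibble::as_tibble(fit$lik.anc)
  anc$node <- length(tree$tip.label) + seq_len(tree$Nnode)
  k <- if (model == "ER") 1 else nlevels(x) * (nlevels(x) - 1)
  list(anc = anc, rates = fit$rates, logLik = fit$loglik,
       AIC = -2 * fit$loglik + 2 * k, model = model, k = k)
}

# --- continuous trait models -------------------------------------------------

# model covariance structures (sigma2 profiled out, so these are correlations
# up to a common scale)
model_V0 <- function(model, C, par) {
  Tdepth <- max(diag(C))
  switch(model,
    BM = C,
    lambda = {
      V <- par * C
      diag(V) <- diag(C)
      V
    },
    OU = {
      a <- par
      exp(-2 * a * (Tdepth - C)) * (1 - exp(-2 * a * C)) / (2 * a)
    },
    EB = {
      a <- par
      if (abs(a) < 1e-10) C else (exp(a * C) - 1) / a
    })
}

# profiled ML log-likelihood of a GLS model with covariance sigma2 * V0
gls_profile_loglik <- function(y, V0) {
  n <- length(y)
  Lt <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(Lt)) return(list(logL = -Inf))
  w <- backsolve(Lt, forwardsolve(t(Lt), cbind(1, y)))
  # w = V0^-1 [1 y]
  one_v1 <- sum(w[, 1]); a <- sum(w[, 2]) / one_v1
  r <- y - a
  rv <- sum(r * backsolve(Lt, forwardsolve(t(Lt), r)))
  s2 <- rv / n
  logdet <- 2 * sum(log(diag(Lt)))
  list(logL = -n / 2 * log(2 * pi) - n / 2 * log(s2) - logdet / 2 - n / 2,
       sigma2 = s2, root = a)
}

#' Fit continuous trait-evolution models (BM, lambda, OU, EB)
#'
#' Univariate maximum-likelihood fits of four models of trait evolution on an
#' ultrametric tree, compared by AICc. The Brownian rate and the root state
#' are profiled by GLS; the remaining parameter (Pagel's lambda, OU attraction
#' alpha, or the early-burst exponent) is optimized on a bounded interval
#' (lambda in \[0,1\], alpha in \[1e-6, 50/T\], EB exponent in \[-10/T, 0\],
#' with T the tree depth).
#'
#' @param tree Ultrametric rooted `phylo`.
#' @param trait Named numeric vector of tip values (e.g. a PC score).
#' @return A `trait_model_fits` tibble: one row per model with parameter
#'   estimates, `logL`, `AICc`, `dAICc`, Akaike `weight`, and a flag
#'   `at_bound`.
#' @export
fit_trait_models <- function(tree, trait) {
  if (is.null(names(trait))) abort_floramod("trait must be named by tip label")
  if (!setequal(names(trait), tree$tip.label)) abort_floramod("trait names do not match tips")
  y <- as.numeric(trait[tree$tip.label])
  n <- length(y)
  if (n < 5) abort_floramod("need at least 5 tips")
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  if (diff(range(depths)) > 1e-6 * max(depths)) {
    abort_floramod("OU/EB fits require an ultrametric tree")
  }
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Tdepth <- max(diag(C))

  fit_one <- function(model, lower, upper) {
    if (model == "BM") {
      g <- gls_profile_loglik(y, C)
      return(list(par = NA_real_, logL = g$logL, sigma2 = g$sigma2, root = g$root,
                  k = 2, at_bound = FALSE))
    }
    obj <- function(par) -gls_profile_loglik(y, model_V0(model, C, par))$logL
    opt <- stats::optimize(obj, c(lower, upper), tol = 1e-8)
    g <- gls_profile_loglik(y, model_V0(model, C, opt$minimum))
    at_bound <- opt$minimum <= lower + 1e-6 * (upper - lower) ||
      opt$minimum >= upper - 1e-6 * (upper - lower)
    list(par = opt$minimum, logL = g$logL, sigma2 = g$sigma2, root = g$root,
         k = 3, at_bound = at_bound)
  }
  fits <- list(
    BM = fit_one("BM", NA, NA),
    lambda = fit_one("lambda", 0, 1),
    OU = fit_one("OU", 1e-6, 50 / Tdepth),
    EB = fit_one("EB", -10 / Tdepth, 0)
  )
  rows <- lapply(names(fits), function(mn) {
    f <- fits[[mn]]
    aicc <- -2 * f$logL + 2 * f$k + 2 * f$k * (f$k + 1) / max(n - f$k - 1, 1e-9)
    tibble::tibble(model = mn, par = f$par, sigma2 = f$sigma2, root = f$root,
                   logL = f$logL, k = f$k, AICc = aicc, at_bound = f$at_bound)
  })
  out <- dplyr::bind_rows(rows)
  out$dAICc <- out$AICc - min(out$AICc)
  w <- exp(-out$dAICc / 2)
  out$weight <- w / sum(w)
  class(out) <- c("trait_model_fits", class(out))
  out
}
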