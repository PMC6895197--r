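# --- CR core -----------------------------------------------------------------
# The covariance ratio works on the 3p x 3p specimen covariance S (landmark-
# major coordinate order). All module sums reduce to the landmark-level matrix
# Tz[k, l] = sum of squared entries of the 3x3 block of S linking landmarks k
# and l, with the matrix diagonal of S zeroed first. For modules A and B:
#   tr(S_AB S_AB')    = sum_{k in A, l in B} Tz[k, l]
#   tr(S_AA* S_AA*')  = sum_{k, l in A}     Tz[k, l]
# so every permutation of landmarks into modules only reweights Tz, which is
# what makes thousand-permutation nulls cheap.

cr_block_matrix <- function(S, p) {
  Sz <- S
  diag(Sz) <- 0
  G <- matrix(0, 3 * p, p)
  G[cbind(seq_len(3 * p), rep(seq_len(p), each = 3))] <- 1
  crossprod(G, (Sz * Sz) %*% G)
}

# pairwise CR matrix (m x m, NA diagonal) from Tz and a module index vector
cr_pairwise <- function(Tz, midx, m = max(midx)) {
  M <- matrix(0, length(midx), m)
  M[cbind(seq_along(midx), midx)] <- 1
  U <- crossprod(M, Tz %*% M)
  W <- diag(U)
  if (any(W <= 0)) {
    abort_floramod("a module has zero within-module off-diagonal covariance (too few coordinates)")
  }
  out <- sqrt(U / sqrt(outer(W, W)))
  diag(out) <- NA_real_
  out
}

cr_from_pairwise <- function(pw) mean(pw[upper.tri(pw)])

# covariance of flattened aligned coordinates; optional fixed center
coord_covariance <- function(x, hypothesis, center = NULL) {
  if (inherits(x, "gpa_fit")) {
    Y <- flatten_coords(x$aligned); labels <- x$labels
  } else if (inherits(x, "landmark_tbl")) {
    a <- lm_array(x)
    if (any(a$mask)) abort_floramod("missing landmarks present")
    Y <- flatten_coords(a$coords); labels <- a$labels
  } else {
    Y <- as.matrix(x); labels <- as.character(seq_len(ncol(Y) / 3))
  }
  n <- nrow(Y)
  if (n < 3) abort_floramod("need at least 3 configurations")
  if (is.null(center)) {
    S <- stats::cov(Y)
  } else {
    Yc <- sweep(Y, 2, center)
    S <- crossprod(Yc) / (n - 1)
  }
  list(S = S, labels = labels, n = n)
}

#' Covariance-ratio (CR) coefficient
#'
#' The CR coefficient of a pair of modules is the ratio of between-module to
#' within-module covariation,
#' `CR(A,B) = sqrt(tr(S_AB S_AB') / sqrt(tr(S_AA* S_AA*') tr(S_BB* S_BB*')))`,
#' where `S_AA*` is the within-module covariance block with its diagonal set
#' to zero. Values below 1 indicate modularity. For more than two modules the
#' overall CR is the mean over all module pairs.
#'
#' @param x A [gpa()] fit, an aligned complete [landmark_table()], or an
#'   n x 3p coordinate matrix (landmark-major order).
#' @param hypothesis A [module_hypothesis()] covering the landmarks.
#' @param center Optional fixed 3p center vector to use instead of the sample
#'   mean (e.g. a global consensus when analysing one group of a joint fit).
#' @return List with `cr` (scalar) and `pairwise` (m x m matrix).
#' @export
cr_coefficient <- function(x, hypothesis, center = NULL) {
  cc <- coord_covariance(x, hypothesis, center)
  p <- length(cc$labels)
  midx <- module_index(hypothesis, cc$labels)
  Tz <- cr_block_matrix(cc$S, p)
  pw <- cr_pairwise(Tz, midx, m = length(hypothesis$module_names))
  dimnames(pw) <- list(hypothesis$module_names, hypothesis$module_names)
  list(cr = cr_from_pairwise(pw), pairwise = pw)
}

#' CR modularity test with a landmark-permutation null
#'
#' Tests whether the observed CR is smaller (more modular) than expected when
#' whole landmarks (each carrying its three coordinates) are randomly
#' reassigned to modules of the observed sizes. The observed value counts as
#' one permutation, so the smallest attainable p is `1/nperm`. The effect size
#' is `z = (mean(perm) - CR_obs) / sd(perm)`: larger positive z means stronger
#' modularity.
#'
#' @inheritParams cr_coefficient
#' @param nperm Total permutations (observed included).
#' @param seed Optional RNG seed.
#' @return A `cr_test`: list with `cr`, `pairwise`, `p`, `z`, `perm`
#'   (permutation CR values, observed first), `nperm`, `hypothesis`, `n`.
#' @examples
#' fl <- simulate_flowers(sim_spec(p = 12, n_species = 6, group_sizes = c(g = 6),
#'                                 missing_fraction = 0,
#'                                 hypothesis = module_hypothesis("true", setNames(
#'                                   rep(c("A", "B"), each = 6), as.character(1:12)))),
#'                        seed = 2)
#' fit <- gpa(fl$table)
#' modularity_test(fit, fl$spec$hypothesis, nperm = 99, seed = 1)
#' @export
modularity_test <- function(x, hypothesis, nperm = 1000, seed = NULL, center = NULL) {
  if (nperm < 100) warning("nperm < 100 gives a very coarse permutation p-value")
  cc <- coord_covariance(x, hypothesis, center)
  res <- cr_test_from_cov(cc$S, cc$labels, hypothesis, nperm, seed)
  res$n <- cc$n
  res
}

# shared permutation machinery for ordinary and phylogenetic CR tests
cr_test_from_cov <- function(S, labels, hypothesis, nperm, seed) {
  p <- length(labels)
  midx <- module_index(hypothesis, labels)
  m <- length(hypothesis$module_names)
  Tz <- cr_block_matrix(S, p)
  pw <- cr_pairwise(Tz, midx, m)
  dimnames(pw) <- list(hypothesis$module_names, hypothesis$module_names)
  cr_obs <- cr_from_pairwise(pw)
  perm <- numeric(nperm)
  perm[1] <- cr_obs
  with_seed(seed, {
    for (i in seq_len(nperm - 1L)) {
      perm[i + 1L] <- cr_from_pairwise(cr_pairwise(Tz, midx[sample.int(p)], m))
    }
  })
  structure(list(
    cr = cr_obs, pairwise = pw,
    # tie-tolerant count: permutations reproducing the observed assignment
    # (exactly equal CR up to roundoff) must count as "as extreme"
    p = sum(perm <= cr_obs + 1e-9 * max(1, abs(cr_obs))) / nperm,
    z = (mean(perm) - cr_obs) / stats::sd(perm),
    perm = perm, nperm = nperm, hypothesis = hypothesis$name, n = NA_integer_
  ), class = "cr_test")
}

#' @export
print.cr_test <- function(x, ...) {
  cat(sprintf("<cr_test %s: CR = %.3f, p = %.4g, Z = %.3f (nperm = %d)>\n",
              x$hypothesis, x$cr, x$p, x$z, x$nperm))
  invisible(x)
}

#' Compare strength of modularity between groups
#'
#' Two-sample comparison of CR effect sizes: for groups 1 and 2,
#' `z_12 = (z_1 - z_2) / sqrt(se_1^2 + se_2^2)` with a two-tailed normal
#' p-value. The standard error of each effect size combines the unit sampling
#' variance of a standardized permutation effect size with the Monte-Carlo
#' error of its estimate, the latter estimated by splitting the permutation
#' sample into 10 blocks and taking the dispersion of block-wise z estimates:
#' `se^2 = 1 + var(z_blocks)/10`.
#'
#' @param results List of [modularity_test()] results (with stored permutation
#'   distributions).
#' @param labels Optional group labels (defaults to list names).
#' @return A `modularity_comparison` tibble: one row per group pair with
#'   `delta_z`, `se`, `p`, plus per-group `z` and `se` in the attribute
#'   `"groups"`.
#' @export
compare_modularity <- function(results, labels = NULL) {
  if (length(results) < 2) abort_floramod("need at least two results to compare")
  ok <- vapply(results, function(r) inherits(r, "cr_test") && !is.null(r$perm), TRUE)
  if (!all(ok)) abort_floramod("every result must be a cr_test with a stored permutation distribution")
  labels <- labels %||% names(results) %||% paste0("group", seq_along(results))
  zs <- vapply(results, `[[`, 0, "z")
  ses <- vapply(results, function(r) {
    blocks <- split(r$perm, cut(seq_along(r$perm), 10, labels = FALSE))
    zb <- vapply(blocks, function(b) (mean(b) - r$cr) / stats::sd(b), numeric(1))
    sqrt(1 + stats::var(zb) / 10)
  }, numeric(1))
  pairs <- utils::combn(seq_along(results), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    dz <- zs[i1] - zs[i2]
    se <- sqrt(ses[i1]^2 + ses[i2]^2)
    same <- identical(results[[i1]], results[[i2]])
    tibble::tibble(
      group1 = labels[i1], group2 = labels[i2],
      z1 = zs[i1], z2 = zs[i2],
      delta_z = if (same) 0 else dz, se = se,
      p = if (same) 1 else 2 * stats::pnorm(-abs(dz) / se))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "groups") <- tibble::tibble(group = labels, z = zs, se = ses)
  class(out) <- c("modularity_comparison", class(out))
  out
}

#' Phylogenetically corrected CR modularity test
#'
#' Computes the evolutionary covariance of species mean shapes under Brownian
#' motion -- `S_evol = (Y - 1a)' C^-1 (Y - 1a) / (n - 1)` with `C` the
#' phylogenetic covariance and `a` the GLS root estimate -- and applies the CR
#' statistic and its landmark-permutation null to it.
#'
#' @param means Species-mean [landmark_table()] (one row set per species) or
#'   n x 3p matrix with species rownames.
#' @param tree Rooted `phylo` whose tip set equals the species set.
#' @param hypothesis A [module_hypothesis()].
#' @inheritParams modularity_test
#' @return A `cr_test` (see [modularity_test()]).
#' @export
phylo_modularity <- function(means, tree, hypothesis, nperm = 1000, seed = NULL) {
  ym <- species_matrix(means, tree)
  ctx <- phylo_context(tree, rownames(ym$Y))
  n <- nrow(ym$Y)
  if (n < 4) abort_floramod("need at least 4 species")
  resid <- sweep(ym$Y, 2, gls_root(ym$Y, ctx$Cinv))
  S_evol <- crossprod(resid, ctx$Cinv %*% resid) / (n - 1)
  res <- cr_test_from_cov(S_evol, ym$labels, hypothesis, nperm, seed)
  res$n <- n
  res
}

# species-mean input -> matrix Y (species x 3p) matched against tree tips
species_matrix <- function(means, tree) {
  if (inherits(means, "landmark_tbl")) {
    a <- lm_array(means)
    if (any(a$mask)) abort_floramod("missing landmarks present")
    Y <- flatten_coords(a$coords)
    rownames(Y) <- a$species_id
    labels <- a$labels
  } else {
    Y <- as.matrix(means)
    if (is.null(rownames(Y))) abort_floramod("species matrix needs species rownames")
    labels <- as.character(seq_len(ncol(Y) / 3))
  }
  if (!setequal(rownames(Y), tree$tip.label)) {
    abort_floramod("species do not match tree tips")
  }
  list(Y = Y[tree$tip.label, , drop = FALSE], labels = labels)
}
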