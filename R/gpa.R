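# optimal proper rotation taking X onto Y (both centered p x 3): R = UV' from
# svd(X'Y) with a sign flip to exclude reflections
proper_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment
#'
#' Iteratively removes position, size and orientation from a set of landmark
#' configurations: each configuration is centered, scaled to unit centroid
#' size, and rotated onto the running consensus by proper orthogonal
#' Procrustes (no reflections); the consensus is recomputed until its summed
#' squared change falls below `tol`. Scaling to unit centroid size is retained
#' after rotation (partial Procrustes), so centroid size is the size variable.
#'
#' @param tbl A complete [landmark_table()] (impute missing landmarks first,
#'   see [estimate_missing()]).
#' @param tol Convergence tolerance on the summed squared change of the
#'   consensus configuration.
#' @param max_iter Iteration cap.
#' @return A `gpa_fit`: list with `aligned` (n x p x 3 array), `consensus`
#'   (p x 3), `centroid_sizes`, `iterations`, `converged`, and the specimen
#'   metadata. Use [aligned_table()] for a tibble view.
#' @examples
#' fl <- simulate_flowers(sim_spec(p = 8, n_species = 4, group_sizes = c(g = 4),
#'                                 missing_fraction = 0), seed = 1)
#' fit <- gpa(fl$table)
#' fit$converged
#' @export
gpa <- function(tbl, tol = 1e-10, max_iter = 100) {
  a <- lm_array(tbl)
  if (any(a$mask)) {
    abort_floramod("missing landmarks present; estimate them first (see estimate_missing())")
  }
  n <- dim(a$coords)[1]; p <- dim(a$coords)[2]
  if (p < 4) abort_floramod("need at least 4 landmarks")
  if (n < 2) abort_floramod("need at least 2 specimens")

  aligned <- array(0, dim = dim(a$coords), dimnames = dimnames(a$coords))
  sizes <- numeric(n)
  for (s in seq_len(n)) {
    cfg <- a$coords[s, , ]
    cfg <- sweep(cfg, 2, colMeans(cfg))
    cs <- sqrt(sum(cfg^2))
    if (cs < 1e-12) abort_floramod(paste0("degenerate configuration: ", a$specimen_id[s]))
    sizes[s] <- cs
    aligned[s, , ] <- cfg / cs
  }
  # degenerate geometry check: configurations must span 3 dimensions poorly at
  # worst 2 (collinear sets break rotation fitting)
  if (qr(aligned[1, , ])$rank < 2) {
    abort_floramod("degenerate (collinear) landmark configuration")
  }

  consensus <- aligned[1, , ]
  consensus <- consensus / sqrt(sum(consensus^2))
  iter <- 0; converged <- FALSE
  repeat {
    iter <- iter + 1
    for (s in seq_len(n)) {
      aligned[s, , ] <- aligned[s, , ] %*% proper_rotation(aligned[s, , ], consensus)
    }
    new_cons <- apply(aligned, c(2, 3), mean)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sum((new_cons - consensus)^2)
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # standardize orientation: rotate everything onto the consensus' principal
  # axes (deterministic signs), so the aligned output does not depend on the
  # arbitrary orientation of the input
  E <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  for (j in 1:3) if (E[which.max(abs(E[, j])), j] < 0) E[, j] <- -E[, j]
  if (det(E) < 0) E[, 3] <- -E[, 3]
  consensus <- consensus %*% E
  for (s in seq_len(n)) aligned[s, , ] <- aligned[s, , ] %*% E
  structure(list(
    aligned = aligned, consensus = consensus, centroid_sizes = sizes,
    iterations = iter, converged = converged,
    specimen_id = a$specimen_id, species_id = a$species_id, group = a$group,
    labels = a$labels
  ), class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit: %d specimens x %d landmarks, %d iteration(s), converged: %s>\n",
              dim(x$aligned)[1], dim(x$aligned)[2], x$iterations, x$converged))
  invisible(x)
}

#' Aligned coordinates of a GPA fit as a landmark table
#' @param fit A [gpa()] fit.
#' @return A [landmark_table()] of Procrustes-aligned coordinates.
#' @export
aligned_table <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  lm_table(fit$aligned, fit$specimen_id, fit$species_id, fit$group, fit$labels)
}

#' Species mean shapes from aligned specimens
#'
#' Species with more than one specimen get the arithmetic mean of their
#' aligned coordinates; singleton species pass their aligned coordinates
#' through unchanged.
#'
#' @param fit A [gpa()] fit.
#' @return A species-mean [landmark_table()] (one "specimen" per species).
#' @export
species_means <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  sp <- unique(fit$species_id)
  p <- dim(fit$aligned)[2]
  out <- array(0, c(length(sp), p, 3))
  grp <- character(length(sp))
  for (i in seq_along(sp)) {
    rows <- which(fit$species_id == sp[i])
    out[i, , ] <- if (length(rows) == 1) fit$aligned[rows, , ] else
      apply(fit$aligned[rows, , , drop = FALSE], c(2, 3), mean)
    grp[i] <- fit$group[rows[1]]
  }
  lm_table(out, specimen_id = sp, species_id = sp, group = grp, labels = fit$labels)
}

#' PCA of shape space
#'
#' Principal component analysis of the flattened (3p-dimensional) aligned
#' coordinates about their mean, via covariance eigendecomposition.
#'
#' @param x A [gpa()] fit, an aligned [landmark_table()], or an n x 3p matrix.
#' @return A `shape_pca`: list with `scores` (tibble: specimen_id, species_id,
#'   group, PC1..PCk), `loadings`, `eigenvalues`, `pct_variance`, `center`.
#' @export
shape_pca <- function(x) {
  if (inherits(x, "gpa_fit")) {
    Y <- flatten_coords(x$aligned)
    meta <- tibble::tibble(specimen_id = x$specimen_id, species_id = x$species_id,
                           group = x$group)
  } else if (inherits(x, "landmark_tbl")) {
    a <- lm_array(x)
    if (any(a$mask)) abort_floramod("missing landmarks present")
    Y <- flatten_coords(a$coords)
    meta <- tibble::tibble(specimen_id = a$specimen_id, species_id = a$species_id,
                           group = a$group)
  } else {
    Y <- as.matrix(x)
    meta <- tibble::tibble(specimen_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
                           species_id = NA_character_, group = NA_character_)
  }
  n <- nrow(Y)
  if (n < 3) abort_floramod("PCA needs at least 3 configurations")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  S <- crossprod(Yc) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  k <- min(n - 1, ncol(Y))
  vals <- pmax(eg$values, 0)
  scores <- Yc %*% eg$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(meta, tibble::as_tibble(scores)),
    loadings = eg$vectors[, seq_len(k), drop = FALSE],
    eigenvalues = vals[seq_len(k)],
    pct_variance = 100 * vals[seq_len(k)] / sum(vals),
    center = ctr
  ), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca: %d axes; PC1 %.1f%%, PC2 %.1f%%>\n",
              length(x$eigenvalues), x$pct_variance[1],
              ifelse(length(x$pct_variance) > 1, x$pct_variance[2], NA)))
  invisible(x)
}

#' Procrustean concordance test of two score matrices (PROTEST)
#'
#' Centers and scales both matrices to unit total sum of squares, superimposes
#' `scores_b` on `scores_a` by the optimal orthogonal transform (reflection
#' allowed), and reports the correlation-like statistic `t = sqrt(1 - m2)`
#' where `m2` is the residual sum of squares. Significance comes from `nperm`
#' random row permutations of `scores_b`.
#'
#' @param scores_a,scores_b Matrices (or data frames) with matched rows,
#'   typically the first two PC axes of two ordinations.
#' @param nperm Number of permutations.
#' @param seed Optional RNG seed.
#' @return Tibble with `correlation`, `m2`, `p`, `nperm`.
#' @export
protest_scores <- function(scores_a, scores_b, nperm = 999, seed = NULL) {
  A <- as.matrix(scores_a); B <- as.matrix(scores_b)
  if (nrow(A) != nrow(B)) abort_floramod("row counts differ")
  if (nrow(A) < 3) abort_floramod("need at least 3 rows")
  norm01 <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  A <- norm01(A); B <- norm01(B)
  stat <- function(Bm) sum(svd(crossprod(A, Bm))$d)  # t = sum of singular values
  t_obs <- stat(B)
  with_seed(seed, {
    t_perm <- vapply(seq_len(nperm), function(i) stat(B[sample(nrow(B)), , drop = FALSE]),
                     numeric(1))
  })
  p <- (1 + sum(t_perm >= t_obs)) / (nperm + 1)
  tibble::tibble(correlation = min(t_obs, 1), m2 = max(1 - t_obs^2, 0), p = p, nperm = nperm)
}
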