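# --- similarity alignment and thin-plate splines -----------------------------

# full similarity (translation + scale + proper rotation) mapping X onto Y,
# least squares over matched rows; returns transform as a closure pair
similarity_transform <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  R <- proper_rotation(Xc, Yc)
  s <- sum(diag(crossprod(Xc %*% R, Yc))) / sum(Xc^2)
  list(
    forward = function(P) sweep(s * (sweep(P, 2, cx) %*% R), 2, cy, "+"),
    inverse = function(P) sweep((sweep(P, 2, cy) %*% t(R)) / s, 2, cx, "+")
  )
}

# 3D thin-plate spline interpolant with kernel U(r) = r and full affine term;
# exact at the control points
tps_fit <- function(ctrl, targ) {
  k <- nrow(ctrl)
  if (k < 4) abort_floramod("TPS needs at least 4 control points")
  K <- as.matrix(stats::dist(ctrl))
  P <- cbind(1, ctrl)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(targ, matrix(0, 4, 3))
  qrL <- qr(L, LAPACK = TRUE)
  if (qrL$rank < ncol(L)) {
    abort_floramod(sprintf(
      "singular TPS system (rank %d of %d); control points may be coplanar-degenerate",
      qrL$rank, ncol(L)))
  }
  coef <- solve(qrL, rhs)
  list(ctrl = ctrl, W = coef[seq_len(k), , drop = FALSE],
       A = coef[(k + 1):(k + 4), , drop = FALSE])
}

tps_predict <- function(fit, newpts) {
  newpts <- matrix(newpts, ncol = 3)
  U <- sqrt(pmax(outer(rowSums(newpts^2), rep(1, nrow(fit$ctrl))) +
                 outer(rep(1, nrow(newpts)), rowSums(fit$ctrl^2)) -
                 2 * newpts %*% t(fit$ctrl), 0))
  U %*% fit$W + cbind(1, newpts) %*% fit$A
}

# --- estimation --------------------------------------------------------------

#' Estimate missing landmarks
#'
#' Fills masked landmarks of damaged specimens from a reference set of
#' complete specimens, by one of three techniques:
#' \describe{
#'   \item{TPS}{Procrustes-align the reference mean shape to the damaged
#'     specimen on the shared landmarks, fit a 3D thin-plate spline (kernel
#'     `U(r) = r`, affine term included) mapping the aligned reference shared
#'     landmarks to the specimen's shared landmarks, and warp the reference
#'     missing-landmark positions through it.}
#'   \item{MS}{Mean substitution: the aligned reference mean positions.}
#'   \item{REG}{Per missing landmark, least-squares regression of its three
#'     coordinates on the shared-landmark coordinates across the reference
#'     specimens, with predictors reduced to the first `min(n_ref - 1, 10)`
#'     principal components.}
#' }
#'
#' @param tbl A [landmark_table()]; specimens without missing landmarks are
#'   returned unchanged.
#' @param method `"TPS"`, `"MS"` or `"REG"`.
#' @param reference Optional character vector of complete specimen ids to
#'   estimate from. Default: complete conspecifics of each damaged specimen
#'   when at least two exist, otherwise all complete specimens.
#' @return A complete [landmark_table()] with the mask cleared.
#' @export
estimate_missing <- function(tbl, method = c("TPS", "MS", "REG"), reference = NULL) {
  method <- match.arg(method)
  a <- lm_array(tbl)
  damaged <- which(rowSums(a$mask) > 0)
  if (length(damaged) == 0) return(tbl)
  complete <- a$specimen_id[rowSums(a$mask) == 0]
  if (!is.null(reference)) {
    bad <- setdiff(reference, complete)
    if (length(bad) > 0) {
      abort_floramod(paste0("reference specimens not complete or unknown: ",
                            paste(bad, collapse = ", ")))
    }
  }
  if (length(complete) < 1) abort_floramod("no complete reference specimens available")

  coords <- a$coords
  ref_cache <- list()
  min_ref <- if (method == "REG") 4 else 1
  for (d in damaged) {
    refs <- reference
    if (is.null(refs)) {
      consp <- intersect(complete, a$specimen_id[a$species_id == a$species_id[d]])
      refs <- if (length(consp) >= max(2, min_ref)) consp else complete
    }
    if (length(refs) < min_ref) {
      abort_floramod(sprintf("method %s needs at least %d reference specimens", method, min_ref))
    }
    key <- paste(refs, collapse = "|")
    if (is.null(ref_cache[[key]])) {
      ref_tbl <- lm_table(
        a$coords[match(refs, a$specimen_id), , , drop = FALSE],
        refs, a$species_id[match(refs, a$specimen_id)],
        a$group[match(refs, a$specimen_id)], a$labels)
      ref_cache[[key]] <- if (length(refs) >= 2) gpa(ref_tbl) else NULL
      if (is.null(ref_cache[[key]])) {
        # single reference: use it, centered and unit-sized, as the "mean"
        cfg <- a$coords[match(refs, a$specimen_id), , ]
        cfg <- sweep(cfg, 2, colMeans(cfg))
        ref_cache[[key]] <- list(consensus = cfg / sqrt(sum(cfg^2)), aligned = NULL)
      }
    }
    rf <- ref_cache[[key]]
    shared <- which(!a$mask[d, ])
    missing <- which(a$mask[d, ])
    if (length(shared) < 4) {
      abort_floramod(sprintf("specimen %s shares only %d landmarks with the reference (need 4)",
                             a$specimen_id[d], length(shared)))
    }
    spec_obs <- a$coords[d, shared, , drop = FALSE][1, , ]
    ref_mean <- rf$consensus

    tf <- similarity_transform(ref_mean[shared, , drop = FALSE], spec_obs)
    ref_in_spec <- tf$forward(ref_mean)

    filled <- switch(method,
      MS = ref_in_spec[missing, , drop = FALSE],
      TPS = {
        warp <- tps_fit(ref_in_spec[shared, , drop = FALSE], spec_obs)
        tps_predict(warp, ref_in_spec[missing, , drop = FALSE])
      },
      REG = {
        Xref <- flatten_coords(rf$aligned[, shared, , drop = FALSE])
        q <- min(nrow(Xref) - 1, 10)
        pc <- stats::prcomp(Xref, center = TRUE, scale. = FALSE)
        q <- min(q, ncol(pc$rotation))
        Sc <- pc$x[, seq_len(q), drop = FALSE]
        # damaged specimen in the reference frame
        d_ref <- tf$inverse(spec_obs)
        d_sc <- (as.vector(t(d_ref)) - pc$center) %*% pc$rotation[, seq_len(q), drop = FALSE]
        X <- cbind(1, Sc)
        beta_all <- qr.solve(X, flatten_coords(rf$aligned[, missing, , drop = FALSE]))
        pred <- cbind(1, d_sc) %*% beta_all
        tf$forward(matrix(pred, ncol = 3, byrow = TRUE))
      })
    coords[d, missing, ] <- filled
  }
  lm_table(coords, a$specimen_id, a$species_id, a$group, a$labels)
}

#' Validate landmark estimation by remove-and-re-estimate
#'
#' Repeatedly removes 1 to `kmax` random landmarks from a randomly chosen
#' intact specimen, re-estimates them with each method, Procrustes-fits the
#' estimated dataset, and compares its PCA (first two axes) with the intact
#' dataset's PCA by [protest_scores()]. Per landmark it reports the mean
#' positional error (Euclidean recovery error relative to centroid size) and
#' Welch T / F tests comparing aligned landmark dispersion around the
#' consensus between the estimated and intact datasets across replicates.
#'
#' @param intact A complete [landmark_table()] with at least 3 specimens.
#' @param methods Subset of `c("TPS", "MS", "REG")`.
#' @param nreps Number of remove-and-re-estimate replicates per method.
#' @param kmax Maximum number of landmarks removed (must leave >= 4 anchors).
#' @param nperm Permutations for each PROTEST comparison.
#' @param seed RNG seed.
#' @return An `imputation_report`: list with `replicates` (one row per method
#'   x replicate: specimen, k, protest correlation and p, mean recovery
#'   error) and `landmarks` (per method x landmark: mean error, T/F p-values).
#' @export
validate_estimation <- function(intact, methods = c("TPS", "MS", "REG"),
                                nreps = 50, kmax = 10, nperm = 499, seed = NULL) {
  a <- lm_array(intact)
  if (any(a$mask)) abort_floramod("intact table must be complete")
  n <- length(a$specimen_id); p <- length(a$labels)
  if (n < 3) abort_floramod("need at least 3 intact specimens")
  if (kmax >= p - 4) abort_floramod("kmax too large: fewer than 4 anchors would remain")
  methods <- match.arg(methods, several.ok = TRUE)

  fit0 <- gpa(intact)
  pca0 <- shape_pca(fit0)
  s0 <- as.matrix(pca0$scores[, c("PC1", "PC2")])
  dist0 <- landmark_consensus_distances(fit0)

  rep_rows <- list(); err_acc <- list(); distA <- list(); distB <- list()
  with_seed(seed, {
    draws <- lapply(seq_len(nreps), function(r) {
      list(spec = sample(n, 1), k = sample(seq_len(kmax), 1))
    })
    for (r in seq_len(nreps)) draws[[r]]$gone <- sample(p, draws[[r]]$k)
    for (m in methods) {
      for (r in seq_len(nreps)) {
        d <- draws[[r]]
        coords <- a$coords
        true_pos <- coords[d$spec, d$gone, , drop = FALSE][1, , , drop = TRUE]
        true_pos <- matrix(true_pos, ncol = 3)
        coords[d$spec, d$gone, ] <- NA_real_
        dam <- lm_table(coords, a$specimen_id, a$species_id, a$group, a$labels)
        est <- estimate_missing(dam, method = m)
        ea <- lm_array(est)
        est_pos <- matrix(ea$coords[d$spec, d$gone, ], ncol = 3)
        cs <- centroid_size(a$coords[d$spec, , ])
        errs <- sqrt(rowSums((est_pos - true_pos)^2)) / cs
        for (j in seq_along(d$gone)) {
          lab <- a$labels[d$gone[j]]
          err_acc[[paste(m, lab)]] <- c(err_acc[[paste(m, lab)]], errs[j])
        }
        fit1 <- gpa(est)
        pca1 <- shape_pca(fit1)
        pr <- protest_scores(s0, as.matrix(pca1$scores[, c("PC1", "PC2")]), nperm = nperm)
        dist1 <- landmark_consensus_distances(fit1)
        for (l in seq_len(p)) {
          keym <- paste(m, a$labels[l])
          distA[[keym]] <- c(distA[[keym]], dist1[d$spec, l])
          distB[[keym]] <- c(distB[[keym]], dist0[d$spec, l])
        }
        rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
          method = m, rep = r, specimen_id = a$specimen_id[d$spec], k = d$k,
          correlation = pr$correlation, p = pr$p, mean_error = mean(errs))
      }
    }
  })
  lm_rows <- list()
  for (m in methods) {
    for (l in seq_len(p)) {
      lab <- a$labels[l]; keym <- paste(m, lab)
      errv <- err_acc[[keym]]
      A <- distA[[keym]]; B <- distB[[keym]]
      tt <- tryCatch(stats::t.test(A, B)$p.value, error = function(e) NA_real_)
      ft <- tryCatch(stats::var.test(A, B)$p.value, error = function(e) NA_real_)
      lm_rows[[length(lm_rows) + 1]] <- tibble::tibble(
        method = m, landmark = lab,
        n_removed = length(errv %||% numeric(0)),
        mean_error = if (is.null(errv)) NA_real_ else mean(errv),
        t_p = tt, f_p = ft)
    }
  }
  structure(list(
    replicates = dplyr::bind_rows(rep_rows),
    landmarks = dplyr::bind_rows(lm_rows),
    nreps = nreps, kmax = kmax
  ), class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, ...) {
  s <- dplyr::summarise(dplyr::group_by(x$replicates, .data$method),
                        mean_correlation = mean(.data$correlation),
                        prop_p_le_05 = mean(.data$p <= 0.05),
                        mean_error = mean(.data$mean_error))
  cat(sprintf("<imputation_report: %d replicates x %d method(s)>\n",
              x$nreps, length(unique(x$replicates$method))))
  print(s)
  invisible(x)
}

# n x p matrix of distances of each aligned specimen's landmarks to the
# consensus landmark
landmark_consensus_distances <- function(fit) {
  n <- dim(fit$aligned)[1]; p <- dim(fit$aligned)[2]
  out <- matrix(0, n, p)
  for (s in seq_len(n)) {
    out[s, ] <- sqrt(rowSums((fit$aligned[s, , ] - fit$consensus)^2))
  }
  out
}

#' Observer (landmarking) error report
#'
#' Procrustes-fits a set of replicate landmarkings of the same specimens and a
#' set of independent specimens separately; per landmark it reports the mean
#' distance of each configuration's landmark to the set consensus, with Welch
#' T and F tests comparing replicate against independent distances. In a
#' precise landmarking protocol the replicate error should be at least an
#' order of magnitude below the independent (biological) variation.
#'
#' @param replicates,independents [landmark_table()]s with identical landmark
#'   labels and at least two specimens each.
#' @return An `observer_error` report: list with `landmarks` (per-landmark
#'   tibble) and `summary` (overall mean distances and their ratio).
#' @export
observer_error <- function(replicates, independents) {
  if (!identical(landmark_labels(replicates), landmark_labels(independents))) {
    abort_floramod("landmark labels differ between the two sets")
  }
  fr <- gpa(replicates); fi <- gpa(independents)
  dr <- landmark_consensus_distances(fr)
  di <- landmark_consensus_distances(fi)
  p <- length(fr$labels)
  rows <- lapply(seq_len(p), function(l) {
    tt <- tryCatch(stats::t.test(dr[, l], di[, l])$p.value, error = function(e) NA_real_)
    ft <- tryCatch(stats::var.test(dr[, l], di[, l])$p.value, error = function(e) NA_real_)
    tibble::tibble(landmark = fr$labels[l],
                   mean_replicate = mean(dr[, l]), mean_independent = mean(di[, l]),
                   t_p = tt, f_p = ft)
  })
  structure(list(
    landmarks = dplyr::bind_rows(rows),
    summary = tibble::tibble(
      mean_replicate = mean(dr), mean_independent = mean(di),
      ratio = mean(di) / mean(dr))
  ), class = "observer_error")
}

#' @export
print.observer_error <- function(x, ...) {
  cat(sprintf("<observer_error: replicate %.3g vs independent %.3g (ratio %.1fx)>\n",
              x$summary$mean_replicate, x$summary$mean_independent, x$summary$ratio))
  invisible(x)
}
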