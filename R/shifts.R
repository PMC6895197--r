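# --- multi-optimum OU regime-shift search ------------------------------------

# per-tip path of edge indices from root to tip, with parent/child node depths
tip_paths <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  parent_edge <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2])  # edge above node
  paths <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    path <- integer(0); node <- i
    while (!is.na(parent_edge[node])) {
      e <- parent_edge[node]
      path <- c(e, path)
      node <- tree$edge[e, 1]
    }
    paths[[i]] <- path
  }
  list(paths = paths, depth = depth, Tdepth = max(depth[seq_len(ntip)]))
}

# regime design matrix: column 1 = root optimum, one column per shift edge;
# entry (i, r) is the weight of regime r's optimum in E[y_i] under OU with
# attraction alpha
regime_design <- function(tp, tree, alpha, shift_edges) {
  ntip <- length(tp$paths)
  s <- length(shift_edges)
  X <- matrix(0, ntip, s + 1)
  Td <- tp$Tdepth
  for (i in seq_len(ntip)) {
    reg <- 1L
    X[i, 1] <- exp(-alpha * Td)
    for (e in tp$paths[[i]]) {
      hit <- match(e, shift_edges)
      if (!is.na(hit)) reg <- hit + 1L
      t0 <- tp$depth[tree$edge[e, 1]]; t1 <- tp$depth[tree$edge[e, 2]]
      X[i, reg] <- X[i, reg] + exp(-alpha * (Td - t1)) - exp(-alpha * (Td - t0))
    }
  }
  X
}

# profiled ML log-likelihood of y ~ X theta with covariance sigma2 * V0(alpha)
ou_shift_loglik <- function(y, X, V0) {
  n <- length(y)
  Lt <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(Lt)) return(list(logL = -Inf))
  Xw <- forwardsolve(t(Lt), X)
  yw <- forwardsolve(t(Lt), y)
  # normalize columns so lm.fit never drops a small-alpha regime column whose
  # scale (not direction) is tiny
  norms <- sqrt(colSums(Xw^2))
  norms[norms < 1e-300] <- 1
  fit <- stats::lm.fit(Xw / rep(norms, each = nrow(Xw)), yw)
  fit$coefficients <- fit$coefficients / norms
  rss <- sum(fit$residuals^2)
  s2 <- rss / n
  if (s2 <= 0) return(list(logL = -Inf))
  logdet <- 2 * sum(log(diag(Lt)))
  list(logL = -n / 2 * log(2 * pi) - n / 2 * log(s2) - logdet / 2 - n / 2,
       sigma2 = s2, theta = fit$coefficients)
}

#' Detect shifts in phenotypic optima along a phylogeny
#'
#' Fits a multi-optimum Ornstein-Uhlenbeck model with a global attraction
#' strength and rate. Every branch is a candidate shift point; shifts are
#' added by greedy forward selection as long as they decrease a BIC score in
#' which each shift costs two parameters (its optimum and its location on the
#' tree -- the location penalty guards against the implicit multiple testing
#' over all branches). Afterwards, pairs of regime optima are greedily merged
#' whenever equating them decreases the BIC; merged regimes reached by
#' distinct shifts are reported as convergent.
#'
#' @param tree Ultrametric rooted `phylo`.
#' @param trait Named numeric vector of tip values (typically a PC score).
#' @param max_shifts Cap on the number of shifts (must be below the branch
#'   count).
#' @param alpha_bounds Search interval for the attraction strength; default
#'   `c(1e-6, 50) / T` with `T` the tree depth.
#' @param min_clade Minimum number of descendant tips a candidate shift
#'   branch must subtend. The default 2 excludes terminal branches, where a
#'   "shift" is indistinguishable from a single-species outlier.
#' @return A `shift_config`: list with `shifts` (tibble: edge, child node,
#'   optimum, example descendant tip), `alpha`, `sigma2`, `theta_root`,
#'   `bic`, `bic_null`, `logL`, `convergent` (list of merged regime groups),
#'   `n_shifts`.
#' @export
detect_shifts <- function(tree, trait, max_shifts = 5, alpha_bounds = NULL,
                          min_clade = 2) {
  if (is.null(names(trait))) abort_floramod("trait must be named by tip label")
  if (!setequal(names(trait), tree$tip.label)) abort_floramod("trait names do not match tips")
  nE <- nrow(tree$edge)
  if (max_shifts >= nE) abort_floramod("max_shifts must be below the branch count")
  y <- as.numeric(trait[tree$tip.label])
  n <- length(y)
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Tdepth <- max(diag(C))
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  if (diff(range(depths)) > 1e-6 * max(depths)) {
    abort_floramod("shift detection requires an ultrametric tree")
  }
  bounds <- alpha_bounds %||% c(1e-6, 50 / Tdepth)
  tp <- tip_paths(tree)
  dt_all <- descendant_tips(tree)
  clade_sizes <- vapply(tree$edge[, 2], function(nd) length(dt_all[[nd]]), 0L)
  candidates <- which(clade_sizes >= min_clade)

  fit_config <- function(shift_edges, merge_map = NULL) {
    obj <- function(a) {
      X <- regime_design(tp, tree, a, shift_edges)
      if (!is.null(merge_map)) X <- merge_columns(X, merge_map)
      -ou_shift_loglik(y, X, model_V0("OU", C, a))$logL
    }
    opt <- stats::optimize(obj, bounds, tol = 1e-6)
    a <- opt$minimum
    X <- regime_design(tp, tree, a, shift_edges)
    if (!is.null(merge_map)) X <- merge_columns(X, merge_map)
    g <- ou_shift_loglik(y, X, model_V0("OU", C, a))
    # alpha + sigma2 + distinct optima are ordinary parameters; each shift
    # location additionally pays 2 log(#branches), a multiplicity correction
    # for selecting among all candidate branches (in the spirit of modified
    # BICs for changepoint selection)
    k <- 2 + ncol(X)
    s <- length(shift_edges)
    list(alpha = a, logL = g$logL, sigma2 = g$sigma2, theta = g$theta,
         bic = -2 * g$logL + k * log(n) + 1.75 * s * log(nE), k = k)
  }

  cur <- fit_config(integer(0))
  bic_null <- cur$bic
  shifts <- integer(0)
  repeat {
    if (length(shifts) >= max_shifts) break
    # scan candidates at the current alpha (cheap), then refit the best
    V0 <- model_V0("OU", C, cur$alpha)
    Lt <- chol(V0)
    yw <- forwardsolve(t(Lt), y)
    cand <- setdiff(candidates, shifts)
    best_e <- NA_integer_; best_rss <- Inf
    for (e in cand) {
      X <- regime_design(tp, tree, cur$alpha, c(shifts, e))
      Xw <- forwardsolve(t(Lt), X)
      nrm <- sqrt(colSums(Xw^2)); nrm[nrm < 1e-300] <- 1
      rss <- sum(stats::lm.fit(Xw / rep(nrm, each = nrow(Xw)), yw)$residuals^2)
      if (rss < best_rss) { best_rss <- rss; best_e <- e }
    }
    trial <- fit_config(c(shifts, best_e))
    if (trial$bic < cur$bic - 1e-8) {
      shifts <- c(shifts, best_e)
      cur <- trial
    } else break
  }

  # convergence evaluation: greedily merge pairs of regime optima
  n_reg <- length(shifts) + 1
  merge_map <- seq_len(n_reg)
  repeat {
    groups <- unique(merge_map)
    if (length(groups) < 2) break
    prs <- utils::combn(groups, 2)
    best <- NULL
    for (j in seq_len(ncol(prs))) {
      mm <- merge_map
      mm[mm == prs[2, j]] <- prs[1, j]
      trial <- fit_config(shifts, merge_map = mm)
      if (trial$bic < cur$bic - 1e-8 && (is.null(best) || trial$bic < best$fit$bic)) {
        best <- list(map = mm, fit = trial)
      }
    }
    if (is.null(best)) break
    merge_map <- best$map
    cur <- best$fit
  }

  # map fitted optima back to regimes
  groups <- match(merge_map, unique(merge_map))
  theta_by_regime <- cur$theta[groups]
  child <- tree$edge[shifts, 2]
  example_tip <- vapply(seq_along(shifts), function(j) {
    tree$tip.label[dt_all[[child[j]]][1]]
  }, "")
  convergent <- split(seq_len(n_reg), groups)
  convergent <- convergent[vapply(convergent, length, 0L) > 1]
  structure(list(
    shifts = tibble::tibble(edge = shifts, child_node = child,
                            optimum = if (length(shifts)) theta_by_regime[-1] else numeric(0),
                            example_tip = example_tip),
    alpha = cur$alpha, sigma2 = cur$sigma2,
    theta_root = unname(cur$theta[groups[1]]),
    logL = cur$logL, bic = cur$bic, bic_null = bic_null,
    convergent = convergent, n_shifts = length(shifts)
  ), class = "shift_config")
}

merge_columns <- function(X, merge_map) {
  groups <- match(merge_map, unique(merge_map))
  out <- matrix(0, nrow(X), max(groups))
  for (j in seq_along(groups)) out[, groups[j]] <- out[, groups[j]] + X[, j]
  out
}

#' @export
print.shift_config <- function(x, ...) {
  cat(sprintf("<shift_config: %d shift(s), alpha = %.3g, BIC %.2f (null %.2f)>\n",
              x$n_shifts, x$alpha, x$bic, x$bic_null))
  if (x$n_shifts > 0) print(x$shifts)
  invisible(x)
}
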