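#' Simulation specification for synthetic floral landmark data
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: 37 landmarks, 30 species in three
#' pollination-syndrome groups of 16/8/6 species, roughly 137 specimens with
#' 1-29 per species, block-modular within-species covariance, species means
#' evolving on an ultrametric depth-1 tree, and 1-10 missing landmarks
#' injected into damaged specimens.
#'
#' @param p Landmark count.
#' @param hypothesis True [module_hypothesis()] generating the block
#'   covariance; defaults to the functional attraction/efficiency partition
#'   (H4) of [merianieae_hypotheses()] when `p = 37`, else two equal modules.
#' @param n_species Number of species (tree tips).
#' @param specimens_per_species Either a single integer, a vector of length
#'   `n_species`, or `NULL` for the study-like skewed draw (zero-truncated
#'   geometric with mean about 4.6, capped at 29).
#' @param group_sizes Species per group; names become group labels.
#' @param rho_w,rho_b Within/between-module correlation of specimen-level
#'   deviations, `0 <= rho_b <= rho_w < 1`.
#' @param within_sd Specimen-level standard deviation per coordinate, in the
#'   same length units as the base configuration (unit-radius sphere).
#' @param sigma2 Per-module Brownian rate(s) of the species means, per unit
#'   tree depth; recycled across modules.
#' @param regime `"BM"` or `"OU"` for the species-mean process.
#' @param ou_alpha,ou_theta_offset OU attraction strength and the magnitude of
#'   per-group optimum offsets (0 = all groups share the root optimum).
#' @param missing_fraction Fraction of specimens damaged (given missing
#'   landmarks); the study had 65/137.
#' @param missing_range Range of missing-landmark counts per damaged specimen.
#' @param nuisance Apply a random similarity transform (rotation, translation,
#'   log-uniform scale in \[0.5, 2\]) to each specimen?
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(p = 37,
                     hypothesis = NULL,
                     n_species = 30,
                     specimens_per_species = NULL,
                     group_sizes = c(buzz_bee = 16, mixed_vertebrate = 8, passerine = 6),
                     rho_w = 0.7, rho_b = 0.1,
                     within_sd = 0.02,
                     sigma2 = 3e-4,
                     regime = c("BM", "OU"),
                     ou_alpha = 2, ou_theta_offset = 0,
                     missing_fraction = 65 / 137,
                     missing_range = c(1, 10),
                     nuisance = TRUE) {
  regime <- match.arg(regime)
  if (is.null(hypothesis)) {
    hypothesis <- if (p == 37) merianieae_hypotheses()$H4 else {
      half <- floor(p / 2)
      module_hypothesis("sim", stats::setNames(
        rep(c("A", "B"), c(half, p - half)), as.character(seq_len(p))
      ))
    }
  }
  if (length(hypothesis$assignment) != p) {
    abort_floramod("hypothesis does not cover p landmarks")
  }
  stopifnot(rho_w >= 0, rho_w < 1, rho_b >= 0, rho_b <= rho_w,
            within_sd >= 0, all(sigma2 > 0),
            sum(group_sizes) == n_species, missing_fraction >= 0, missing_fraction <= 1)
  m <- length(hypothesis$module_names)
  sigma2 <- stats::setNames(rep_len(sigma2, m), hypothesis$module_names)
  structure(list(
    p = p, hypothesis = hypothesis, n_species = n_species,
    specimens_per_species = specimens_per_species, group_sizes = group_sizes,
    rho_w = rho_w, rho_b = rho_b, within_sd = within_sd, sigma2 = sigma2,
    regime = regime, ou_alpha = ou_alpha, ou_theta_offset = ou_theta_offset,
    missing_fraction = missing_fraction, missing_range = missing_range,
    nuisance = nuisance
  ), class = "sim_spec")
}

#' Simulate an ultrametric pure-birth tree rescaled to unit depth
#'
#' @param n_tips Number of tips (>= 2), labelled `sp01`, `sp02`, ...
#' @param seed Optional RNG seed for reproducibility.
#' @return A `phylo` object with root-to-tip depth 1.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) abort_floramod("n_tips must be >= 2")
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  })
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

# base mean configuration: p points spread on an anisotropic ellipsoid
# (Fibonacci lattice squeezed along y and z, like a zygomorphic flower) plus a
# small per-module radial offset. Anisotropy keeps the geometry non-degenerate
# *and* gives the configuration well-separated principal axes, so the
# orientation standardized by GPA is stable
base_configuration <- function(p, module_idx) {
  i <- seq_len(p) - 0.5
  phi <- acos(1 - 2 * i / p)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- cbind(sin(phi) * cos(theta), 0.8 * sin(phi) * sin(theta), 0.6 * cos(phi))
  r <- 1 + 0.15 * (module_idx - mean(module_idx)) / max(1, max(module_idx) - 1)
  xyz * r
}

# edge indices in preorder (each edge after the edge above its parent node)
preorder_edges <- function(tree) {
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- length(tree$tip.label) + 1
  out <- integer(nrow(tree$edge)); k <- 0
  stack <- children[[as.character(root)]]
  while (length(stack) > 0) {
    e <- stack[1]; stack <- stack[-1]
    k <- k + 1; out[k] <- e
    ch <- children[[as.character(tree$edge[e, 2])]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  out
}

# group labels for tips: contiguous blocks in cladewise tip order, so groups
# are phylogenetically clustered like real syndromes
assign_groups <- function(tree, group_sizes) {
  ntip <- length(tree$tip.label)
  ord_edges <- preorder_edges(tree)
  tip_nodes <- tree$edge[ord_edges, 2]
  tip_nodes <- tip_nodes[tip_nodes <= ntip]
  ord <- tree$tip.label[tip_nodes]
  grp <- rep(names(group_sizes), group_sizes)
  stats::setNames(grp, ord)[tree$tip.label]
}

#' Simulate species mean shapes on a tree
#'
#' Each of the 3p landmark coordinates evolves independently along the tree,
#' under Brownian motion with the rate of its landmark's module, or under an
#' Ornstein-Uhlenbeck process with group-specific optima.
#'
#' @param tree Ultrametric `phylo`; tips become species.
#' @param spec A [sim_spec()].
#' @param seed Optional RNG seed.
#' @return A list: `means` (species-mean [landmark_table()]), `groups`
#'   (named group label per species), `root` (p x 3 root configuration),
#'   `regimes` (per-tip regime labels; equals `groups` under OU).
#' @export
simulate_species_means <- function(tree, spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (length(tree$tip.label) != spec$n_species) {
    abort_floramod("tree tip count does not match spec$n_species")
  }
  p <- spec$p
  midx <- module_index(spec$hypothesis, as.character(seq_len(p)))
  root <- base_configuration(p, midx)
  rate_j <- rep(spec$sigma2[midx], each = 3)          # 3p per-coordinate rates
  n <- spec$n_species
  groups <- assign_groups(tree, spec$group_sizes)

  with_seed(seed, {
    if (spec$regime == "BM") {
      C <- ape::vcv(tree)
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) abort_floramod("phylogenetic covariance not positive definite")
      L <- t(chol(C))
      Z <- matrix(stats::rnorm(n * 3 * p), n, 3 * p)
      Y <- sweep(L %*% Z, 2, sqrt(rate_j), "*")
      Y <- sweep(Y, 2, as.vector(t(root)), "+")
      rownames(Y) <- rownames(C)
      Y <- Y[tree$tip.label, , drop = FALSE]
    } else {
      theta0 <- as.vector(t(root))
      offsets <- lapply(names(spec$group_sizes), function(g) {
        stats::rnorm(3 * p, 0, spec$ou_theta_offset)
      })
      names(offsets) <- names(spec$group_sizes)
      Y <- simulate_ou_tips(tree, theta0, offsets, groups,
                            alpha = spec$ou_alpha, rate_j = rate_j)
    }
  })
  arr <- unflatten_coords(Y, p)
  means <- lm_table(arr, specimen_id = tree$tip.label, species_id = tree$tip.label,
                    group = unname(groups[tree$tip.label]),
                    labels = as.character(seq_len(p)))
  list(means = means, groups = groups, root = root, regimes = groups)
}

# OU simulation by preorder recursion along edges; each tip's regime is its
# group, painted on an edge when all descendant tips share the group
simulate_ou_tips <- function(tree, theta0, offsets, groups, alpha, rate_j) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  d <- length(theta0)
  tips_below <- descendant_tips(tree)
  edge_group <- function(node) {
    tips <- tips_below[[node]]
    g <- unique(groups[tree$tip.label[tips]])
    if (length(g) == 1) g else NA_character_
  }
  states <- matrix(NA_real_, ntip + nnode, d)
  root <- ntip + 1
  states[root, ] <- theta0
  for (e in preorder_edges(tree)) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]; t_e <- tree$edge.length[e]
    g <- edge_group(child)
    theta <- theta0 + if (!is.na(g)) offsets[[g]] else 0
    mu <- theta + (states[par, ] - theta) * exp(-alpha * t_e)
    sd_e <- sqrt(rate_j / (2 * alpha) * (1 - exp(-2 * alpha * t_e)))
    states[child, ] <- mu + stats::rnorm(d, 0, sd_e)
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  out <- vector("list", n_all)
  for (i in seq_len(ntip)) out[[i]] <- i
  for (e in rev(preorder_edges(tree))) {   # postorder: children before parents
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    out[[par]] <- c(out[[par]], out[[child]])
  }
  out
}

#' Simulate specimens around species means
#'
#' Specimen deviations are drawn from a 3p-dimensional normal whose
#' correlation is `rho_w` for coordinate pairs within a module (a landmark's
#' three coordinates share its module) and `rho_b` between modules, scaled by
#' `within_sd`. Optional nuisance similarity transforms and missing-landmark
#' injection emulate raw digitized data.
#'
#' @param means Species-mean [landmark_table()] (e.g. from
#'   [simulate_species_means()]).
#' @param spec A [sim_spec()].
#' @param seed Optional RNG seed.
#' @return A [landmark_table()] of specimens, with attribute `"n_per_species"`.
#' @export
simulate_specimens <- function(means, spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  a <- lm_array(means)
  p <- spec$p
  midx <- module_index(spec$hypothesis, a$labels)
  R <- block_correlation(midx, spec$rho_w, spec$rho_b)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) abort_floramod("implied block correlation is not positive definite")
  Lr <- t(chol(R)) * spec$within_sd

  n_sp <- length(a$specimen_id)
  with_seed(seed, {
    nper <- spec$specimens_per_species
    if (is.null(nper)) {
      nper <- pmin(1 + stats::rgeom(n_sp, prob = 1 / 4.57), 29)
    } else {
      nper <- rep_len(nper, n_sp)
    }
    if (any(nper < 1)) abort_floramod("specimens_per_species must be >= 1")
    total <- sum(nper)
    coords <- array(NA_real_, c(total, p, 3))
    specimen_id <- character(total); species_id <- character(total); group <- character(total)
    row <- 1
    for (s in seq_len(n_sp)) {
      mu <- as.vector(t(a$coords[s, , ]))
      for (k in seq_len(nper[s])) {
        dev <- as.vector(Lr %*% stats::rnorm(3 * p))
        cfg <- matrix(mu + dev, p, 3, byrow = TRUE)
        if (isTRUE(spec$nuisance)) {
          rot <- random_rotation()
          scl <- exp(stats::runif(1, log(0.5), log(2)))
          trn <- stats::runif(3, -0.5, 0.5)
          cfg <- sweep(scl * (cfg %*% rot), 2, trn, "+")
        }
        coords[row, , ] <- cfg
        specimen_id[row] <- sprintf("%s_%02d", a$specimen_id[s], k)
        species_id[row] <- a$species_id[s]
        group[row] <- a$group[s]
        row <- row + 1
      }
    }
    # missing-landmark injection
    if (spec$missing_fraction > 0) {
      n_dam <- round(spec$missing_fraction * total)
      damaged <- sample(total, n_dam)
      for (s in damaged) {
        k <- sample(seq(spec$missing_range[1], spec$missing_range[2]), 1)
        gone <- sample(p, k)
        coords[s, gone, ] <- NA_real_
      }
    }
  })
  out <- lm_table(coords, specimen_id, species_id, group, labels = a$labels)
  attr(out, "n_per_species") <- stats::setNames(nper, a$species_id)
  out
}

# 3p x 3p block correlation on landmark modules
block_correlation <- function(midx, rho_w, rho_b) {
  mod_j <- rep(midx, each = 3)
  R <- ifelse(outer(mod_j, mod_j, "=="), rho_w, rho_b)
  diag(R) <- 1
  R
}

#' Simulate a full synthetic dataset (tree, species means, specimens)
#'
#' @param spec A [sim_spec()].
#' @param seed RNG seed controlling every draw.
#' @return List with `table` (specimen [landmark_table()]), `tree`, `means`,
#'   `groups`, `spec`.
#' @export
simulate_flowers <- function(spec = sim_spec(), seed = 1) {
  with_seed(seed, {
    tree <- simulate_tree(spec$n_species)
    sm <- simulate_species_means(tree, spec)
    tab <- simulate_specimens(sm$means, spec)
  })
  list(table = tab, tree = tree, means = sm$means, groups = sm$groups, spec = spec)
}

#' Simulate a univariate trait under a shifted Ornstein-Uhlenbeck process
#'
#' Used as ground truth for [detect_shifts()]: the trait starts at the root
#' optimum `theta0` and is attracted with strength `alpha`; each entry of
#' `shifts` moves the optimum for the whole clade below a given edge.
#'
#' @param tree Ultrametric `phylo`.
#' @param alpha Attraction strength (> 0); `alpha = 0` gives Brownian motion.
#' @param sigma2 Diffusion rate.
#' @param theta0 Root optimum (and root state).
#' @param shifts Named numeric vector: names are edge indices into
#'   `tree$edge`, values the new optimum below that edge.
#' @param seed Optional RNG seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_ou_trait <- function(tree, alpha, sigma2, theta0 = 0, shifts = NULL, seed = NULL) {
  ntip <- length(tree$tip.label)
  states <- rep(NA_real_, ntip + tree$Nnode)
  states[ntip + 1] <- theta0
  # optimum per edge: inherit from parent edge, overridden at shift edges
  theta_edge <- rep(theta0, nrow(tree$edge))
  pre <- preorder_edges(tree)
  if (!is.null(shifts)) {
    idx <- as.integer(names(shifts))
    parent_of <- match(tree$edge[, 1], tree$edge[, 2])  # edge above each edge's parent node
    for (e in pre) {
      pe <- parent_of[e]
      if (!is.na(pe)) theta_edge[e] <- theta_edge[pe]
      hit <- match(e, idx)
      if (!is.na(hit)) theta_edge[e] <- shifts[hit]
    }
  }
  with_seed(seed, {
    for (e in pre) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]; t_e <- tree$edge.length[e]
      th <- theta_edge[e]
      if (alpha > 0) {
        mu <- th + (states[par] - th) * exp(-alpha * t_e)
        v <- sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * t_e))
      } else {
        mu <- states[par]; v <- sigma2 * t_e
      }
      states[child] <- stats::rnorm(1, mu, sqrt(v))
    }
  })
  stats::setNames(states[seq_len(ntip)], tree$tip.label)
}
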