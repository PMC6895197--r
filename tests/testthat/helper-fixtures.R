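# shared fixture builders; everything is generated in code

# two-module hypothesis on p landmarks (first half / second half)
two_module_hyp <- function(p, name = "AB") {
  half <- floor(p / 2)
  module_hypothesis(name, setNames(rep(c("A", "B"), c(half, p - half)),
                                   as.character(seq_len(p))))
}

# n specimens drawn from a 3p-dimensional normal with landmark-block
# correlation (rho_w within modules, rho_b between); common frame, no
# nuisance transforms -- the covariance structure the CR test sees directly
block_mvn <- function(n, p, hyp, rho_w, rho_b, sd = 1) {
  midx <- match(unname(hyp$assignment[as.character(seq_len(p))]), hyp$module_names)
  modj <- rep(midx, each = 3)
  R <- ifelse(outer(modj, modj, "=="), rho_w, rho_b)
  diag(R) <- 1
  t(t(chol(R)) %*% matrix(rnorm(3 * p * n), 3 * p, n)) * sd
}

# landmark table of n specimens around a fixed non-degenerate configuration
toy_table <- function(n, p, sd = 0.05, species = rep("sp1", n), group = rep("", n)) {
  base <- floramod:::base_configuration(p, rep(1, p))
  arr <- array(0, c(n, p, 3))
  for (s in seq_len(n)) arr[s, , ] <- base + matrix(rnorm(3 * p, 0, sd), p, 3)
  floramod:::lm_table(arr, sprintf("s%02d", seq_len(n)), species, group,
                      as.character(seq_len(p)))
}

# independent brute-force CR oracle working directly on a covariance matrix
cr_oracle <- function(S, midx) {
  p <- length(midx)
  stopifnot(nrow(S) == 3 * p)
  Sz <- S; diag(Sz) <- 0
  dims_of <- function(mod) {
    ks <- which(midx == mod)
    as.vector(vapply(ks, function(k) (3 * k - 2):(3 * k), numeric(3)))
  }
  mods <- sort(unique(midx))
  pairs <- utils::combn(mods, 2)
  crs <- apply(pairs, 2, function(ab) {
    A <- dims_of(ab[1]); B <- dims_of(ab[2])
    Sab <- S[A, B, drop = FALSE]
    Saa <- Sz[A, A, drop = FALSE]; Sbb <- Sz[B, B, drop = FALSE]
    sqrt(sum(Sab^2) / sqrt(sum(Saa^2) * sum(Sbb^2)))
  })
  mean(crs)
}

# full-Procrustes mean oracle: iterative SVD-based mean of unit-size centered
# configurations (independent of the package's gpa() code path)
procrustes_mean_oracle <- function(cfgs, iter = 200) {
  norm1 <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  cfgs <- lapply(cfgs, norm1)
  mu <- cfgs[[1]]
  for (i in seq_len(iter)) {
    rot <- lapply(cfgs, function(x) {
      s <- svd(crossprod(x, mu))
      R <- s$u %*% t(s$v)
      if (det(R) < 0) { u <- s$u; u[, 3] <- -u[, 3]; R <- u %*% t(s$v) }
      x %*% R
    })
    mu_new <- norm1(Reduce(`+`, rot) / length(rot))
    if (sum((mu_new - mu)^2) < 1e-24) { mu <- mu_new; break }
    mu <- mu_new
  }
  mu
}

# procrustes distance up to rotation/reflection-free alignment
shape_distance <- function(x, y) {
  norm1 <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  x <- norm1(x); y <- norm1(y)
  s <- svd(crossprod(x, y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { u <- s$u; u[, 3] <- -u[, 3]; R <- u %*% t(s$v) }
  sqrt(sum((x %*% R - y)^2))
}
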