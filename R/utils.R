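# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_floramod <- function(msg, class = "floramod_error") {
  rlang::abort(msg, class = class)
}

# set RNG state only when a seed is supplied
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  expr
}

# centroid size of a p x 3 configuration
centroid_size <- function(x) {
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

# flatten n x p x 3 array to n x 3p, landmark-major (L1x,L1y,L1z,L2x,...)
flatten_coords <- function(arr) {
  n <- dim(arr)[1]; p <- dim(arr)[2]
  out <- matrix(0, n, 3 * p)
  for (k in seq_len(p)) out[, (3 * k - 2):(3 * k)] <- arr[, k, ]
  out
}

unflatten_coords <- function(mat, p) {
  n <- nrow(mat)
  arr <- array(0, dim = c(n, p, 3))
  for (k in seq_len(p)) arr[, k, ] <- mat[, (3 * k - 2):(3 * k)]
  arr
}

# uniform proper rotation in SO(3)
random_rotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 3] <- -q[, 3]
    if (abs(det(q) - 1) < 1e-8) return(q)
  }
}

is_complete_tbl <- function(tbl) !any(is.na(tbl$x) | is.na(tbl$y) | is.na(tbl$z))
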