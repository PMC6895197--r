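#' Congruence-coefficient correlation matrix of landmarks
#'
#' For each specimen, each landmark's deviation vector is its aligned position
#' minus the consensus position. The congruence coefficient of landmarks i and
#' j is the cosine-type correlation of their deviation fields across
#' specimens: `sum_s d_si . d_sj / sqrt(sum_s |d_si|^2 sum_s |d_sj|^2)`.
#'
#' @param x A [gpa()] fit or an aligned complete [landmark_table()].
#' @return A `congruence_matrix`: p x p matrix with unit diagonal, carrying
#'   the specimen count as attribute `"N"`.
#' @export
congruence_matrix <- function(x) {
  if (inherits(x, "gpa_fit")) {
    arr <- x$aligned; cons <- x$consensus; labels <- x$labels
  } else {
    a <- lm_array(x)
    if (any(a$mask)) abort_floramod("missing landmarks present")
    arr <- a$coords; labels <- a$labels
    cons <- apply(arr, c(2, 3), mean)
  }
  n <- dim(arr)[1]; p <- dim(arr)[2]
  if (n < 4) abort_floramod("need at least 4 specimens")
  # D[s, k, ] = deviation of landmark k in specimen s
  R <- matrix(0, p, p, dimnames = list(labels, labels))
  Dx <- arr[, , 1] - matrix(cons[, 1], n, p, byrow = TRUE)
  Dy <- arr[, , 2] - matrix(cons[, 2], n, p, byrow = TRUE)
  Dz <- arr[, , 3] - matrix(cons[, 3], n, p, byrow = TRUE)
  G <- crossprod(Dx) + crossprod(Dy) + crossprod(Dz)   # sum_s d_si . d_sj
  norms <- diag(G)
  if (any(norms <= 0)) {
    abort_floramod(paste0("landmark with zero total deviation: ",
                          labels[which(norms <= 0)[1]]))
  }
  R <- G / sqrt(outer(norms, norms))
  structure(R, N = n, class = c("congruence_matrix", "matrix", "array"))
}

#' Build the correlation-model set for EMMLi
#'
#' For each modularity hypothesis, sub-models are generated from the grammar
#' \{within-module rho: single shared | one per module\} x \{between-module
#' rho: single shared | one per module pair\}; models inducing identical
#' partitions of the p(p-1)/2 landmark-pair cells are deduplicated (for a
#' two-module hypothesis the two between-rho variants coincide), and a
#' no-modularity null (one rho for every cell) is appended. The five floral
#' hypotheses (module counts 4, 2, 2, 2, 3) plus the null give 15 models.
#'
#' @param hypotheses List of [module_hypothesis()] objects sharing one
#'   landmark set.
#' @return An `emmli_models` list; each element has `name`, `hypothesis`,
#'   `within`, `between`, and `classes`, a p x p matrix of cell-class labels.
#' @export
build_model_set <- function(hypotheses) {
  if (inherits(hypotheses, "module_hypothesis")) hypotheses <- list(hypotheses)
  if (length(hypotheses) < 1) abort_floramod("need at least one hypothesis")
  labels <- sort(names(hypotheses[[1]]$assignment))
  models <- list()
  canon <- character(0)
  add_model <- function(name, hyp_name, within, between, classes) {
    cells <- classes[upper.tri(classes)]
    key <- paste(match(cells, unique(cells)), collapse = ",")
    if (key %in% canon) return(invisible(NULL))
    canon <<- c(canon, key)
    models[[length(models) + 1]] <<- list(
      name = name, hypothesis = hyp_name, within = within, between = between,
      classes = classes)
    invisible(NULL)
  }
  for (h in hypotheses) {
    if (length(h$module_names) < 2) abort_floramod("hypotheses need >= 2 modules")
    if (!setequal(names(h$assignment), labels)) {
      abort_floramod("hypotheses must share one landmark set")
    }
    midx <- h$assignment[labels]
    for (wtype in c("single", "per-module")) {
      for (btype in c("single", "per-pair")) {
        cls <- matrix("", length(labels), length(labels),
                      dimnames = list(labels, labels))
        for (i in seq_along(labels)) {
          for (j in seq_along(labels)) {
            mi <- midx[i]; mj <- midx[j]
            cls[i, j] <- if (mi == mj) {
              if (wtype == "single") "w" else paste0("w:", mi)
            } else {
              if (btype == "single") "b" else paste0("b:", paste(sort(c(mi, mj)), collapse = "~"))
            }
          }
        }
        add_model(sprintf("%s.%s.%s", h$name, wtype, btype), h$name, wtype, btype, cls)
      }
    }
  }
  null_cls <- matrix("r", length(labels), length(labels), dimnames = list(labels, labels))
  add_model("null", "null", "single", "single", null_cls)
  structure(models, class = "emmli_models", labels = labels)
}

#' @export
print.emmli_models <- function(x, ...) {
  cat(sprintf("<emmli_models: %d distinct models on %d landmarks>\n",
              length(x), length(attr(x, "labels"))))
  for (m in x) cat(" -", m$name, "\n")
  invisible(x)
}

#' Maximum-likelihood comparison of modularity models on a correlation matrix
#'
#' Each upper-triangle correlation is Fisher-transformed,
#' `z = atanh(r)`; under a model, all cells of a parameter class share one
#' correlation whose MLE is the class mean of z, and the log-likelihood is the
#' normal density of the cell z-values around their class means with fixed
#' variance `1/(N-3)`. Models are compared by the finite-sample corrected
#' AICc with `n_r = p(p-1)/2` cells and `K` = number of correlation classes,
#' and by Akaike weights ("posterior probabilities").
#'
#' @param corr A [congruence_matrix()] (or plain correlation matrix with
#'   attribute `"N"` = specimen count behind it).
#' @param models An `emmli_models` set from [build_model_set()].
#' @return An `emmli_fit` tibble: one row per model with `K`, `logL`, `AICc`,
#'   `dAICc`, `weight` and a list-column `rho` of class MLEs.
#' @export
emmli_fit <- function(corr, models) {
  N <- attr(corr, "N")
  if (is.null(N)) abort_floramod("correlation matrix lacks the specimen count attribute 'N'")
  if (N < 5) abort_floramod("need N >= 5 specimens behind the correlation matrix")
  labels <- attr(models, "labels")
  R <- unclass(corr)[labels, labels]
  ut <- upper.tri(R)
  r <- pmin(pmax(R[ut], -(1 - 1e-9)), 1 - 1e-9)
  z <- atanh(r)
  n_r <- length(z)
  sd_z <- sqrt(1 / (N - 3))
  rows <- lapply(models, function(m) {
    cls <- m$classes[ut]
    zhat <- tapply(z, cls, mean)
    K <- length(zhat)
    if (n_r - K - 1 <= 0) {
      abort_floramod(sprintf("model %s too rich: %d classes for %d cells", m$name, K, n_r))
    }
    logL <- sum(stats::dnorm(z, mean = zhat[cls], sd = sd_z, log = TRUE))
    aicc <- -2 * logL + 2 * K + 2 * K * (K + 1) / (n_r - K - 1)
    tibble::tibble(model = m$name, hypothesis = m$hypothesis, K = K,
                   logL = logL, AICc = aicc,
                   rho = list(tibble::tibble(class = names(zhat),
                                             rho = tanh(as.numeric(zhat)))))
  })
  out <- dplyr::bind_rows(rows)
  out$dAICc <- out$AICc - min(out$AICc)
  w <- exp(-out$dAICc / 2)
  out$weight <- w / sum(w)
  out <- out[order(out$AICc), c("model", "hypothesis", "K", "logL", "AICc", "dAICc", "weight", "rho")]
  class(out) <- c("emmli_fit", class(out))
  out
}
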