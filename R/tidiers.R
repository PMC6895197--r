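#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CR modularity test
#' @param x A `cr_test`.
#' @param ... Unused.
#' @return One-row tibble with `hypothesis`, `cr`, `p`, `z`, `nperm`, `n`.
#' @method tidy cr_test
#' @export
tidy.cr_test <- function(x, ...) {
  tibble::tibble(hypothesis = x$hypothesis, cr = x$cr, p = x$p, z = x$z,
                 nperm = x$nperm, n = x$n)
}

#' @rdname tidy.cr_test
#' @method glance cr_test
#' @export
glance.cr_test <- function(x, ...) tidy.cr_test(x)

#' @method tidy rate_comparison
#' @export
tidy.rate_comparison <- function(x, ...) x$rates

#' @method glance rate_comparison
#' @export
glance.rate_comparison <- function(x, ...) {
  tibble::tibble(hypothesis = x$hypothesis, ratio = x$ratio, p = x$p, nsim = x$nsim)
}

#' @method tidy shift_config
#' @export
tidy.shift_config <- function(x, ...) x$shifts

#' @method glance shift_config
#' @export
glance.shift_config <- function(x, ...) {
  tibble::tibble(n_shifts = x$n_shifts, alpha = x$alpha, sigma2 = x$sigma2,
                 theta_root = x$theta_root, bic = x$bic, bic_null = x$bic_null,
                 n_convergent_groups = length(x$convergent))
}

#' @method tidy emmli_fit
#' @export
tidy.emmli_fit <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  dplyr::select(out, -"rho")
}

#' @method glance emmli_fit
#' @export
glance.emmli_fit <- function(x, ...) {
  tibble::tibble(best_model = x$model[1], best_hypothesis = x$hypothesis[1],
                 best_AICc = x$AICc[1], best_weight = x$weight[1], n_models = nrow(x))
}

#' @method tidy imputation_report
#' @export
tidy.imputation_report <- function(x, ...) x$landmarks

#' @method glance imputation_report
#' @export
glance.imputation_report <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$replicates, .data$method),
                   mean_correlation = mean(.data$correlation),
                   prop_p_le_05 = mean(.data$p <= 0.05),
                   mean_error = mean(.data$mean_error), .groups = "drop")
}

#' @method tidy observer_error
#' @export
tidy.observer_error <- function(x, ...) x$landmarks

#' @method glance observer_error
#' @export
glance.observer_error <- function(x, ...) x$summary

#' @method tidy gpa_fit
#' @export
tidy.gpa_fit <- function(x, ...) {
  tibble::tibble(specimen_id = x$specimen_id, species_id = x$species_id,
                 group = x$group, centroid_size = x$centroid_sizes)
}

#' @method glance gpa_fit
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(n = dim(x$aligned)[1], p = dim(x$aligned)[2],
                 iterations = x$iterations, converged = x$converged)
}

#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) x$scores

#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
                 pct_variance = x$pct_variance)
}

# --- plots -------------------------------------------------------------------

#' Plot shape space
#' @param object A `shape_pca`.
#' @param axes Two axes to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, axes = c(1, 2), ...) {
  nm <- paste0("PC", axes)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                               colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", nm[1], object$pct_variance[axes[1]]),
      y = sprintf("%s (%.1f%%)", nm[2], object$pct_variance[axes[2]])) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null of a CR test
#' @param object A `cr_test`.
#' @param ... Unused.
#' @return A ggplot: permutation CR distribution with the observed value.
#' @method autoplot cr_test
#' @export
autoplot.cr_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(cr = object$perm), ggplot2::aes(x = .data$cr)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$cr, colour = "red") +
    ggplot2::labs(x = "CR under landmark permutation",
                  subtitle = sprintf("%s: CR = %.3f, p = %.3g, Z = %.2f",
                                     object$hypothesis, object$cr, object$p, object$z)) +
    ggplot2::theme_minimal()
}

#' @method autoplot emmli_fit
#' @export
autoplot.emmli_fit <- function(object, ...) {
  df <- tidy.emmli_fit(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot trait_model_fits
#' @export
autoplot.trait_model_fits <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(y = "Akaike weight") +
    ggplot2::theme_minimal()
}
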