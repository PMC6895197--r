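#' Modularity hypotheses
#'
#' A modularity hypothesis is a named partition of the landmark set into two
#' or more non-empty modules. `module_hypothesis()` builds and validates one;
#' `merianieae_hypotheses()` returns the five built-in floral hypotheses
#' (developmental whorls H1; functional partitions H2-H5) on the standard
#' 37-landmark scheme: 1-10 stamen appendage tips, 11-20 appendage bases,
#' 21-30 anther pores, 31 style base, 32 stigma, 33-37 petal tips.
#'
#' @param name Hypothesis name, e.g. `"H4"`.
#' @param assignment Named character vector mapping each landmark label to a
#'   module name; every landmark appears exactly once.
#' @return A `module_hypothesis`: list with `name`, `assignment`,
#'   `module_names`.
#' @examples
#' h <- module_hypothesis("toy", c(`1` = "A", `2` = "A", `3` = "B", `4` = "B"))
#' h$module_names
#' @export
module_hypothesis <- function(name, assignment) {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  if (anyDuplicated(names(assignment)) > 0) {
    dup <- names(assignment)[duplicated(names(assignment))][1]
    abort_floramod(paste0("landmark ", dup, " assigned more than once"))
  }
  modules <- unique(unname(assignment))
  if (length(modules) < 2) abort_floramod("a hypothesis needs at least 2 modules")
  if (any(table(assignment) < 1)) abort_floramod("every module must be non-empty")
  structure(
    list(name = as.character(name), assignment = assignment, module_names = modules),
    class = "module_hypothesis"
  )
}

#' @export
print.module_hypothesis <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$module_names))
  cat(sprintf("<module_hypothesis %s: %s>\n", x$name,
              paste(sprintf("%s(%d)", names(sizes), sizes), collapse = " + ")))
  invisible(x)
}

# check that a hypothesis covers exactly the given landmark labels
validate_hypothesis <- function(hyp, labels) {
  unassigned <- setdiff(labels, names(hyp$assignment))
  if (length(unassigned) > 0) {
    abort_floramod(paste0("landmark ", unassigned[1], " unassigned in hypothesis ", hyp$name))
  }
  extra <- setdiff(names(hyp$assignment), labels)
  if (length(extra) > 0) {
    abort_floramod(paste0("hypothesis ", hyp$name, " assigns unknown landmark ", extra[1]))
  }
  invisible(hyp)
}

# integer module index (1..m) per landmark label, in label order
module_index <- function(hyp, labels) {
  validate_hypothesis(hyp, labels)
  match(unname(hyp$assignment[labels]), hyp$module_names)
}

#' @rdname module_hypothesis
#' @param whorl1 Integer stamen indices (subset of 1:10) making up the first
#'   stamen whorl of the developmental hypothesis H1; membership of the two
#'   whorls is morphology the landmark scheme itself does not encode, so it is
#'   user-configurable. Defaults to stamens 1-5.
#' @return `merianieae_hypotheses()`: named list of five `module_hypothesis`
#'   objects H1-H5.
#' @export
merianieae_hypotheses <- function(whorl1 = 1:5) {
  stopifnot(all(whorl1 %in% 1:10), length(whorl1) >= 1, length(whorl1) <= 9)
  whorl2 <- setdiff(1:10, whorl1)
  lab <- as.character
  stamen_landmarks <- function(idx) lab(c(idx, idx + 10, idx + 20))
  petals <- lab(33:37)
  appendages <- lab(1:20)
  pore_stigma <- lab(21:32)
  carpel <- lab(31:32)

  assign_from <- function(...) {
    parts <- list(...)
    out <- unlist(lapply(names(parts), function(m) {
      stats::setNames(rep(m, length(parts[[m]])), parts[[m]])
    }))
    out[order(as.integer(names(out)))]
  }

  list(
    H1 = module_hypothesis("H1", assign_from(
      petals = petals,
      stamen_whorl1 = stamen_landmarks(whorl1),
      stamen_whorl2 = stamen_landmarks(whorl2),
      carpel = carpel
    )),
    H2 = module_hypothesis("H2", assign_from(
      attraction = petals, reproduction = lab(1:32)
    )),
    H3 = module_hypothesis("H3", assign_from(
      attraction = c(appendages, petals), efficiency = pore_stigma
    )),
    H4 = module_hypothesis("H4", assign_from(
      attraction = appendages, efficiency = c(pore_stigma, petals)
    )),
    H5 = module_hypothesis("H5", assign_from(
      corolla = petals, appendages = appendages, efficiency = pore_stigma
    ))
  )
}
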