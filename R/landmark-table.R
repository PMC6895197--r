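#' Landmark tables
#'
#' A landmark table is the package's central data container: a long-format
#' tibble with one row per specimen x landmark, columns `specimen_id`,
#' `species_id`, `group`, `landmark`, `x`, `y`, `z`. A landmark whose three
#' coordinate cells are all `NA` is *missing* (e.g. a broken petal tip that
#' could not be digitized); partial `NA` triples are rejected. All specimens
#' must carry the same ordered set of at least four landmark labels.
#'
#' @param df A data frame with the columns above. `group` may be omitted and
#'   defaults to `""`.
#' @param landmark_labels Optional character vector fixing the landmark order;
#'   defaults to order of first appearance.
#' @return A `landmark_tbl` (subclass of `tbl_df`).
#' @examples
#' df <- tidyr::expand_grid(specimen_id = c("s1", "s2"), landmark = as.character(1:4))
#' df$species_id <- "spA"; df$group <- ""
#' df$x <- rnorm(8); df$y <- rnorm(8); df$z <- rnorm(8)
#' landmark_table(df)
#' @export
landmark_table <- function(df, landmark_labels = NULL) {
  stopifnot(is.data.frame(df))
  needed <- c("specimen_id", "species_id", "landmark", "x", "y", "z")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    abort_floramod(paste0("landmark table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"group" %in% names(df)) df$group <- ""
  df <- tibble::as_tibble(df)[, c("specimen_id", "species_id", "group", "landmark", "x", "y", "z")]
  df$specimen_id <- as.character(df$specimen_id)
  df$species_id <- as.character(df$species_id)
  df$group <- as.character(df$group)
  df$landmark <- as.character(df$landmark)

  labels <- landmark_labels %||% unique(df$landmark)
  if (length(labels) < 4) abort_floramod("at least 4 landmarks are required")
  if (!setequal(labels, unique(df$landmark))) {
    abort_floramod("landmark_labels do not match the landmarks present in the data")
  }

  # every specimen must have exactly one row per label
  counts <- table(df$specimen_id)
  bad <- names(counts)[counts != length(labels)]
  if (length(bad) > 0) {
    abort_floramod(paste0(
      "specimen(s) with inconsistent landmark count: ", paste(bad, collapse = ", ")
    ), class = "floramod_format_error")
  }
  key <- paste(df$specimen_id, df$landmark)
  if (anyDuplicated(key) > 0) {
    abort_floramod("duplicated specimen/landmark rows", class = "floramod_format_error")
  }

  na3 <- is.na(df$x) + is.na(df$y) + is.na(df$z)
  if (any(na3 %in% c(1, 2))) {
    abort_floramod("landmarks must be fully observed or fully missing (all of x,y,z NA)")
  }
  obs <- na3 == 0
  if (any(!is.finite(c(df$x[obs], df$y[obs], df$z[obs])))) {
    abort_floramod("non-finite coordinate in an observed landmark")
  }

  sp_map <- unique(df[, c("specimen_id", "species_id")])
  if (anyDuplicated(sp_map$specimen_id) > 0) {
    abort_floramod("a specimen_id maps to more than one species_id")
  }

  # canonical ordering: specimens in first-appearance order, landmarks in label order
  spec_order <- unique(df$specimen_id)
  df <- df[order(match(df$specimen_id, spec_order), match(df$landmark, labels)), ]
  structure(df,
    landmark_labels = labels,
    class = c("landmark_tbl", class(tibble::tibble()))
  )
}

#' @export
print.landmark_tbl <- function(x, ...) {
  n <- length(unique(x$specimen_id))
  p <- length(attr(x, "landmark_labels"))
  nmiss <- sum(is.na(x$x))
  cat(sprintf(
    "<landmark_tbl: %d specimens x %d landmarks, %d species, %d missing landmark(s)>\n",
    n, p, length(unique(x$species_id)), nmiss
  ))
  NextMethod()
}

#' Landmark labels of a landmark table
#' @param tbl A `landmark_tbl`.
#' @return Character vector of ordered landmark labels.
#' @export
landmark_labels <- function(tbl) {
  attr(tbl, "landmark_labels") %||% unique(tbl$landmark)
}

# --- array view ---------------------------------------------------------------

# Convert landmark_tbl to list(coords = n x p x 3 array, mask = n x p logical,
# specimen_id, species_id, group, labels). Missing landmarks are NA in coords.
lm_array <- function(tbl) {
  labels <- landmark_labels(tbl)
  specs <- unique(tbl$specimen_id)
  n <- length(specs); p <- length(labels)
  ord <- order(match(tbl$specimen_id, specs), match(tbl$landmark, labels))
  tbl <- tbl[ord, ]
  coords <- array(NA_real_, dim = c(n, p, 3),
                  dimnames = list(specs, labels, c("x", "y", "z")))
  coords[, , 1] <- matrix(tbl$x, n, p, byrow = TRUE)
  coords[, , 2] <- matrix(tbl$y, n, p, byrow = TRUE)
  coords[, , 3] <- matrix(tbl$z, n, p, byrow = TRUE)
  mask <- is.na(coords[, , 1, drop = TRUE])
  if (n == 1) mask <- matrix(mask, 1, p)
  meta <- tbl[match(specs, tbl$specimen_id), c("specimen_id", "species_id", "group")]
  list(coords = coords, mask = mask, specimen_id = specs,
       species_id = meta$species_id, group = meta$group, labels = labels)
}

# inverse of lm_array
lm_table <- function(coords, specimen_id, species_id, group = NULL, labels = NULL) {
  n <- dim(coords)[1]; p <- dim(coords)[2]
  labels <- labels %||% dimnames(coords)[[2]] %||% as.character(seq_len(p))
  group <- group %||% rep("", n)
  df <- tibble::tibble(
    specimen_id = rep(specimen_id, each = p),
    species_id = rep(species_id, each = p),
    group = rep(group, each = p),
    landmark = rep(labels, times = n),
    x = as.vector(t(coords[, , 1])),
    y = as.vector(t(coords[, , 2])),
    z = as.vector(t(coords[, , 3]))
  )
  landmark_table(df, landmark_labels = labels)
}
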