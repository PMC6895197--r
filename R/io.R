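#' Read and write landmark data
#'
#' Two plain-text dialects are supported. `"csv"` is a long-format table with
#' header `specimen_id,species_id,group,landmark,x,y,z`; a missing landmark has
#' empty coordinate cells. `"tps3"` is the 3D analogue of the classical TPS
#' landmark file: per specimen a `LM3=<p>` line, p lines of three
#' whitespace-separated reals (missing landmarks as three `NaN` tokens), then
#' `ID=<specimen>` plus optional `SPECIES=` / `GROUP=` metadata lines.
#'
#' @param path File path.
#' @param format `"csv"` or `"tps3"`. Guessed from the extension when missing.
#' @return `read_landmarks()`: a [landmark_table()].
#' @export
read_landmarks <- function(path, format = c("csv", "tps3")) {
  if (!file.exists(path)) abort_floramod(paste0("file not found: ", path))
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (format == "csv") read_landmarks_csv(path) else read_landmarks_tps3(path)
}

guess_format <- function(path) {
  if (grepl("\\.tps3?$", path, ignore.case = TRUE)) "tps3" else "csv"
}

read_landmarks_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  needed <- c("specimen_id", "species_id", "group", "landmark", "x", "y", "z")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) abort_floramod(paste0("csv lacks column(s): ", paste(miss, collapse = ", ")))
  for (col in c("x", "y", "z")) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num) & toupper(raw) != "NAN")
    if (length(bad) > 0) {
      abort_floramod(sprintf("non-numeric %s value '%s' at data line %d", col, raw[bad[1]], bad[1] + 1),
                     class = "floramod_parse_error")
    }
    num[!is.na(raw) & toupper(raw) == "NAN"] <- NA_real_
    df[[col]] <- num
  }
  df$group[is.na(df$group)] <- ""
  landmark_table(df)
}

read_landmarks_tps3 <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  recs <- list(); i <- 1; n_line <- length(lines)
  while (i <= n_line) {
    if (lines[i] == "") { i <- i + 1; next }
    if (!grepl("^LM3=", lines[i])) {
      abort_floramod(sprintf("expected 'LM3=' at line %d", i), class = "floramod_parse_error")
    }
    p <- as.integer(sub("^LM3=", "", lines[i])); i <- i + 1
    coords <- matrix(NA_real_, p, 3)
    for (k in seq_len(p)) {
      toks <- strsplit(lines[i], "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) != 3 || (any(is.na(vals)) && !all(toupper(toks) == "NAN"))) {
        abort_floramod(sprintf("bad coordinate row at line %d: '%s'", i, lines[i]),
                       class = "floramod_parse_error")
      }
      coords[k, ] <- vals
      i <- i + 1
    }
    id <- species <- NULL; grp <- ""
    while (i <= n_line && grepl("^(ID|SPECIES|GROUP)=", lines[i])) {
      key <- sub("=.*$", "", lines[i]); val <- sub("^[A-Z]+=", "", lines[i])
      if (key == "ID") id <- val
      if (key == "SPECIES") species <- val
      if (key == "GROUP") grp <- val
      i <- i + 1
    }
    if (is.null(id)) abort_floramod("tps3 record without ID=", class = "floramod_parse_error")
    recs[[length(recs) + 1]] <- list(id = id, species = species %||% id, group = grp,
                                     coords = coords)
  }
  if (length(recs) == 0) abort_floramod("empty tps3 file", class = "floramod_parse_error")
  ps <- vapply(recs, function(r) nrow(r$coords), integer(1))
  if (length(unique(ps)) != 1) {
    counts <- table(ps)
    majority <- as.integer(names(counts)[which.max(counts)])
    bad <- recs[[which(ps != majority)[1]]]$id
    abort_floramod(paste0("inconsistent landmark count for specimen ", bad),
                   class = "floramod_format_error")
  }
  p <- ps[1]
  coords <- array(NA_real_, c(length(recs), p, 3))
  for (s in seq_along(recs)) coords[s, , ] <- recs[[s]]$coords
  lm_table(coords,
           specimen_id = vapply(recs, `[[`, "", "id"),
           species_id = vapply(recs, `[[`, "", "species"),
           group = vapply(recs, `[[`, "", "group"),
           labels = as.character(seq_len(p)))
}

#' @rdname read_landmarks
#' @param tbl A [landmark_table()].
#' @return `write_landmarks()`: `path`, invisibly.
#' @export
write_landmarks <- function(tbl, path, format = c("csv", "tps3")) {
  tbl <- landmark_table(tbl, landmark_labels = landmark_labels(tbl))
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (format == "csv") {
    out <- tbl
    for (col in c("x", "y", "z")) out[[col]] <- num17(out[[col]])
    readr::write_csv(out, path, na = "")
  } else {
    a <- lm_array(tbl)
    p <- length(a$labels)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (s in seq_along(a$specimen_id)) {
      writeLines(paste0("LM3=", p), con)
      rows <- apply(a$coords[s, , , drop = FALSE][1, , ], 1, function(v) {
        paste(ifelse(is.na(v), "NaN", num17(v)), collapse = " ")
      })
      writeLines(rows, con)
      writeLines(paste0("ID=", a$specimen_id[s]), con)
      writeLines(paste0("SPECIES=", a$species_id[s]), con)
      if (nzchar(a$group[s])) writeLines(paste0("GROUP=", a$group[s]), con)
    }
  }
  invisible(path)
}

num17 <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) NA_character_ else sprintf("%.17g", v), "")
  out
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Newick file path.
#' @param species Optional character vector of tip labels; the tree is pruned
#'   to exactly this set and an error lists any absent species.
#' @param ultrametric_tol Relative tolerance on the root-to-tip depth spread
#'   before a non-ultrametry warning is issued.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path, species = NULL, ultrametric_tol = 1e-6) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort_floramod(paste0("could not parse Newick in ", path))
  check_tree(tr, species = NULL, ultrametric_tol = ultrametric_tol)
  if (!is.null(species)) tr <- prune_tree(tr, species, ultrametric_tol)
  tr
}

check_tree <- function(tr, species = NULL, ultrametric_tol = 1e-6) {
  if (is.null(tr$edge.length)) abort_floramod("tree has no branch lengths")
  if (any(tr$edge.length < 0)) abort_floramod("negative branch length in tree")
  if (anyDuplicated(tr$tip.label) > 0) abort_floramod("duplicate tip labels in tree")
  if (!is.null(species)) {
    absent <- setdiff(species, tr$tip.label)
    if (length(absent) > 0) {
      abort_floramod(paste0("species absent from tree: ", paste(absent, collapse = ", ")))
    }
  }
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  spread <- diff(range(depths))
  if (spread > ultrametric_tol * max(depths)) {
    warning(sprintf("tree is not ultrametric (depth spread %.3g over depth %.3g)",
                    spread, max(depths)))
  }
  invisible(tr)
}

#' @rdname read_tree
#' @param tree A `phylo` object.
#' @export
prune_tree <- function(tree, species, ultrametric_tol = 1e-6) {
  check_tree(tree, species, ultrametric_tol)
  ape::keep.tip(tree, species)
}

#' Read modularity hypotheses from a YAML module map
#'
#' The config lists hypotheses, each a mapping of module names to landmark
#' labels, e.g.
#' ```yaml
#' hypotheses:
#'   - name: H2
#'     modules:
#'       attraction: ["33", "34", "35", "36", "37"]
#'       reproduction: ["1", "2", ...]
#' ```
#'
#' @param path YAML file path.
#' @param labels Optional landmark labels to validate each hypothesis against
#'   (unassigned or doubly assigned landmarks raise an error naming them).
#' @return Named list of [module_hypothesis()] objects.
#' @export
read_module_map <- function(path, labels = NULL) {
  cfg <- yaml::read_yaml(path)
  hyps <- cfg$hypotheses %||% cfg
  out <- lapply(hyps, function(h) {
    stopifnot(!is.null(h$name), !is.null(h$modules))
    assignment <- unlist(lapply(names(h$modules), function(m) {
      lmks <- as.character(unlist(h$modules[[m]]))
      stats::setNames(rep(m, length(lmks)), lmks)
    }))
    hyp <- module_hypothesis(h$name, assignment)
    if (!is.null(labels)) validate_hypothesis(hyp, labels)
    hyp
  })
  stats::setNames(out, vapply(out, function(h) h$name, ""))
}
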