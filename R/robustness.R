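# one resampling replicate: GPA the drawn specimens and run the requested
# analyses; returns a list of per-analysis records. `seed` is held constant
# across replicates so identical draws give identical results
run_rep_analyses <- function(tab, tree, hypotheses, analyses, nperm, rep_id,
                             seed = NULL) {
  fit <- gpa(tab)
  means <- species_means(fit)
  groups <- split(unique(tab$specimen_id),
                  tab$group[match(unique(tab$specimen_id), tab$specimen_id)])
  out <- list()
  if ("modularity" %in% analyses) {
    rows <- list()
    for (g in names(groups)) {
      keep <- fit$specimen_id %in% groups[[g]]
      if (sum(keep) < 3) next
      sub <- fit$aligned[keep, , , drop = FALSE]
      Y <- flatten_coords(sub)
      for (h in hypotheses) {
        ct <- modularity_test(Y, h, nperm = nperm, seed = seed)
        rows[[length(rows) + 1]] <- tibble::tibble(
          rep = rep_id, group = g, hypothesis = h$name,
          cr = ct$cr, p = ct$p, z = ct$z)
      }
    }
    out$modularity <- dplyr::bind_rows(rows)
  }
  if ("emmli" %in% analyses) {
    models <- build_model_set(hypotheses)
    cm <- congruence_matrix(fit)
    ef <- emmli_fit(cm, models)
    out$emmli <- tibble::tibble(rep = rep_id, best_model = ef$model[1],
                                best_hypothesis = ef$hypothesis[1],
                                weight = ef$weight[1])
  }
  if (!is.null(tree)) {
    if ("kmult" %in% analyses) {
      km <- kmult(means, tree, nperm = nperm, seed = seed)
      out$kmult <- tibble::tibble(rep = rep_id, k_mult = km$k_mult, p = km$p)
    }
    if ("rates" %in% analyses) {
      h <- hypotheses[[1]]
      mr <- module_rates(means, tree, h, nsim = nperm, seed = seed)
      out$rates <- tibble::tibble(
        rep = rep_id, hypothesis = h$name,
        fastest = mr$rates$module[which.max(mr$rates$sigma2)],
        ratio = mr$ratio, p = mr$p)
    }
    if ("fitmodels" %in% analyses || "shifts" %in% analyses) {
      pc <- shape_pca(means)
      tr1 <- stats::setNames(pc$scores$PC1, pc$scores$species_id)
      if ("fitmodels" %in% analyses) {
        tf <- fit_trait_models(tree, tr1)
        out$fitmodels <- tibble::tibble(rep = rep_id,
                                        best_model = tf$model[which.min(tf$AICc)])
      }
      if ("shifts" %in% analyses) {
        sc <- detect_shifts(tree, tr1)
        shifted <- shifted_species(tree, sc)
        out$shifts <- tibble::tibble(rep = rep_id, n_shifts = sc$n_shifts,
                                     species = list(shifted))
      }
    }
  }
  out
}

shifted_species <- function(tree, sc) {
  if (sc$n_shifts == 0) return(character(0))
  dt <- descendant_tips(tree)
  unique(tree$tip.label[unlist(dt[sc$shifts$child_node])])
}

summarize_reps <- function(records, nreps) {
  out <- list(nreps = nreps)
  mod <- dplyr::bind_rows(purrr::map(records, "modularity"))
  if (nrow(mod) > 0) {
    out$modularity <- dplyr::summarise(
      dplyr::group_by(mod, .data$group, .data$hypothesis),
      mean_cr = mean(.data$cr), mean_p = mean(.data$p), mean_z = mean(.data$z),
      prop_significant = mean(.data$p <= 0.05), .groups = "drop")
  }
  em <- dplyr::bind_rows(purrr::map(records, "emmli"))
  if (nrow(em) > 0) {
    out$emmli <- dplyr::count(em, .data$best_model, .data$best_hypothesis,
                              name = "n_best")
  }
  km <- dplyr::bind_rows(purrr::map(records, "kmult"))
  if (nrow(km) > 0) {
    out$kmult <- dplyr::summarise(km, mean_k = mean(.data$k_mult),
                                  prop_significant = mean(.data$p <= 0.05))
  }
  rt <- dplyr::bind_rows(purrr::map(records, "rates"))
  if (nrow(rt) > 0) {
    out$rates <- dplyr::count(rt, .data$fastest, name = "n_fastest")
    out$rates_summary <- dplyr::summarise(rt, mean_ratio = mean(.data$ratio),
                                          prop_significant = mean(.data$p <= 0.05))
  }
  fm <- dplyr::bind_rows(purrr::map(records, "fitmodels"))
  if (nrow(fm) > 0) out$fitmodels <- dplyr::count(fm, .data$best_model, name = "n_best")
  sh <- dplyr::bind_rows(purrr::map(records, "shifts"))
  if (nrow(sh) > 0) {
    all_sp <- table(unlist(sh$species))
    out$shifts <- tibble::tibble(species = names(all_sp),
                                 prop_in_shifted_regime = as.numeric(all_sp) / nreps)
    out$shifts_summary <- dplyr::summarise(sh, mean_n_shifts = mean(.data$n_shifts))
  }
  out$records <- records
  structure(out, class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf("<resample_summary: %d replicate(s)>\n", x$nreps))
  for (nm in intersect(c("modularity", "emmli", "kmult", "rates", "fitmodels"), names(x))) {
    cat("--", nm, "--\n"); print(x[[nm]])
  }
  invisible(x)
}

#' Rarefaction harness: one specimen per species, repeated
#'
#' Draws one specimen per species uniformly at random, re-runs the requested
#' analyses on the rarefied dataset (a fresh Procrustes fit each time), and
#' summarizes results across replicates: mean CR/p/z and the proportion of
#' replicates significant at alpha = 0.05 per group and hypothesis, best-model
#' counts, fastest-module counts, and per-species shift-inclusion proportions.
#'
#' @param table Specimen [landmark_table()] (complete; impute first).
#' @param tree Rooted `phylo` or `NULL` (phylogenetic analyses then error if
#'   requested).
#' @param hypotheses List of [module_hypothesis()] objects.
#' @param analyses Subset of
#'   `c("modularity", "emmli", "kmult", "rates", "fitmodels", "shifts")`.
#' @param nreps Number of rarefaction replicates.
#' @param nperm Permutations/simulations inside each replicate's tests.
#' @param seed RNG seed.
#' @return A `resample_summary` (summaries plus all per-rep records).
#' @export
rarefy_run <- function(table, tree = NULL, hypotheses,
                       analyses = c("modularity", "emmli"),
                       nreps = 100, nperm = 199, seed = NULL) {
  need_tree <- intersect(analyses, c("kmult", "rates", "fitmodels", "shifts"))
  if (is.null(tree) && length(need_tree) > 0) {
    abort_floramod(paste0("analyses need a tree: ", paste(need_tree, collapse = ", ")))
  }
  a <- lm_array(table)
  if (any(a$mask)) abort_floramod("estimate missing landmarks before resampling")
  species <- unique(a$species_id)
  records <- vector("list", nreps)
  # draw all replicates first, then analyse each with the same test seed, so
  # identical draws always give identical results
  with_seed(seed, {
    picks <- lapply(seq_len(nreps), function(r) {
      vapply(species, function(sp) {
        ids <- a$specimen_id[a$species_id == sp]
        if (length(ids) == 1) ids else sample(ids, 1)
      }, "")
    })
  })
  for (r in seq_len(nreps)) {
    tab <- landmark_table(table[table$specimen_id %in% picks[[r]], ],
                          landmark_labels = a$labels)
    records[[r]] <- run_rep_analyses(tab, tree, hypotheses, analyses, nperm, r,
                                     seed = seed)
  }
  summarize_reps(records, nreps)
}

#' Down-sampling harness: a fraction of species per group, repeated
#'
#' Per replicate, samples `ceiling(fraction * n_g)` species (at least
#' `min_per_group`) within each group, one specimen each, and re-runs the
#' analyses as in [rarefy_run()].
#'
#' @inheritParams rarefy_run
#' @param fraction Fraction of species retained per group.
#' @param min_per_group Minimum species per group after rounding; groups
#'   smaller than this are an error.
#' @return A `resample_summary`.
#' @export
downsample_run <- function(table, tree = NULL, hypotheses,
                           analyses = c("modularity", "emmli"),
                           fraction = 0.5, min_per_group = 4,
                           nreps = 100, nperm = 199, seed = NULL) {
  a <- lm_array(table)
  if (any(a$mask)) abort_floramod("estimate missing landmarks before resampling")
  sp_grp <- unique(tibble::tibble(species = a$species_id, group = a$group))
  g_sizes <- table(sp_grp$group)
  if (any(g_sizes < min_per_group)) {
    abort_floramod(sprintf("group '%s' has fewer than min_per_group = %d species",
                           names(g_sizes)[which(g_sizes < min_per_group)[1]], min_per_group))
  }
  records <- vector("list", nreps)
  with_seed(seed, {
    picks <- lapply(seq_len(nreps), function(r) {
      keep_sp <- unlist(lapply(split(sp_grp$species, sp_grp$group), function(sp) {
        k <- max(min_per_group, ceiling(fraction * length(sp)))
        sample(sp, min(k, length(sp)))
      }))
      vapply(keep_sp, function(sp) {
        ids <- a$specimen_id[a$species_id == sp]
        if (length(ids) == 1) ids else sample(ids, 1)
      }, "")
    })
  })
  for (r in seq_len(nreps)) {
    tab <- landmark_table(table[table$specimen_id %in% picks[[r]], ],
                          landmark_labels = a$labels)
    subtree <- if (!is.null(tree)) ape::keep.tip(tree, unique(tab$species_id)) else NULL
    records[[r]] <- run_rep_analyses(tab, subtree, hypotheses, analyses, nperm, r,
                                     seed = seed)
  }
  summarize_reps(records, nreps)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes imputation, Procrustes alignment, species means, per-group CR
#' modularity tests with effect-size comparisons, EMMLi model selection,
#' phylogenetic analyses (Kmult, module rates, trait models, shifts) and
#' optional resampling, writing TSV/JSON results to an output directory.
#'
#' @param config A list or YAML file path with (all optional unless noted)
#'   sections: `inputs` (`landmarks` file or a `landmark_tbl` under `table`;
#'   `tree` file or `phylo`; `module_map` file, defaults to the built-in
#'   floral hypotheses), `analyses` (character vector as in [rarefy_run()],
#'   plus `"compare"`), `impute_method`, `nperm`, `seed`, `resampling`
#'   (`rarefy`/`downsample` with `nreps`), `out_dir`.
#' @return A results bundle (list), invisibly; written to `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  nperm <- config$nperm %||% 999
  inp <- config$inputs %||% list()
  tab <- if (!is.null(inp$table)) inp$table else read_landmarks(inp$landmarks)
  tree <- if (!is.null(inp$tree)) {
    if (inherits(inp$tree, "phylo")) inp$tree else read_tree(inp$tree)
  } else NULL
  hyps <- if (!is.null(inp$module_map)) {
    read_module_map(inp$module_map, labels = landmark_labels(tab))
  } else merianieae_hypotheses()
  analyses <- config$analyses %||% c("modularity", "compare", "emmli", "kmult", "rates")

  res <- list(config = config)
  if (any(is.na(tab$x))) {
    tab <- estimate_missing(tab, method = config$impute_method %||% "TPS")
  }
  fit <- gpa(tab)
  res$gpa <- tibble::tibble(specimen_id = fit$specimen_id, species_id = fit$species_id,
                            group = fit$group, centroid_size = fit$centroid_sizes)
  means <- species_means(fit)
  pca <- shape_pca(fit)
  res$pca <- pca$scores
  groups <- unique(fit$group[nzchar(fit$group)])

  if ("modularity" %in% analyses) {
    rows <- list(); tests <- list()
    for (g in groups) {
      keep <- fit$group == g
      if (sum(keep) < 3) next
      Y <- flatten_coords(fit$aligned[keep, , , drop = FALSE])
      for (h in hyps) {
        ct <- modularity_test(Y, h, nperm = nperm, seed = seed)
        tests[[paste(g, h$name)]] <- ct
        rows[[length(rows) + 1]] <- tibble::tibble(group = g, hypothesis = h$name,
                                                   CR = ct$cr, p = ct$p, Z = ct$z)
      }
    }
    if (!is.null(tree)) {
      for (h in hyps) {
        ct <- phylo_modularity(means, tree, h, nperm = nperm, seed = seed)
        rows[[length(rows) + 1]] <- tibble::tibble(group = "all (phylogenetic)",
                                                   hypothesis = h$name,
                                                   CR = ct$cr, p = ct$p, Z = ct$z)
      }
    }
    res$modularity <- dplyr::bind_rows(rows)
    if ("compare" %in% analyses) {
      res$comparisons <- dplyr::bind_rows(lapply(names(hyps), function(hn) {
        sub <- tests[paste(groups, hn)]
        sub <- sub[!vapply(sub, is.null, TRUE)]
        if (length(sub) < 2) return(NULL)
        cmp <- compare_modularity(sub, labels = sub_labels <- sub("\\s.*$", "", names(sub)))
        cmp$hypothesis <- hn
        cmp
      }))
    }
  }
  if ("emmli" %in% analyses) {
    models <- build_model_set(hyps)
    res$emmli <- list()
    for (g in groups) {
      keep <- fit$group == g
      if (sum(keep) < 5) next
      sub_tbl <- lm_table(fit$aligned[keep, , , drop = FALSE],
                          fit$specimen_id[keep], fit$species_id[keep],
                          fit$group[keep], fit$labels)
      res$emmli[[g]] <- emmli_fit(congruence_matrix(sub_tbl), models)
    }
    res$emmli$all <- emmli_fit(congruence_matrix(fit), models)
  }
  if (!is.null(tree)) {
    if ("kmult" %in% analyses) res$kmult <- kmult(means, tree, nperm = nperm, seed = seed)
    if ("rates" %in% analyses) {
      res$rates <- lapply(hyps, function(h) module_rates(means, tree, h, nsim = nperm, seed = seed))
    }
    if ("fitmodels" %in% analyses || "shifts" %in% analyses) {
      pcm <- shape_pca(means)
      tr1 <- stats::setNames(pcm$scores$PC1, pcm$scores$species_id)
      if ("fitmodels" %in% analyses) res$fitmodels <- fit_trait_models(tree, tr1)
      if ("shifts" %in% analyses) res$shifts <- detect_shifts(tree, tr1)
    }
  }
  rs <- config$resampling
  if (!is.null(rs)) {
    if (isTRUE(rs$rarefy) || !is.null(rs$rarefy)) {
      res$rarefaction <- rarefy_run(tab, tree, hyps,
                                    analyses = intersect(analyses, c("modularity", "emmli")),
                                    nreps = rs$nreps %||% 100, nperm = nperm, seed = seed)
    }
  }
  if (!is.null(config$out_dir)) write_results_bundle(res, config$out_dir)
  invisible(res)
}

write_results_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      readr::write_tsv(dplyr::select(df, -dplyr::any_of("rho")), file.path(out_dir, name))
    }
  }
  wr(res$gpa, "gpa.tsv"); wr(res$pca, "pca_scores.tsv")
  wr(res$modularity, "modularity.tsv"); wr(res$comparisons, "comparisons.tsv")
  wr(res$kmult, "kmult.tsv")
  if (!is.null(res$emmli)) {
    for (g in names(res$emmli)) wr(res$emmli[[g]], paste0("emmli_", gsub("\\W+", "_", g), ".tsv"))
  }
  summary <- list(
    n_specimens = nrow(res$gpa),
    kmult = if (!is.null(res$kmult)) res$kmult$k_mult,
    shifts = if (!is.null(res$shifts)) res$shifts$n_shifts
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
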