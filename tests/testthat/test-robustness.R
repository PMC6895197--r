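make_flowers <- function(seed = 21) {
  spec <- sim_spec(p = 8, hypothesis = two_module_hyp(8), n_species = 10,
                   group_sizes = c(a = 5, b = 5), specimens_per_species = 3,
                   missing_fraction = 0, nuisance = FALSE)
  simulate_flowers(spec, seed = seed)
}

test_that("rarefaction on singleton species is degenerate and reproducible", {
  spec <- sim_spec(p = 8, hypothesis = two_module_hyp(8), n_species = 8,
                   group_sizes = c(a = 4, b = 4), specimens_per_species = 1,
                   missing_fraction = 0, nuisance = FALSE)
  fl <- simulate_flowers(spec, seed = 22)
  rs <- rarefy_run(fl$table, tree = NULL, hypotheses = list(two_module_hyp(8)),
                   analyses = "modularity", nreps = 4, nperm = 199, seed = 23)
  # every rep sees the identical dataset: CRs identical, significance all-or-none
  expect_equal(length(unique(round(rs$modularity$mean_cr, 12))),
               nrow(rs$modularity))
  per_rep <- dplyr::bind_rows(purrr::map(rs$records, "modularity"))
  for (g in unique(per_rep$group)) {
    crs <- per_rep$cr[per_rep$group == g]
    expect_equal(max(crs) - min(crs), 0, tolerance = 1e-12)
  }
  expect_true(all(rs$modularity$prop_significant %in% c(0, 1)))
})

test_that("rarefaction draws one specimen per species and summarizes per group", {
  fl <- make_flowers()
  rs <- rarefy_run(fl$table, tree = fl$tree, hypotheses = list(two_module_hyp(8)),
                   analyses = c("modularity", "kmult"), nreps = 3, nperm = 101,
                   seed = 24)
  expect_s3_class(rs$modularity, "tbl_df")
  expect_true(all(rs$modularity$prop_significant >= 0 & rs$modularity$prop_significant <= 1))
  expect_equal(nrow(dplyr::bind_rows(purrr::map(rs$records, "kmult"))), 3)
  # identical seed reproduces the summary exactly
  rs2 <- rarefy_run(fl$table, tree = fl$tree, hypotheses = list(two_module_hyp(8)),
                    analyses = c("modularity", "kmult"), nreps = 3, nperm = 101,
                    seed = 24)
  expect_equal(rs$modularity, rs2$modularity)
  expect_error(rarefy_run(fl$table, tree = NULL, hypotheses = list(two_module_hyp(8)),
                          analyses = "kmult", nreps = 2), "need a tree")
})

test_that("down-sampling respects group fractions and minimum group sizes", {
  spec <- sim_spec(p = 8, hypothesis = two_module_hyp(8), n_species = 30,
                   group_sizes = c(bb = 16, mv = 8, pa = 6),
                   specimens_per_species = 2, missing_fraction = 0, nuisance = FALSE)
  fl <- simulate_flowers(spec, seed = 25)
  rs <- downsample_run(fl$table, tree = NULL, hypotheses = list(two_module_hyp(8)),
                       analyses = "modularity", fraction = 0.5, min_per_group = 4,
                       nreps = 2, nperm = 101, seed = 26)
  # the 16/8/6 groups must be sampled to 8/4/4 species
  per_rep <- rs$records
  for (r in per_rep) {
    tabg <- r$modularity
    expect_setequal(unique(tabg$group), c("bb", "mv", "pa"))
  }
  # explicit size check on one draw
  set.seed(26)
  sp_grp <- unique(tibble::tibble(species = fl$table$species_id,
                                  group = fl$table$group))
  sizes <- vapply(split(sp_grp$species, sp_grp$group),
                  function(s) max(4, ceiling(0.5 * length(s))), 0)
  expect_equal(unname(sizes[c("bb", "mv", "pa")]), c(8, 4, 4))
  expect_error(
    downsample_run(fl$table, NULL, list(two_module_hyp(8)), min_per_group = 7,
                   nreps = 1),
    "min_per_group")
})

test_that("the pipeline runs end to end, writes a results bundle, and is seed-stable", {
  fl <- make_flowers(seed = 27)
  out_dir <- withr::local_tempdir()
  cfg <- list(
    inputs = list(table = fl$table, tree = fl$tree),
    analyses = c("modularity", "compare", "emmli", "kmult", "rates"),
    nperm = 101, seed = 5, out_dir = out_dir
  )
  # built-in hypotheses are for 37 landmarks; supply a matching map instead
  f <- file.path(out_dir, "map.yaml")
  writeLines(c("hypotheses:",
               "  - name: T1",
               "    modules:",
               paste0("      left: [", paste(sprintf("'%d'", 1:4), collapse = ", "), "]"),
               paste0("      right: [", paste(sprintf("'%d'", 5:8), collapse = ", "), "]")), f)
  cfg$inputs$module_map <- f
  res1 <- run_pipeline(cfg)
  expect_true(file.exists(file.path(out_dir, "modularity.tsv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_s3_class(res1$modularity, "tbl_df")
  expect_true(all(c("group", "hypothesis", "CR", "p", "Z") %in% names(res1$modularity)))
  expect_equal(nrow(res1$kmult), 1)
  res2 <- run_pipeline(cfg)
  expect_equal(res1$modularity, res2$modularity)
  expect_equal(res1$kmult, res2$kmult)
})

test_that("pipeline output on modular synthetic data ranks the true hypothesis highly", {
  spec <- sim_spec(p = 10, hypothesis = two_module_hyp(10), n_species = 6,
                   group_sizes = c(a = 6), specimens_per_species = 6,
                   rho_w = 0.7, rho_b = 0.1, within_sd = 0.05, sigma2 = 1e-8,
                   missing_fraction = 0, nuisance = FALSE)
  fl <- simulate_flowers(spec, seed = 28)
  # feed common-frame coordinates straight to the model-selection stage
  cm <- congruence_matrix(fl$table)
  ef <- emmli_fit(cm, build_model_set(list(two_module_hyp(10))))
  expect_equal(ef$hypothesis[1], "AB")
  expect_lt(ef$weight[ef$model == "null"], 0.5)
})
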