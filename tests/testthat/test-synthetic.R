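test_that("generators are bit-reproducible per seed", {
  m1 <- gen_toy_gem(5, 8, 10, 0.3, seed = 1)
  m2 <- gen_toy_gem(5, 8, 10, 0.3, seed = 1)
  expect_identical(m1, m2)
  expect_false(identical(m1, gen_toy_gem(5, 8, 10, 0.3, seed = 2)))

  e1 <- gen_expression(n_genes = 50, seed = 3)
  e2 <- gen_expression(n_genes = 50, seed = 3)
  expect_identical(e1$matrix, e2$matrix)

  l1 <- gen_lipidome(c("PC", "PI"), seed = 4)
  l2 <- gen_lipidome(c("PC", "PI"), seed = 4)
  expect_identical(l1$table$intensities, l2$table$intensities)

  s1 <- gen_tdl_study(seed = 5)
  s2 <- gen_tdl_study(seed = 5)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expression$matrix, s2$expression$matrix)
})

test_that("toy model construction honors its constraints", {
  m <- gen_toy_gem(5, 8, 10, 0.3, seed = 1)
  expect_s3_class(validate_gem(m), "tdl_gem")
  for (r in m$reactions) {
    expect_gte(length(r$genes), 1)
    expect_gte(length(r$stoich), 2)
    expect_true(any(r$stoich < 0) && any(r$stoich > 0))
  }
  # saturation: density 1 puts every gene on every reaction
  sat <- gen_toy_gem(4, 6, 8, density = 1, seed = 2)
  for (r in sat$reactions) expect_setequal(r$genes, sat$genes)
  # formulas cover pass, fail and unfilterable outcomes across seeds
  fates <- unlist(lapply(1:10, function(s) {
    vapply(gen_toy_gem(5, 8, 30, 0.3, seed = s)$metabolites$formula,
           function(f) {
             r <- formula_passes(f)
             if (is.na(r)) "na" else if (r) "pass" else "fail"
           }, "")
  }))
  expect_setequal(unique(fates), c("na", "pass", "fail"))
  expect_error(gen_toy_gem(0, 5, 5), "n_genes")
  expect_error(gen_toy_gem(5, 5, 1), "n_metabolites")
})

test_that("generated models survive a tabular round-trip and validation", {
  dir <- withr::local_tempdir()
  m <- gen_toy_gem(8, 12, 15, 0.25, seed = 6)
  write_gem(m, file.path(dir, "g"))
  expect_identical(read_gem(file.path(dir, "g"))$metabolites, m$metabolites)
})

test_that("expression generator plants recoverable effects", {
  x <- gen_expression(n_genes = 300, n_per_group = 8,
                      planted = sprintf("GENE%04d", 1:10), effect_log2 = 4,
                      sigma = 0.5, seed = 7)
  de <- filter_de(run_de(x$matrix, x$groups))
  expect_true(all(x$truth$planted %in% de$gene))
  expect_error(gen_expression(n_genes = 10, planted = "NOPE"),
               "outside the gene universe")
})

test_that("null expression stays calibrated under BH", {
  x <- gen_expression(n_genes = 2000, n_per_group = 8, effect_log2 = 0,
                      seed = 8)
  de <- run_de(x$matrix, x$groups)
  # expected false-rejection fraction under the global null is <= 0.05;
  # binomial slack on 2000 genes
  expect_lte(mean(de$q < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("lipidome generator plants class shifts and exclusive species", {
  l <- gen_lipidome(c("PC", "PI", "TAG"), planted_classes = "PC",
                    shift_sd = 4, n_exclusive = 1, seed = 9)
  expect_s3_class(l$table, "tdl_lipid_table")
  expect_true(all(lipid_class_of(l$truth$shifted_species) == "PC"))
  expect_length(l$truth$exclusive_species, 1)
  ev <- evaluate_lipidome(l$table, consensus = NULL)
  expect_true(ev$per_class$observed_change[ev$per_class$class == "PC"])

  # null lipidome: observed change only at FDR-level rates
  l0 <- gen_lipidome(paste0("C", 1:10), planted_classes = character(),
                     shift_sd = 0, seed = 10)
  ev0 <- evaluate_lipidome(l0$table, consensus = NULL)
  expect_lte(sum(ev0$per_class$observed_change), 2)
})

test_that("the linked study is internally consistent", {
  study <- gen_tdl_study(seed = 11)
  tr <- study$truth
  # causal genes exist everywhere they should
  expect_true(all(unlist(tr$causal_genes) %in% rownames(study$expression$matrix)))
  expect_true(all(unlist(tr$causal_genes) %in% study$gem$genes))
  expect_true(all(unlist(tr$causal_genes) %in% study$lmpd$gene))
  # planted lipid classes are the image of the causal map
  expect_setequal(names(tr$causal_genes), tr$planted_classes)
  expect_true(all(tr$lipid_truth$planted_classes %in% tr$planted_classes))
  # controls are disjoint from planted classes
  expect_length(intersect(study$controls, tr$planted_classes), 0)
})

test_that("a written study reloads into an equivalent pipeline run", {
  dir <- withr::local_tempdir()
  study <- gen_tdl_study(seed = 12, n_background = 60)
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expression.tsv", "groups.tsv", "lipid_genes.tsv", "pathways.tsv",
    "lipids.tsv", "lipids.groups.tsv", "controls.txt", "truth.json")))))
  res_mem <- run_pipeline(list(
    expression = study$expression$matrix, groups = study$expression$groups,
    lmpd = study$lmpd, pathways = study$pathways, gem = study$gem,
    lipids = study$lipids, controls = study$controls), quiet = TRUE)
  res_disk <- run_pipeline(list(
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    lmpd = file.path(dir, "lipid_genes.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    gem = file.path(dir, "gem"),
    lipids = file.path(dir, "lipids.tsv"),
    lipid_groups = file.path(dir, "lipids.groups.tsv"),
    controls = file.path(dir, "controls.txt")), quiet = TRUE)
  expect_identical(res_disk$de$gene, res_mem$de$gene)
  expect_identical(res_disk$consensus$entities, res_mem$consensus$entities)
  expect_identical(res_disk$evaluation$per_class, res_mem$evaluation$per_class)
})
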