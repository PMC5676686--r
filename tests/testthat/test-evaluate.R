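test_that("KS statistic matches the ECDF-sup oracle on random tied samples", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  expect_error(ks_two_sample(numeric(), 1:3), "empty")

  set.seed(61)
  for (i in 1:1000) {
    na <- sample(2:12, 1); nb <- sample(2:12, 1)
    # integer draws force ties
    a <- sample(1:6, na, replace = TRUE)
    b <- sample(1:6, nb, replace = TRUE) + sample(0:1, 1)
    expect_equal(ks_two_sample(a, b)$D, oracle_ks_D(a, b), tolerance = 1e-12)
  }
})

test_that("exact KS p equals full label enumeration for small samples", {
  set.seed(62)
  for (i in 1:120) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)  # n_a + n_b <= 12
    tied <- runif(1) < 0.5
    a <- if (tied) sample(1:4, na, TRUE) else rnorm(na)
    b <- if (tied) sample(1:4, nb, TRUE) else rnorm(nb, 0.5)
    got <- ks_two_sample(a, b)
    expect_true(got$exact)
    expect_equal(got$p, oracle_ks_exact_p(a, b), tolerance = 1e-10,
                 info = paste(c(a, "|", b), collapse = " "))
  }
})

test_that("large-sample p switches to the asymptotic Kolmogorov tail", {
  set.seed(63)
  a <- rnorm(150); b <- rnorm(150, 0.3)
  got <- ks_two_sample(a, b)
  expect_false(got$exact)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
  expect_equal(got$p, ref, tolerance = 1e-6)
})

test_that("log ratios substitute absences", {
  expect_equal(log_ratio(5, 5), 0)
  expect_equal(log_ratio(1, NA), 4)
  expect_equal(log_ratio(NA, NA), 0)
  expect_equal(log_ratio(NA, 1), -4)
  expect_equal(log_ratio(2, 0.002), 3)
})

test_that("lipid significance flags a shifted species and presence patterns", {
  tab <- toy_lipid_table()
  res <- lipid_significance(tab)
  expect_identical(res$species, rownames(tab$intensities))
  expect_true(res$significant[res$species == "PC 34:1"])
  expect_false(any(res$significant[res$species != "PC 34:1"]))
  expect_true(all(res$presence == "both"))
  # oracle route: enumeration KS + brute-force BH over the same four species
  ia <- tab$groups == "A"
  ps <- vapply(rownames(tab$intensities), function(s) {
    va <- tab$intensities[s, ia]; vb <- tab$intensities[s, !ia]
    va[is.na(va)] <- 1e-4; vb[is.na(vb)] <- 1e-4
    oracle_ks_exact_p(va, vb)
  }, 0)
  expect_equal(res$q, unname(oracle_bh(ps)), tolerance = 1e-10)

  # identical groups: nothing significant
  m <- tab$intensities
  m[, 6:10] <- m[, 1:5]
  tab2 <- lipid_table(m, unname(tab$classes), tab$groups)
  expect_false(any(lipid_significance(tab2)$significant))

  # entire-group absence -> differential by presence, no KS p
  m3 <- tab$intensities
  m3["PI 38:4", 1:5] <- NA
  tab3 <- lipid_table(m3, unname(tab$classes), tab$groups)
  res3 <- lipid_significance(tab3)
  row <- res3[res3$species == "PI 38:4", ]
  expect_identical(row$presence, "B-only")
  expect_true(row$differential_by_presence)
  expect_true(is.na(row$p))

  # species absent everywhere is dropped with a warning
  m4 <- tab$intensities
  m4["PI 34:2", ] <- NA
  tab4 <- lipid_table(m4, unname(tab$classes), tab$groups)
  expect_warning(res4 <- lipid_significance(tab4), "PI 34:2")
  expect_false("PI 34:2" %in% res4$species)
})

test_that("class summaries count significance and presence differentials", {
  res <- data.frame(
    species = paste0("s", 1:6),
    class = c("PI", "PI", "PG", "PG", "LPI", "LPS"),
    significant = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    differential_by_presence = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  cs <- class_summary(res)
  expect_identical(cs$observed_change[cs$class == "PI"], TRUE)
  expect_identical(cs$observed_change[cs$class == "PG"], TRUE)   # 1/2 counts
  expect_identical(cs$observed_change[cs$class == "LPI"], FALSE) # 0/1
  expect_identical(cs$observed_change[cs$class == "LPS"], TRUE)  # presence-only
  expect_true(all(cs$n_significant <= cs$n_measured))

  set.seed(64)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    r <- data.frame(species = paste0("s", 1:n),
                    class = sample(c("A", "B", "C"), n, TRUE),
                    significant = sample(c(TRUE, FALSE), n, TRUE),
                    differential_by_presence = sample(c(TRUE, FALSE), n, TRUE))
    cs <- class_summary(r)
    for (k in cs$class) {
      expect_equal(cs$n_significant[cs$class == k],
                   sum(r$significant[r$class == k]))
      expect_equal(cs$n_measured[cs$class == k], sum(r$class == k))
    }
  }
})

test_that("the category grid is total and covers each cell exactly once", {
  grid <- expand.grid(support = 0:3, observed = c(TRUE, FALSE))
  cat <- categorize(grid$support, grid$observed)
  expect_true(all(cat %in% 1:6))
  expect_setequal(cat, 1:6)  # all six categories are reachable
  # one category per cell, and the published anchor cases
  expect_equal(categorize(3, TRUE), 1)   # PI: all branches, change observed
  expect_equal(categorize(1, TRUE), 2)   # PS/PG: one branch, correct
  expect_equal(categorize(0, FALSE), 3)  # LPI/LPC: none, correct
  expect_equal(categorize(2, FALSE), 4)  # PA: database branches, wrong
  expect_equal(categorize(1, FALSE), 4)
  expect_equal(categorize(3, FALSE), 5)  # predicted by all, not observed
  expect_equal(categorize(0, TRUE), 6)   # LPS: unpredicted change
  expect_error(categorize(4, TRUE), "0,1,2,3")
})

test_that("evaluation ties branch support to measured classes", {
  study <- gen_tdl_study(seed = 17)
  de <- filter_de(run_de(study$expression$matrix, study$expression$groups))
  cons <- merge_branches(list(predict_lmpd(de, study$lmpd),
                              predict_pathway(de, study$pathways),
                              predict_gem(de, study$gem)))
  ev <- evaluate_lipidome(study$lipids, cons)
  planted <- sort(study$truth$planted_classes)
  got1 <- sort(ev$per_class$class[ev$per_class$category == 1])
  expect_identical(got1, planted)
  expect_true(all(ev$per_class$branch_support_count[
    ev$per_class$class %in% study$controls] == 0))
})
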