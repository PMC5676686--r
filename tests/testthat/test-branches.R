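random_annot <- function(genes, labels, n) {
  data.frame(gene = sample(genes, n, replace = TRUE),
             level = "class",
             name = sample(labels, n, replace = TRUE),
             source = "x", stringsAsFactors = FALSE)
}

test_that("lipid-gene branch equals a nested-loop join", {
  annot <- data.frame(gene = "G1", level = "class", name = "PC", source = "s")
  p <- predict_lmpd("G1", annot)
  expect_identical(p$entities$name, "PC")
  expect_identical(p$gene_support[["class:PC"]], "G1")

  expect_equal(nrow(predict_lmpd(c("GX", "GY"), annot)$entities), 0)

  set.seed(31)
  for (i in 1:100) {
    genes <- sprintf("G%02d", 1:20)
    labels <- c("PC", "PI", "PE", "TAG", "Cer")
    de <- sample(genes, sample(0:10, 1))
    annot <- random_annot(genes, labels, sample(1:30, 1))
    got <- predict_lmpd(de, annot)
    # oracle: literal nested loop
    want <- character()
    for (g in de) for (j in seq_len(nrow(annot))) {
      if (annot$gene[j] == g) want <- union(want, annot$name[j])
    }
    expect_setequal(got$entities$name, want)
    for (k in seq_len(nrow(got$entities))) {
      nm <- got$entities$name[k]
      drivers <- got$gene_support[[paste0("class:", nm)]]
      expect_setequal(drivers, intersect(de, annot$gene[annot$name == nm]))
    }
  }
})

test_that("pathway branch gates on the lipid_relevant flag", {
  annot <- data.frame(
    gene = c("G1", "G1"), pathway_id = c("P1", "P2"),
    pathway_name = c("PC metabolism", "Signal transduction"),
    lipid_relevant = c(TRUE, FALSE),
    class = c("PC", "Signal transduction"))
  p <- predict_pathway("G1", annot)
  expect_identical(p$entities$name, "PC")
  expect_identical(p$entities$level, "class")

  annot$lipid_relevant <- FALSE
  expect_equal(nrow(predict_pathway("G1", annot)$entities), 0)

  set.seed(32)
  for (i in 1:100) {
    genes <- sprintf("G%02d", 1:15)
    de <- sample(genes, sample(0:8, 1))
    n <- sample(1:25, 1)
    annot <- data.frame(gene = sample(genes, n, TRUE),
                        pathway_id = sample(paste0("P", 1:6), n, TRUE),
                        pathway_name = "x",
                        lipid_relevant = sample(c(TRUE, FALSE), n, TRUE),
                        class = sample(c("PC", "PI", "TAG"), n, TRUE))
    got <- predict_pathway(de, annot)
    want <- unique(annot$class[annot$lipid_relevant & annot$gene %in% de])
    expect_setequal(got$entities$name, want)
  }
})

test_that("gene overlap with the model is case-insensitive", {
  m <- tiny_model()
  expect_identical(gem_gene_overlap(c("A", "GENE2"), m), "GENE2")
  expect_identical(gem_gene_overlap("gene2", m), "GENE2")
  expect_identical(gem_gene_overlap(data.frame(gene = "Gene1"), m), "GENE1")
  expect_length(gem_gene_overlap(character(), m), 0)
})

test_that("gene->reaction->metabolite propagation equals the dense-matrix oracle", {
  m <- tiny_model()
  expect_length(genes_to_reactions(m, character()), 0)
  rm1 <- genes_to_reactions(m, "GENE2")
  expect_identical(names(rm1), "r2")
  expect_identical(rm1$r2, "GENE2")
  expect_setequal(reactions_to_metabolites(m, "r1"), c("a[c]", "b[c]"))
  expect_length(reactions_to_metabolites(m, character()), 0)
  expect_error(reactions_to_metabolites(m, "nope"), "unknown reaction")
  expect_error(genes_to_reactions(m, "NOT_A_GENE"), "outside the model")

  for (seed in 1:200) {
    set.seed(seed)
    ng <- sample(2:30, 1); nr <- sample(2:50, 1); nm <- sample(2:40, 1)
    model <- gen_toy_gem(ng, nr, nm, density = runif(1, 0.05, 0.5),
                         seed = seed)
    genes <- sample(model$genes, sample(0:min(5, ng), 1))
    rmap <- genes_to_reactions(model, genes)
    mets <- reactions_to_metabolites(model, names(rmap))
    want <- oracle_gem_propagation(model, genes)
    expect_setequal(names(rmap), want$reactions)
    expect_setequal(mets, want$metabolites)
    for (r in names(rmap)) {
      expect_setequal(rmap[[r]], intersect(model$reactions[[r]]$genes, genes))
    }
  }
})

test_that("propagation is monotone in the DE gene set", {
  for (seed in 1:20) {
    model <- gen_toy_gem(15, 25, 20, density = 0.2, seed = seed)
    set.seed(seed + 1000)
    small <- sample(model$genes, 3)
    big <- union(small, sample(model$genes, 5))
    r_small <- names(genes_to_reactions(model, small))
    r_big <- names(genes_to_reactions(model, big))
    expect_true(all(r_small %in% r_big))
    expect_true(all(reactions_to_metabolites(model, r_small) %in%
                      reactions_to_metabolites(model, r_big)))
  }
})

test_that("composition gate applies the C4H8O2 thresholds to C,H,O only", {
  mets <- data.frame(
    id = paste0(c("water", "palmitate", "glycerol", "pc", "mystery", "atp"), "[c]"),
    base_name = c("water", "palmitate", "glycerol", "pc", "mystery", "atp"),
    compartment = "c",
    formula = c("H2O", "C16H32O2", "C3H8O3", "C42H82NO8P", NA,
                "C10H16N5O13P3"))
  got <- composition_filter(mets)
  expect_setequal(got$base_name, c("palmitate", "pc", "mystery", "atp"))
  expect_true(got$unfiltered[got$base_name == "mystery"])
  expect_false(any(got$unfiltered[got$base_name %in% c("palmitate", "pc")]))
  # N and P do not disqualify (pc has N, P; atp passes on raw C,H,O)
  expect_true("atp" %in% got$base_name)
  # ... which is what the cofactor stop-list is for
  got2 <- composition_filter(mets, stoplist = "atp")
  expect_false("atp" %in% got2$base_name)
  # order-independence
  got3 <- composition_filter(mets[sample(nrow(mets)), ])
  expect_setequal(got3$id, got$id)

  expect_false(formula_passes("H2O"))
  expect_true(formula_passes("C16H32O2"))
  expect_false(formula_passes("C3H8O3"))
  expect_true(is.na(formula_passes("C40H77NO8R")))
})

test_that("driver-multiplicity statistics match a brute-force tally", {
  st <- reaction_driver_stats(list(r1 = "g1", r2 = c("g1", "g2")))
  expect_equal(st$singly_driven, 1)
  expect_equal(st$singular_per_gene[["g1"]], 1)
  expect_equal(st$singular_per_gene[["g2"]], 0)

  st2 <- reaction_driver_stats(list(r1 = c("a", "b"), r2 = c("a", "c")))
  expect_equal(st2$singly_driven, 0)
  expect_equal(st2$multi_driven, 2)

  set.seed(77)
  for (i in 1:50) {
    genes <- letters[1:6]
    rmap <- lapply(seq_len(sample(1:20, 1)),
                   function(j) sample(genes, sample(1:3, 1)))
    names(rmap) <- paste0("r", seq_along(rmap))
    st <- reaction_driver_stats(rmap)
    expect_equal(st$singly_driven,
                 sum(vapply(rmap, function(d) length(d) == 1L, NA)))
    for (g in genes) {
      want <- sum(vapply(rmap, function(d) identical(d, g), NA))
      got <- if (g %in% names(st$singular_per_gene))
        st$singular_per_gene[[g]] else 0L
      expect_equal(got, want)
    }
  }
})

test_that("compartment deduplication keeps one row per base name", {
  mets <- data.frame(id = c("X[c]", "X[m]", "Y[c]"),
                     base_name = c("X", "X", "Y"),
                     compartment = c("c", "m", "c"),
                     formula = NA)
  expect_identical(dedupe_across_compartments(mets)$base_name, c("X", "Y"))
  solo <- mets[c(1, 3), ]
  expect_equal(nrow(dedupe_across_compartments(solo)), 2)
  set.seed(9)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    df <- data.frame(base_name = sample(LETTERS[1:8], n, TRUE))
    expect_equal(nrow(dedupe_across_compartments(df)),
                 length(unique(df$base_name)))
  }
})

test_that("GEM branch: entity disappears when its drivers leave the DE list", {
  study <- gen_tdl_study(seed = 13)
  de_genes <- study$truth$planted_de_genes
  p_full <- predict_gem(de_genes, study$gem)
  expect_gt(nrow(p_full$entities), 0)
  for (k in seq_len(nrow(p_full$entities))) {
    key <- paste0(p_full$entities$level[k], ":", p_full$entities$name[k])
    drivers <- p_full$gene_support[[key]]
    reduced <- predict_gem(setdiff(de_genes, drivers), study$gem)
    keys <- paste0(reduced$entities$level, ":", reduced$entities$name)
    expect_false(key %in% keys)
  }
})

test_that("GEM branch resolves pools to class-level entities", {
  study <- gen_tdl_study(seed = 4)
  p <- predict_gem(study$truth$planted_de_genes, study$gem)
  cls <- p$entities$name[p$entities$level == "class"]
  expect_setequal(cls, study$truth$planted_classes)
  sp <- p$entities[p$entities$level == "species", ]
  expect_true(all(sp$class %in% study$truth$planted_classes))
})
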