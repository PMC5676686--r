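.LIPID_FORMULA_POOL <- c(
  "C42H82NO8P", "C44H86NO8P", "C40H80NO8P",   # PC-like
  "C41H78NO8P", "C43H74NO10P",                # PE/PS-like
  "C45H87O13P", "C47H83O13P",                 # PI-like
  "C16H32O2", "C18H34O2", "C20H32O2",         # fatty acids
  "C55H98O6", "C57H104O6",                    # TAG-like
  "C37H72O5", "C41H74O5",                     # DAG-like
  "C42H83NO3", "C40H79NO3")                   # ceramide-like

.NONLIPID_FORMULA_POOL <- c(
  "H2O", "CO2", "NH3", "C3H8O3", "C2H4O2", "C3H4O3", "H3O4P", "C2H3O2")

.GENERIC_FORMULA_POOL <- c("C40H77NO8R", "C25H40N7O17P3SR", "CO2R")

.CHAIN_LABELS <- c("32:0", "32:1", "34:1", "34:2", "36:1", "36:2", "36:3",
                   "36:4", "38:3", "38:4", "40:1", "40:2", "42:1", "42:2",
                   "44:2", "46:3")

#' Random toy genome-scale metabolic model
#'
#' A seeded random bipartite gene-reaction incidence and reaction-metabolite
#' stoichiometry. Every reaction carries at least one gene and at least two
#' metabolites (one consumed, one produced). Metabolite formulas are sampled
#' from a lipid-like pool, a small-molecule pool and a generic-residue pool so
#' the composition gate sees every outcome; base names are reused across
#' compartments so compartment deduplication is exercised.
#'
#' @param n_genes,n_reactions,n_metabolites sizes (all >= 1,
#'   `n_metabolites >= 2`).
#' @param density probability that a given gene drives a given reaction,
#'   in (0, 1].
#' @param seed integer seed; the generator is bit-reproducible per seed.
#' @return a validated [metabolic_model()].
#' @export
gen_toy_gem <- function(n_genes, n_reactions, n_metabolites, density = 0.3,
                        seed = 1) {
  stopifnot(n_genes >= 1, n_reactions >= 1, n_metabolites >= 2,
            density > 0, density <= 1)
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  comps <- c("c", "m", "e")
  n_base <- max(2L, ceiling(n_metabolites * 0.75))
  combos <- expand.grid(base = sprintf("MET%03d", seq_len(n_base)),
                        comp = comps, stringsAsFactors = FALSE)
  if (nrow(combos) < n_metabolites) {
    stop("infeasible: cannot place ", n_metabolites,
         " unique metabolites across ", n_base, " base names")
  }
  pick <- combos[sample.int(nrow(combos), n_metabolites), ]
  formulas <- sample(c(.LIPID_FORMULA_POOL, .NONLIPID_FORMULA_POOL,
                       .GENERIC_FORMULA_POOL, NA_character_),
                     n_base, replace = TRUE)
  mets <- data.frame(
    id = paste0(pick$base, "[", pick$comp, "]"),
    base_name = pick$base, compartment = pick$comp,
    formula = formulas[match(pick$base, sprintf("MET%03d", seq_len(n_base)))],
    stringsAsFactors = FALSE)

  reactions <- lapply(seq_len(n_reactions), function(i) {
    g <- genes[stats::runif(n_genes) < density]
    if (length(g) == 0L) g <- sample(genes, 1L)
    k <- sample(2:min(4L, n_metabolites), 1L)
    mids <- sample(mets$id, k)
    coef <- sample(c(1, 2), k, replace = TRUE)
    coef[1] <- -coef[1]                      # at least one substrate
    if (k > 2L) {
      flip <- sample(c(TRUE, FALSE), k - 2L, replace = TRUE)
      coef[seq(2, k - 1)][flip] <- -coef[seq(2, k - 1)][flip]
    }
    list(genes = g, stoich = stats::setNames(coef, mids))
  })
  names(reactions) <- sprintf("R%03d", seq_len(n_reactions))
  metabolic_model(genes, reactions, mets)
}

#' Two-group log2 expression matrix with planted effects
#'
#' Gaussian log2 expression around gene-specific baselines; planted genes are
#' shifted upward by `effect_log2` in the second group. Ground truth is
#' attached for recovery checks.
#'
#' @param n_genes number of genes (ignored when `gene_names` given).
#' @param n_per_group samples per group.
#' @param planted character vector of planted gene names (must exist).
#' @param effect_log2 shift (log2 units, >= 0) applied in group B.
#' @param sigma within-group standard deviation (log2 units, > 0).
#' @param seed integer seed.
#' @param gene_names optional explicit gene universe.
#' @param group_labels the two group names.
#' @return list with `matrix` (genes x samples), `groups` (named character)
#'   and `truth` (planted genes, effect, seed).
#' @export
gen_expression <- function(n_genes = 2000, n_per_group = 8,
                           planted = character(), effect_log2 = 0,
                           sigma = 0.5, seed = 1, gene_names = NULL,
                           group_labels = c("A", "B")) {
  stopifnot(effect_log2 >= 0, sigma > 0, n_per_group >= 2,
            length(group_labels) == 2L)
  set.seed(seed)
  genes <- if (is.null(gene_names)) sprintf("GENE%04d", seq_len(n_genes)) else
    normalize_genes(gene_names)
  planted <- normalize_genes(planted)
  outside <- setdiff(planted, genes)
  if (length(outside)) {
    stop("planted gene(s) outside the gene universe: ",
         paste(outside, collapse = ", "))
  }
  n <- length(genes)
  samples <- c(paste0(group_labels[1], seq_len(n_per_group)),
               paste0(group_labels[2], seq_len(n_per_group)))
  groups <- stats::setNames(rep(group_labels, each = n_per_group), samples)
  mu <- stats::runif(n, 6, 12)
  m <- matrix(stats::rnorm(n * length(samples), mean = mu, sd = sigma),
              nrow = n, dimnames = list(genes, samples))
  m[planted, groups == group_labels[2]] <-
    m[planted, groups == group_labels[2]] + effect_log2
  list(matrix = m, groups = groups,
       truth = list(planted = planted, effect_log2 = effect_log2,
                    sigma = sigma, seed = seed))
}

#' Measured lipid table with planted class-level shifts
#'
#' Log-normal intensities (Gaussian on log10 scale); in each planted class a
#' random fraction of species is shifted by `shift_sd` pooled standard
#' deviations in the second group (direction random per class, consistent
#' within a class), mimicking partial-class signals where only some member
#' species respond. Optionally some shifted species are made group-exclusive
#' (absent from the other group) to exercise presence/absence logic.
#'
#' @param classes character vector of class labels.
#' @param species_per_class species per class.
#' @param planted_classes subset of `classes` with planted shifts.
#' @param shift_sd effect size in within-group SD units (log scale).
#' @param n_per_group samples per group.
#' @param frac_shifted fraction of species shifted within a planted class.
#' @param n_exclusive number of group-exclusive species (drawn from planted
#'   classes).
#' @param sigma_log within-group SD on log10 scale.
#' @param seed integer seed.
#' @param group_labels the two group names.
#' @return list with `table` (a [lipid_table()]) and `truth` (planted classes,
#'   shifted species, directions, exclusive species, seed).
#' @export
gen_lipidome <- function(classes, species_per_class = 8,
                         planted_classes = character(), shift_sd = 4,
                         n_per_group = 8, frac_shifted = 0.4,
                         n_exclusive = 0, sigma_log = 0.25, seed = 1,
                         group_labels = c("A", "B")) {
  stopifnot(all(planted_classes %in% classes), shift_sd >= 0,
            frac_shifted > 0, frac_shifted <= 1, n_per_group >= 2)
  set.seed(seed)
  species <- unlist(lapply(classes, function(cl) {
    paste(cl, .CHAIN_LABELS[seq_len(min(species_per_class,
                                        length(.CHAIN_LABELS)))])
  }))
  cls <- rep(classes, each = min(species_per_class, length(.CHAIN_LABELS)))
  n <- length(species)
  samples <- c(paste0(group_labels[1], seq_len(n_per_group)),
               paste0(group_labels[2], seq_len(n_per_group)))
  groups <- stats::setNames(rep(group_labels, each = n_per_group), samples)
  mu <- stats::runif(n, 2, 6)
  logm <- matrix(stats::rnorm(n * length(samples), mean = mu, sd = sigma_log),
                 nrow = n, dimnames = list(species, samples))
  shifted <- character(); dirs <- integer()
  for (cl in planted_classes) {
    idx <- which(cls == cl)
    k <- max(1L, ceiling(frac_shifted * length(idx)))
    pick <- sample(idx, k)
    dir <- sample(c(-1L, 1L), 1L)
    logm[pick, groups == group_labels[2]] <-
      logm[pick, groups == group_labels[2]] + dir * shift_sd * sigma_log
    shifted <- c(shifted, species[pick])
    dirs <- c(dirs, rep(dir, k))
  }
  m <- 10^logm
  exclusive <- character()
  if (n_exclusive > 0 && length(shifted)) {
    exclusive <- sample(shifted, min(n_exclusive, length(shifted)))
    for (j in seq_along(exclusive)) {
      gone <- group_labels[1 + (j %% 2)]
      m[exclusive[j], groups == gone] <- NA_real_
    }
  }
  list(table = lipid_table(m, cls, groups),
       truth = list(planted_classes = planted_classes,
                    shifted_species = shifted,
                    directions = stats::setNames(dirs, shifted),
                    exclusive_species = exclusive, seed = seed))
}

#' Linked synthetic study with one ground truth
#'
#' Generates every input the pipeline consumes from a single causal story:
#' a set of planted lipid classes, each driven by causal genes that are (a)
#' differentially expressed in the expression matrix, (b) annotated to the
#' class in the lipid-gene table, (c) members of lipid-relevant pathways
#' mapping to the class, and (d) attached to metabolic reactions producing the
#' class's pool and species metabolites in the model; the measured lipid
#' table carries shifts in exactly the planted classes. Decoy DE genes drive
#' non-lipid reactions and non-lipid-relevant pathways; background genes and
#' annotation noise are inert. Negative-control classes are non-planted
#' classes no branch can predict.
#'
#' @param seed integer seed (sub-generators get derived seeds).
#' @param n_classes number of lipid classes measured.
#' @param n_planted number of planted (truly shifted) classes.
#' @param genes_per_class causal genes per planted class.
#' @param n_decoy decoy DE genes without lipid links.
#' @param n_background inert background genes.
#' @param n_per_group samples per group (expression and lipidomics).
#' @param effect_log2 expression effect size of planted genes.
#' @param sigma expression within-group SD (log2).
#' @param species_per_class measured species per class.
#' @param shift_sd lipid effect size in SD units.
#' @param n_exclusive group-exclusive lipid species.
#' @param n_controls negative-control classes.
#' @return list with `expression`, `gem`, `lmpd`, `pathways`, `lipids`
#'   (a `tdl_lipid_table`), `controls`, and `truth`.
#' @export
gen_tdl_study <- function(seed = 1, n_classes = 10, n_planted = 4,
                          genes_per_class = 2, n_decoy = 3,
                          n_background = 200, n_per_group = 8,
                          effect_log2 = 4, sigma = 0.5,
                          species_per_class = 8, shift_sd = 4,
                          n_exclusive = 2, n_controls = 3) {
  stopifnot(n_planted >= 1, n_planted <= n_classes,
            n_controls <= n_classes - n_planted)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  classes <- c("PC", "PI", "PE", "PS", "PG", "TAG", "DAG", "Cer", "SM",
               "LPC", "LPI", "PA", "LPG", "LPA", "LPS")[seq_len(n_classes)]
  planted <- sample(classes, n_planted)
  controls <- sample(setdiff(classes, planted), n_controls)

  causal <- lapply(planted, function(cl) {
    sprintf("%sGEN%d", gsub("[^A-Za-z]", "", cl), seq_len(genes_per_class))
  })
  names(causal) <- planted
  causal_genes <- normalize_genes(unlist(causal))
  decoys <- sprintf("DECOY%d", seq_len(n_decoy))
  background <- sprintf("BG%04d", seq_len(n_background))
  universe <- c(causal_genes, decoys, background)

  expr <- gen_expression(n_per_group = n_per_group,
                         planted = c(causal_genes, decoys),
                         effect_log2 = effect_log2, sigma = sigma,
                         seed = sub_seeds[1], gene_names = universe)

  # lipid-gene annotation: causal genes -> their class, plus inert noise
  noise_genes <- background[seq_len(min(6L, n_background))]
  noise_classes <- setdiff(classes, c(planted, controls))
  lmpd <- data.frame(
    gene = c(causal_genes, noise_genes),
    level = "class",
    name = c(rep(planted, each = genes_per_class),
             if (length(noise_classes)) {
               rep_len(noise_classes, length(noise_genes))
             } else rep_len(planted, length(noise_genes))),
    source = "synthetic-lmpd", stringsAsFactors = FALSE)

  # pathway annotation: lipid-relevant pathways for causal genes, decoys in
  # non-lipid pathways
  pathways <- rbind(
    data.frame(gene = causal_genes,
               pathway_id = sprintf("RP%02d", match(
                 rep(planted, each = genes_per_class), classes)),
               pathway_name = paste(rep(planted, each = genes_per_class),
                                    "metabolism"),
               lipid_relevant = TRUE,
               class = rep(planted, each = genes_per_class),
               stringsAsFactors = FALSE),
    data.frame(gene = decoys, pathway_id = "RP99",
               pathway_name = "Signal transduction", lipid_relevant = FALSE,
               class = "Signal transduction", stringsAsFactors = FALSE))

  # GEM: causal genes drive reactions producing the class pool (+ species);
  # decoys drive small-molecule reactions; background genes pad the universe
  mets <- data.frame(id = character(), base_name = character(),
                     compartment = character(), formula = character(),
                     stringsAsFactors = FALSE)
  add_met <- function(base, comp, formula) {
    id <- paste0(base, "[", comp, "]")
    if (!id %in% mets$id) {
      mets <<- rbind(mets, data.frame(id = id, base_name = base,
                                      compartment = comp, formula = formula,
                                      stringsAsFactors = FALSE))
    }
    id
  }
  acoa <- add_met("acyl-CoA", "c", "C25H40N7O17P3SR")   # generic precursor
  h2o <- add_met("H2O", "c", "H2O")
  reactions <- list()
  for (cl in planted) {
    pool_c <- add_met(paste(cl, "pool"), "c", NA_character_)
    pool_m <- add_met(paste(cl, "pool"), "m", NA_character_)  # compartment dup
    sp1 <- add_met(paste(cl, .CHAIN_LABELS[1]), "c",
                   sample(.LIPID_FORMULA_POOL, 1))
    sp2 <- add_met(paste(cl, .CHAIN_LABELS[2]), "c",
                   sample(.LIPID_FORMULA_POOL, 1))
    reactions[[paste0("R_", gsub("[^A-Za-z]", "", cl), "_syn")]] <-
      list(genes = causal[[cl]],
           stoich = stats::setNames(c(-1, 1, 1), c(acoa, pool_c, sp1)))
    reactions[[paste0("R_", gsub("[^A-Za-z]", "", cl), "_remod")]] <-
      list(genes = causal[[cl]][1],
           stoich = stats::setNames(c(-1, 1, 1), c(sp1, sp2, pool_m)))
  }
  co2 <- add_met("CO2", "c", "CO2")
  for (i in seq_along(decoys)) {
    reactions[[paste0("R_decoy", i)]] <-
      list(genes = decoys[i],
           stoich = stats::setNames(c(-1, 1), c(h2o, co2)))
  }
  gem_background <- background[seq_len(min(10L, n_background))]
  glc <- add_met("glucose", "c", "C6H12O6")
  pyr <- add_met("pyruvate", "c", "C3H4O3")
  reactions[["R_bg"]] <- list(genes = gem_background,
                              stoich = stats::setNames(c(-1, 2), c(glc, pyr)))
  gem <- metabolic_model(c(causal_genes, decoys, gem_background),
                         reactions, mets)

  lip <- gen_lipidome(classes = classes,
                      species_per_class = species_per_class,
                      planted_classes = planted, shift_sd = shift_sd,
                      n_per_group = n_per_group, n_exclusive = n_exclusive,
                      seed = sub_seeds[2])

  list(expression = expr, gem = gem, lmpd = lmpd, pathways = pathways,
       lipids = lip$table, controls = controls,
       truth = list(seed = seed, planted_classes = planted,
                    causal_genes = causal, decoy_genes = decoys,
                    planted_de_genes = c(causal_genes, decoys),
                    lipid_truth = lip$truth))
}

#' Write a generated study to disk as pipeline-ready TSVs
#'
#' Emits `expression.tsv`, `groups.tsv`, `lipid_genes.tsv`, `pathways.tsv`,
#' the tabular model under `gem/`, `lipids.tsv` + `lipids.groups.tsv`,
#' `controls.txt`, and `truth.json`.
#'
#' @param study output of [gen_tdl_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  em <- study$expression$matrix
  .write_tsv(data.frame(gene = rownames(em), em, check.names = FALSE),
             file.path(dir, "expression.tsv"))
  .write_tsv(data.frame(sample = names(study$expression$groups),
                        group = unname(study$expression$groups)),
             file.path(dir, "groups.tsv"))
  .write_tsv(study$lmpd, file.path(dir, "lipid_genes.tsv"))
  .write_tsv(study$pathways, file.path(dir, "pathways.tsv"))
  write_gem(study$gem, file.path(dir, "gem"))
  write_lipid_table(study$lipids, file.path(dir, "lipids.tsv"),
                    file.path(dir, "lipids.groups.tsv"))
  writeLines(study$controls, file.path(dir, "controls.txt"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}
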