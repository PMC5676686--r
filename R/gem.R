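#' Construct a metabolic model
#'
#' A validated in-memory genome-scale metabolic model (GEM): the gene
#' universe, reactions with flattened gene associations and signed
#' stoichiometry, and metabolites with compartment and (optional) elemental
#' formula. Gene-protein-reaction boolean structure is deliberately flattened
#' to plain gene sets: the propagation steps only need the binary
#' gene-reaction incidence.
#'
#' @param genes character vector of gene symbols (normalized internally).
#' @param reactions named list; each element a list with `genes` (character)
#'   and `stoich` (named numeric, metabolite id -> nonzero coefficient).
#'   Names are the reaction ids.
#' @param metabolites data.frame with columns `id`, `base_name`,
#'   `compartment`, `formula` (`NA` allowed).
#' @return an object of class `tdl_gem`.
#' @seealso [read_gem()], [write_gem()], [gen_toy_gem()]
#' @export
metabolic_model <- function(genes, reactions, metabolites) {
  genes <- sort(unique(normalize_genes(genes)))
  stopifnot(is.list(reactions), is.data.frame(metabolites))
  req <- c("id", "base_name", "compartment", "formula")
  miss <- setdiff(req, names(metabolites))
  if (length(miss)) {
    stop("metabolites table lacks column(s): ", paste(miss, collapse = ", "))
  }
  metabolites <- metabolites[, req]
  metabolites[] <- lapply(metabolites, as.character)
  rownames(metabolites) <- NULL
  reactions <- lapply(reactions, function(r) {
    list(genes = sort(unique(normalize_genes(r$genes))),
         stoich = r$stoich)
  })
  model <- structure(
    list(genes = genes, reactions = reactions, metabolites = metabolites),
    class = "tdl_gem")
  validate_gem(model)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique reaction and metabolite ids,
#' non-empty stoichiometries with nonzero coefficients, and no dangling
#' metabolite or gene references from reactions.
#'
#' @param model a `tdl_gem`.
#' @return the model, invisibly-checked (returned unchanged).
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "tdl_gem"))
  rids <- names(model$reactions)
  if (is.null(rids) || anyNA(rids) || any(!nzchar(rids))) {
    stop("validation error: reactions must be a named list of reaction ids")
  }
  if (anyDuplicated(rids)) {
    stop("validation error: duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  mids <- model$metabolites$id
  if (anyDuplicated(mids)) {
    stop("validation error: duplicate metabolite ids: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))
  }
  for (rid in rids) {
    r <- model$reactions[[rid]]
    if (length(r$stoich) == 0L) {
      stop("validation error: empty stoichiometry in reaction ", rid)
    }
    if (any(r$stoich == 0)) {
      stop("validation error: zero coefficient in reaction ", rid)
    }
    dangling_m <- setdiff(names(r$stoich), mids)
    if (length(dangling_m)) {
      stop("validation error: reaction ", rid,
           " references undeclared metabolite(s): ",
           paste(dangling_m, collapse = ", "))
    }
    dangling_g <- setdiff(r$genes, model$genes)
    if (length(dangling_g)) {
      stop("validation error: reaction ", rid,
           " references undeclared gene(s): ",
           paste(dangling_g, collapse = ", "))
    }
  }
  model
}

#' @export
print.tdl_gem <- function(x, ...) {
  cat(sprintf("tdl metabolic model: %d genes, %d reactions, %d metabolites\n",
              length(x$genes), length(x$reactions), nrow(x$metabolites)))
  invisible(x)
}

#' Read a genome-scale metabolic model
#'
#' Two dialects are supported. `"tabular"` expects a directory with four TSVs:
#' `genes.tsv` (column `gene`), `metabolites.tsv` (`id`, `name`,
#' `compartment`, `formula`), `reactions.tsv` (`id`, `gene_set`
#' pipe-delimited) and `stoich.tsv` (`reaction_id`, `metabolite_id`,
#' `coefficient`). `"sbml-fbc"` expects an SBML Level 3 file using the FBC
#' package for gene products and gene-product associations; boolean AND/OR
#' association structure is flattened to the set of referenced genes.
#'
#' Metabolite ids in the tabular dialect follow the `name[compartment]`
#' convention (e.g. `retinoate[c]`); in SBML the compartment attribute is
#' authoritative and ids are rebuilt in the same convention.
#'
#' @param path directory (tabular) or SBML file.
#' @param dialect `"tabular"` or `"sbml-fbc"`; default guessed from `path`.
#' @return a validated [metabolic_model()].
#' @export
read_gem <- function(path, dialect = c("auto", "tabular", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (dir.exists(path)) "tabular" else "sbml-fbc"
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(dialect,
         "tabular" = .read_gem_tabular(path),
         "sbml-fbc" = .read_gem_sbml(path))
}

.read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("parse error: missing file ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", quote = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop(sprintf("parse error in %s: missing column(s) %s",
                   path, paste(miss, collapse = ", ")))
    }
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.read_gem_tabular <- function(dir) {
  genes <- .read_tsv(file.path(dir, "genes.tsv"), "gene")$gene
  mets <- .read_tsv(file.path(dir, "metabolites.tsv"),
                    c("id", "name", "compartment", "formula"))
  rxns <- .read_tsv(file.path(dir, "reactions.tsv"), c("id", "gene_set"))
  stoich <- .read_tsv(file.path(dir, "stoich.tsv"),
                      c("reaction_id", "metabolite_id", "coefficient"))
  bad_id <- mets$id != paste0(mets$name, "[", mets$compartment, "]")
  if (any(bad_id)) {
    stop("validation error: metabolite id not of form name[compartment]: ",
         paste(mets$id[bad_id], collapse = ", "))
  }
  reactions <- lapply(seq_len(nrow(rxns)), function(i) {
    gs <- rxns$gene_set[i]
    genes_i <- if (is.na(gs) || !nzchar(gs)) character() else
      strsplit(gs, "|", fixed = TRUE)[[1]]
    s <- stoich[stoich$reaction_id == rxns$id[i], ]
    coef <- as.numeric(s$coefficient)
    names(coef) <- s$metabolite_id
    list(genes = genes_i, stoich = coef)
  })
  names(reactions) <- rxns$id
  metabolic_model(
    genes = genes,
    reactions = reactions,
    metabolites = data.frame(id = mets$id, base_name = mets$name,
                             compartment = mets$compartment,
                             formula = mets$formula,
                             stringsAsFactors = FALSE))
}

#' Write a metabolic model in the tabular dialect
#'
#' Emits the four TSVs read by [read_gem()] (`genes.tsv`, `metabolites.tsv`,
#' `reactions.tsv`, `stoich.tsv`) into `dir`. `write_gem` followed by
#' `read_gem` round-trips the model exactly.
#'
#' @param model a `tdl_gem`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gem <- function(model, dir) {
  stopifnot(inherits(model, "tdl_gem"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .write_tsv(data.frame(gene = model$genes), file.path(dir, "genes.tsv"))
  .write_tsv(data.frame(id = model$metabolites$id,
                        name = model$metabolites$base_name,
                        compartment = model$metabolites$compartment,
                        formula = model$metabolites$formula),
             file.path(dir, "metabolites.tsv"))
  .write_tsv(data.frame(
    id = names(model$reactions),
    gene_set = vapply(model$reactions,
                      function(r) paste(r$genes, collapse = "|"), "")),
    file.path(dir, "reactions.tsv"))
  st <- do.call(rbind, lapply(names(model$reactions), function(rid) {
    s <- model$reactions[[rid]]$stoich
    data.frame(reaction_id = rid, metabolite_id = names(s),
               coefficient = unname(s), stringsAsFactors = FALSE)
  }))
  .write_tsv(st, file.path(dir, "stoich.tsv"))
  invisible(dir)
}

.read_gem_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("parse error reading SBML '", path, "': ", conditionMessage(e))
  })
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("parse error: no <model> element in ", path)
  }
  # an fbc attribute may be serialized with any prefix; try the canonical
  # namespaced form first, then the bare name
  attr2 <- function(nodes, name) {
    v <- xml2::xml_attr(nodes, paste0("fbc:", name), ns = ns)
    bare <- xml2::xml_attr(nodes, name)
    ifelse(is.na(v), bare, v)
  }
  # gene products: fbc id -> label (symbol)
  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_id <- attr2(gp, "id")
  gp_label <- attr2(gp, "label")
  gp_label[is.na(gp_label)] <- gp_id[is.na(gp_label)]
  gene_map <- stats::setNames(normalize_genes(gp_label), gp_id)

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_name <- xml2::xml_attr(sp, "name")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_formula <- attr2(sp, "chemicalFormula")
  base <- ifelse(is.na(sp_name) | !nzchar(sp_name),
                 sub(paste0("_", sp_comp, "$"), "", sub("^M_", "", sp_id)),
                 sp_name)
  mets <- data.frame(id = paste0(base, "[", sp_comp, "]"),
                     base_name = base, compartment = sp_comp,
                     formula = sp_formula, stringsAsFactors = FALSE)
  sbml_to_id <- stats::setNames(mets$id, sp_id)

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L) stop("parse error: no reactions in ", path)
  reactions <- lapply(rx, function(node) {
    refs <- xml2::xml_find_all(node, ".//fbc:geneProductRef", ns)
    gp_refs <- attr2(refs, "geneProduct")
    genes <- unname(gene_map[gp_refs])
    genes <- genes[!is.na(genes)]
    if (length(gp_refs) && length(genes) < length(gp_refs)) {
      stop("validation error: reaction ",
           xml2::xml_attr(node, "id"),
           " cites undeclared gene product(s): ",
           paste(gp_refs[!gp_refs %in% names(gene_map)], collapse = ", "))
    }
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    ref_ids <- c(xml2::xml_attr(reac, "species"), xml2::xml_attr(prod, "species"))
    coefs <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
               as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    unknown <- setdiff(ref_ids, names(sbml_to_id))
    if (length(unknown)) {
      stop("validation error: reaction ", xml2::xml_attr(node, "id"),
           " cites undeclared species: ", paste(unknown, collapse = ", "))
    }
    stoich <- stats::setNames(coefs, unname(sbml_to_id[ref_ids]))
    list(genes = genes, stoich = stoich)
  })
  names(reactions) <- sub("^R_", "", xml2::xml_attr(rx, "id"))
  metabolic_model(genes = unname(gene_map), reactions = reactions,
                  metabolites = mets)
}
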