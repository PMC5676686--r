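#' Branch prediction container
#'
#' A set of predicted lipid entities (species- or class-level) produced by one
#' branch of the prediction strategy, with the differentially expressed genes
#' driving each entity.
#'
#' @param branch one of `"LMPD"`, `"PATHWAY"`, `"GEM"`.
#' @param entities data.frame with columns `level` (`"species"`/`"class"`),
#'   `name`, `class` (resolved lipid class, `NA` allowed for species without a
#'   vocabulary class, e.g. oxylipins).
#' @param gene_support named list keyed by `"<level>:<name>"`, each a
#'   character vector of driver genes (nonempty).
#' @return an object of class `tdl_branch`.
#' @export
branch_prediction <- function(branch, entities, gene_support) {
  branch <- match.arg(branch, c("LMPD", "PATHWAY", "GEM"))
  stopifnot(is.data.frame(entities),
            all(c("level", "name", "class") %in% names(entities)))
  keys <- .ent_keys(entities$level, entities$name)
  if (anyDuplicated(keys)) stop("duplicate entities in branch prediction")
  if (nrow(entities)) {
    stopifnot(all(entities$level %in% c("species", "class")))
    if (!setequal(names(gene_support), keys)) {
      stop("gene_support keys must match entities")
    }
    if (any(vapply(gene_support, length, 0L) == 0L)) {
      stop("every predicted entity needs at least one driver gene")
    }
  }
  rownames(entities) <- NULL
  structure(list(branch = branch, entities = entities,
                 gene_support = gene_support),
            class = "tdl_branch")
}

#' @export
print.tdl_branch <- function(x, ...) {
  cat(sprintf("tdl %s branch: %d predicted entities (%d species, %d class) from %d driver genes\n",
              x$branch, nrow(x$entities), sum(x$entities$level == "species"),
              sum(x$entities$level == "class"),
              length(unique(unlist(x$gene_support)))))
  invisible(x)
}

#' Driver genes of a branch prediction, pooled over entities
#' @param prediction a `tdl_branch`.
#' @return character vector of driver gene symbols.
#' @export
branch_genes <- function(prediction) {
  stopifnot(inherits(prediction, "tdl_branch"))
  sort(unique(unlist(prediction$gene_support, use.names = FALSE)))
}

.de_genes <- function(de) {
  g <- if (is.data.frame(de)) de$gene else de
  unique(normalize_genes(g))
}

# entity keys; paste0() on zero-length inputs would yield ":" (length 1)
.ent_keys <- function(level, name) {
  if (length(name) == 0L) return(character())
  paste0(level, ":", name)
}

.support_from_join <- function(join, lv, nm) {
  if (nrow(join) == 0L) return(list())
  keys <- paste0(lv, ":", nm)
  split(join$gene, factor(keys, levels = unique(keys)))
}

#' Lipid-gene database branch
#'
#' Joins the differentially expressed genes onto a lipid-gene annotation
#' table (LIPID MAPS Proteome Database style): every annotation label of a
#' differentially expressed, annotated gene becomes a predicted entity, with
#' the contributing genes recorded as its drivers.
#'
#' @param de DE table (data.frame with `gene`) or character vector of genes.
#' @param annot lipid-gene annotation data.frame (`gene`, `level`, `name`,
#'   `source`), see [read_lipid_gene_annotation()].
#' @return a [branch_prediction()] tagged `"LMPD"`.
#' @export
predict_lmpd <- function(de, annot) {
  stopifnot(is.data.frame(annot),
            all(c("gene", "level", "name") %in% names(annot)))
  if (nrow(annot) == 0L) stop("empty annotation table")
  annot$gene <- normalize_genes(annot$gene)
  hit <- annot[annot$gene %in% .de_genes(de), , drop = FALSE]
  ent <- unique(hit[, c("level", "name")])
  ent$class <- ifelse(ent$level == "class", ent$name,
                      lipid_class_of(ent$name))
  sup <- lapply(.support_from_join(hit, hit$level, hit$name),
                function(g) sort(unique(g)))
  branch_prediction("LMPD", ent, sup[.ent_keys(ent$level, ent$name)])
}

#' Pathway database branch
#'
#' Restricts a pathway annotation (Reactome style) to lipid-relevant
#' pathways, joins the differentially expressed genes, and predicts the
#' lipid classes those pathways map to. All entities are class-level.
#'
#' @param de DE table or character vector of genes.
#' @param annot pathway annotation data.frame (`gene`, `pathway_id`,
#'   `pathway_name`, `lipid_relevant`, optional `class`), see
#'   [read_pathway_annotation()].
#' @return a [branch_prediction()] tagged `"PATHWAY"`.
#' @export
predict_pathway <- function(de, annot) {
  stopifnot(is.data.frame(annot),
            all(c("gene", "pathway_id", "pathway_name", "lipid_relevant")
                %in% names(annot)))
  if (!"class" %in% names(annot)) annot$class <- annot$pathway_name
  annot$gene <- normalize_genes(annot$gene)
  hit <- annot[annot$lipid_relevant & annot$gene %in% .de_genes(de), ,
               drop = FALSE]
  ent <- unique(data.frame(level = rep("class", nrow(hit)), name = hit$class,
                           class = hit$class, stringsAsFactors = FALSE))
  sup <- lapply(.support_from_join(hit, rep("class", nrow(hit)), hit$class),
                function(g) sort(unique(g)))
  branch_prediction("PATHWAY", ent, sup[.ent_keys(ent$level, ent$name)])
}

#' Overlap of DE genes with the metabolic gene universe
#'
#' @param de DE table or character vector of genes.
#' @param model a `tdl_gem`.
#' @return character vector of genes present in both (canonical symbols).
#' @export
gem_gene_overlap <- function(de, model) {
  stopifnot(inherits(model, "tdl_gem"))
  sort(intersect(.de_genes(de), model$genes))
}

#' Map genes to the reactions they impact
#'
#' A reaction is impacted when its (flattened) gene association intersects
#' the query set; the intersection is recorded as the reaction's driver
#' genes. This is the binary gene-reaction incidence lookup.
#'
#' @param model a `tdl_gem`.
#' @param genes character vector; must lie within `model$genes`.
#' @return named list, reaction id -> character vector of driver genes
#'   (impacted reactions only).
#' @export
genes_to_reactions <- function(model, genes) {
  stopifnot(inherits(model, "tdl_gem"))
  genes <- normalize_genes(genes)
  outside <- setdiff(genes, model$genes)
  if (length(outside)) {
    stop("gene(s) outside the model universe: ",
         paste(outside, collapse = ", "))
  }
  drivers <- lapply(model$reactions, function(r) intersect(r$genes, genes))
  drivers[vapply(drivers, length, 0L) > 0L]
}

#' Metabolites touched by a set of reactions
#'
#' Union of metabolites with nonzero stoichiometry in any listed reaction;
#' substrates and products are both included (unsigned participation).
#'
#' @param model a `tdl_gem`.
#' @param reaction_ids character vector of reaction ids.
#' @return character vector of metabolite ids.
#' @export
reactions_to_metabolites <- function(model, reaction_ids) {
  stopifnot(inherits(model, "tdl_gem"))
  unknown <- setdiff(reaction_ids, names(model$reactions))
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  }
  mids <- unlist(lapply(model$reactions[reaction_ids],
                        function(r) names(r$stoich)), use.names = FALSE)
  if (is.null(mids)) character() else sort(unique(mids))
}

#' Elemental composition gate for lipid-like metabolites
#'
#' Retains metabolites whose formula has at least `min_counts` atoms of each
#' thresholded element (C4 H8 O2 by default, a practical cutoff for lipid and
#' lipid-related species). The threshold applies only to the listed elements;
#' additional elements (N, P, S, ...) neither help nor disqualify.
#' Metabolites without a parseable formula (missing or generic acyl-residue
#' formulas) are retained but flagged `unfiltered`; they are treated as
#' class-level predictions downstream. An optional stop-list (cofactors such
#' as ATP or NADP that pass the gate on raw composition) is applied last, by
#' base name.
#'
#' @param metabolites data.frame with columns `id`, `base_name`,
#'   `compartment`, `formula` (a subset of a model's metabolite table).
#' @param min_counts named minimum element counts.
#' @param stoplist character vector of base names to drop after filtering.
#' @return the filtered metabolite data.frame with a logical `unfiltered`
#'   column.
#' @export
composition_filter <- function(metabolites,
                               min_counts = c(C = 4L, H = 8L, O = 2L),
                               stoplist = NULL) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "base_name", "formula") %in% names(metabolites)))
  pass <- vapply(metabolites$formula, function(f) {
    formula_passes(f, min_counts)
  }, NA)
  out <- metabolites[is.na(pass) | pass, , drop = FALSE]
  out$unfiltered <- is.na(pass[is.na(pass) | pass])
  if (!is.null(stoplist)) {
    out <- out[!out$base_name %in% stoplist, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Driver-multiplicity statistics over impacted reactions
#'
#' A reaction is "singly driven" when exactly one differentially expressed
#' gene maps to it; a gene's singular-reaction count is the number of
#' reactions whose driver set is exactly that gene.
#'
#' @param reaction_map output of [genes_to_reactions()].
#' @return list with `n_reactions`, `driver_count_histogram` (table of driver
#'   set sizes), `singly_driven` (count), `multi_driven` (count), and
#'   `singular_per_gene` (named integer vector).
#' @export
reaction_driver_stats <- function(reaction_map) {
  sizes <- vapply(reaction_map, length, 0L)
  single <- unlist(reaction_map[sizes == 1L], use.names = FALSE)
  genes <- sort(unique(unlist(reaction_map, use.names = FALSE)))
  singular <- stats::setNames(integer(length(genes)), genes)
  if (length(single)) {
    tab <- table(single)
    singular[names(tab)] <- as.integer(tab)
  }
  list(n_reactions = length(reaction_map),
       driver_count_histogram = table(sizes),
       singly_driven = sum(sizes == 1L),
       multi_driven = sum(sizes > 1L),
       singular_per_gene = singular)
}

#' Collapse metabolites across cellular compartments
#'
#' One representative row per base name (the same chemical species can occur
#' in cytosol, mitochondria, ...). The first occurrence is kept; driver
#' aggregation happens upstream on ids.
#'
#' @param metabolites data.frame with `base_name`.
#' @return deduplicated data.frame.
#' @export
dedupe_across_compartments <- function(metabolites) {
  stopifnot(is.data.frame(metabolites), "base_name" %in% names(metabolites))
  out <- metabolites[!duplicated(metabolites$base_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-scale metabolic model branch
#'
#' The full gene -> reaction -> metabolite propagation: intersect the DE
#' genes with the model's gene universe, collect impacted reactions with
#' their drivers, collect participating metabolites, apply the composition
#' gate and the optional cofactor stop-list, deduplicate across compartments,
#' and turn the survivors into predicted entities. Base names ending in
#' `"pool"` and metabolites without a filterable formula become class-level
#' predictions (resolved through [lipid_class_of()]); everything else is a
#' species-level prediction. Unresolvable class-level candidates are dropped.
#'
#' @param de DE table or character vector of genes.
#' @param model a `tdl_gem`.
#' @param min_counts composition gate thresholds.
#' @param stoplist optional cofactor stop-list (base names).
#' @return a [branch_prediction()] tagged `"GEM"`, with attributes
#'   `overlap_genes`, `reaction_map`, `metabolite_ids`, `filtered_metabolites`
#'   exposing the intermediate stages.
#' @export
predict_gem <- function(de, model, min_counts = c(C = 4L, H = 8L, O = 2L),
                        stoplist = NULL) {
  overlap <- gem_gene_overlap(de, model)
  rmap <- genes_to_reactions(model, overlap)
  met_ids <- reactions_to_metabolites(model, names(rmap))
  mets <- model$metabolites[model$metabolites$id %in% met_ids, , drop = FALSE]
  kept <- composition_filter(mets, min_counts = min_counts, stoplist = stoplist)

  # drivers per metabolite id = union of drivers of reactions touching it
  drv <- new.env(parent = emptyenv())
  for (rid in names(rmap)) {
    for (mid in names(model$reactions[[rid]]$stoich)) {
      assign(mid, union(if (exists(mid, drv)) get(mid, drv) else character(),
                        rmap[[rid]]), envir = drv)
    }
  }

  uniq <- dedupe_across_compartments(kept)
  if (nrow(uniq) == 0L) {
    return(branch_prediction("GEM",
                             data.frame(level = character(), name = character(),
                                        class = character()),
                             list()))
  }
  is_pool <- grepl("pool$", uniq$base_name) | uniq$unfiltered
  cls <- lipid_class_of(uniq$base_name)
  ent <- data.frame(
    level = ifelse(is_pool, "class", "species"),
    name = ifelse(is_pool, cls, uniq$base_name),
    class = cls, stringsAsFactors = FALSE)
  keep <- !(ent$level == "class" & is.na(ent$name))
  ent <- ent[keep, , drop = FALSE]
  uniq <- uniq[keep, , drop = FALSE]

  # entity drivers: union over all compartment copies of member base names
  base_of <- kept$base_name
  sup <- lapply(seq_len(nrow(ent)), function(i) {
    ids <- kept$id[base_of == uniq$base_name[i]]
    sort(unique(unlist(lapply(ids, function(mid)
      if (exists(mid, drv)) get(mid, drv) else character()))))
  })
  names(sup) <- paste0(ent$level, ":", ent$name)

  # class-level entities may collapse (several pools/unfiltered species of one
  # class): merge duplicates, pooling drivers
  if (anyDuplicated(names(sup))) {
    sup <- lapply(split(sup, names(sup)),
                  function(l) sort(unique(unlist(l))))
    ent <- unique(ent)
    sup <- sup[paste0(ent$level, ":", ent$name)]
  }
  out <- branch_prediction("GEM", ent, sup)
  attr(out, "overlap_genes") <- overlap
  attr(out, "reaction_map") <- rmap
  attr(out, "metabolite_ids") <- met_ids
  attr(out, "filtered_metabolites") <- kept
  out
}
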