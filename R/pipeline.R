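#' Run the full prediction-and-evaluation pipeline
#'
#' Orchestrates the stages end to end: differential expression (or a
#' precomputed DE table), the enabled prediction branches, the consensus
#' merge with Venn accounting of driver genes, the measurement panel with
#' negative controls, and — when a measured lipid table is supplied — the
#' per-species and per-class evaluation. Inputs may be in-memory objects or
#' file paths (TSV / tabular or SBML model); tables are order-normalized
#' before processing so row order never changes the result. When `out_dir`
#' is set, stage outputs are written as TSVs along with a run manifest
#' (package version, configuration, input checksums).
#'
#' @param config a list (or path to a JSON/YAML config file) with entries:
#'   \describe{
#'     \item{expression, groups}{expression matrix TSV + groups TSV, or}
#'     \item{de}{precomputed DE table (TSV path or data.frame)}
#'     \item{lmpd}{lipid-gene annotation (path or data.frame)}
#'     \item{pathways}{pathway annotation (path or data.frame)}
#'     \item{gem}{metabolic model (path or `tdl_gem`)}
#'     \item{lipids, lipid_groups}{measured lipid table + groups (optional)}
#'     \item{controls}{negative-control classes (vector, or path to a
#'       one-per-line file)}
#'     \item{branches}{subset of `c("LMPD","PATHWAY","GEM")`; at least one}
#'     \item{q_max, fc_min, method, log_base, min_counts, stoplist, mode,
#'       absence_value}{thresholds and options with the usual defaults}
#'     \item{out_dir}{output directory (optional)}
#'   }
#' @param quiet suppress per-stage log lines.
#' @return list with `de_full`, `de`, `predictions`, `venn`, `consensus`,
#'   `panel`, `evaluation` (NULL without lipid data), `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- .read_config(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(branches = c("LMPD", "PATHWAY", "GEM"), q_max = 0.05, fc_min = 1.5,
         method = "anova", log_base = 2,
         min_counts = c(C = 4L, H = 8L, O = 2L), stoplist = NULL,
         mode = "strict", absence_value = 0.0001, controls = character(),
         out_dir = NULL),
    config)
  cfg$branches <- unlist(cfg$branches)
  cfg$min_counts <- unlist(cfg$min_counts)
  cfg$controls <- unlist(cfg$controls)
  if (is.null(cfg$controls)) cfg$controls <- character()
  if (length(cfg$branches) == 0L) stop("at least one branch must be enabled")
  cfg$branches <- match.arg(cfg$branches, c("LMPD", "PATHWAY", "GEM"),
                            several.ok = TRUE)
  stopifnot(cfg$q_max > 0, cfg$q_max <= 1, cfg$fc_min >= 1)
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- character()
  track <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      inputs <<- c(inputs, if (dir.exists(x)) {
        list.files(x, full.names = TRUE, recursive = TRUE)
      } else x)
    }
    x
  }

  # --- differential expression ----------------------------------------------
  if (!is.null(cfg$de)) {
    de_full <- if (is.character(cfg$de)) read_de_table(track(cfg$de)) else cfg$de
  } else {
    if (is.null(cfg$expression) || is.null(cfg$groups)) {
      stop("config needs either 'de' or 'expression' + 'groups'")
    }
    ex <- if (is.character(cfg$expression)) {
      read_expression(track(cfg$expression), track(cfg$groups))
    } else {
      list(matrix = cfg$expression, groups = cfg$groups)
    }
    ex$matrix <- ex$matrix[order(rownames(ex$matrix)), , drop = FALSE]
    de_full <- run_de(ex$matrix, ex$groups, method = cfg$method,
                      log_base = cfg$log_base)
  }
  de_full <- de_full[order(de_full$gene), , drop = FALSE]
  de <- filter_de(de_full, q_max = cfg$q_max, fc_min = cfg$fc_min)
  say("de: %d genes tested, %d pass q<%g & |fc|>%g", nrow(de_full), nrow(de),
      cfg$q_max, cfg$fc_min)

  # --- branches --------------------------------------------------------------
  predictions <- list()
  if ("LMPD" %in% cfg$branches) {
    if (is.null(cfg$lmpd)) stop("LMPD branch enabled but no 'lmpd' input")
    annot <- if (is.character(cfg$lmpd)) {
      read_lipid_gene_annotation(track(cfg$lmpd))
    } else cfg$lmpd
    annot <- annot[order(annot$gene, annot$name), , drop = FALSE]
    predictions$LMPD <- predict_lmpd(de, annot)
    say("lmpd: %d entities from %d driver genes",
        nrow(predictions$LMPD$entities), length(branch_genes(predictions$LMPD)))
  }
  if ("PATHWAY" %in% cfg$branches) {
    if (is.null(cfg$pathways)) stop("PATHWAY branch enabled but no 'pathways' input")
    annot <- if (is.character(cfg$pathways)) {
      read_pathway_annotation(track(cfg$pathways))
    } else cfg$pathways
    annot <- annot[order(annot$gene, annot$pathway_id), , drop = FALSE]
    predictions$PATHWAY <- predict_pathway(de, annot)
    say("pathway: %d entities from %d driver genes",
        nrow(predictions$PATHWAY$entities),
        length(branch_genes(predictions$PATHWAY)))
  }
  if ("GEM" %in% cfg$branches) {
    if (is.null(cfg$gem)) stop("GEM branch enabled but no 'gem' input")
    model <- if (is.character(cfg$gem)) {
      track(cfg$gem); read_gem(cfg$gem)
    } else cfg$gem
    predictions$GEM <- predict_gem(de, model, min_counts = cfg$min_counts,
                                   stoplist = cfg$stoplist)
    rmap <- attr(predictions$GEM, "reaction_map")
    say("gem: %d overlap genes -> %d reactions -> %d metabolites -> %d entities",
        length(attr(predictions$GEM, "overlap_genes")), length(rmap),
        length(attr(predictions$GEM, "metabolite_ids")),
        nrow(predictions$GEM$entities))
  }

  # --- consensus + panel ------------------------------------------------------
  consensus <- merge_branches(unname(predictions))
  venn <- if (length(predictions) == 3L) {
    venn_counts(lapply(predictions, branch_genes))
  } else NULL
  if (is.character(cfg$controls) && length(cfg$controls) == 1L &&
      file.exists(cfg$controls)) {
    cfg$controls <- readLines(track(cfg$controls))
  }
  panel <- build_measurement_panel(consensus, cfg$controls)
  say("consensus: %d entities; panel: %d rows (%d negative controls)",
      nrow(consensus$entities), nrow(panel),
      sum(panel$tag == "negative-control"))

  # --- evaluation -------------------------------------------------------------
  evaluation <- NULL
  if (!is.null(cfg$lipids)) {
    table <- if (is.character(cfg$lipids)) {
      read_lipid_table(track(cfg$lipids), track(cfg$lipid_groups))
    } else cfg$lipids
    table$intensities <- table$intensities[order(rownames(table$intensities)), ,
                                           drop = FALSE]
    table$classes <- table$classes[rownames(table$intensities)]
    evaluation <- evaluate_lipidome(table, consensus, q_max = cfg$q_max,
                                    mode = cfg$mode,
                                    absence_value = cfg$absence_value)
    say("evaluation: %d/%d species significant; %d classes scored",
        sum(evaluation$per_species$significant),
        nrow(evaluation$per_species), nrow(evaluation$per_class))
  }

  manifest <- list(
    package = "tdl",
    version = as.character(utils::packageVersion("tdl")),
    config = cfg[setdiff(names(cfg), c("expression", "groups", "de", "lmpd",
                                       "pathways", "gem", "lipids",
                                       "lipid_groups"))],
    input_checksums = as.list(tools::md5sum(unique(inputs))))

  result <- list(de_full = de_full, de = de, predictions = predictions,
                 venn = venn, consensus = consensus, panel = panel,
                 evaluation = evaluation, manifest = manifest)
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(result, cfg$out_dir)
  result
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .write_tsv(result$de, file.path(dir, "de.tsv"))
  .write_tsv(result$panel, file.path(dir, "panel.tsv"))
  .write_tsv(result$consensus$entities, file.path(dir, "consensus.tsv"))
  if (!is.null(result$evaluation)) {
    .write_tsv(result$evaluation$per_species, file.path(dir, "per_species.tsv"))
    .write_tsv(result$evaluation$per_class, file.path(dir, "per_class.tsv"))
  }
  if (!is.null(result$venn)) {
    jsonlite::write_json(
      list(totals = as.list(result$venn$totals),
           pairwise = as.list(result$venn$pairwise),
           triple = result$venn$triple,
           regions = as.list(result$venn$regions),
           union = result$venn$union,
           exactly_one = result$venn$exactly_one,
           exactly_two = result$venn$exactly_two),
      file.path(dir, "venn.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}
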