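#' Construct a measured lipid table
#'
#' Species-by-sample intensities for a two-group lipidomics experiment.
#' Absences (species not detected in a sample) are explicit `NA`, never zero:
#' downstream logic distinguishes "absent" from "measured low". Every species
#' carries a lipid-class label; every sample belongs to one of exactly two
#' groups.
#'
#' @param intensities numeric matrix, species in rows (rownames = species
#'   names), samples in columns; `NA` = absent.
#' @param classes character vector of class labels, one per species.
#' @param groups named character vector mapping sample -> group label.
#' @param strict_vocabulary if `TRUE`, class labels must come from
#'   [lipid_class_vocabulary()].
#' @return an object of class `tdl_lipid_table`.
#' @export
lipid_table <- function(intensities, classes, groups, strict_vocabulary = FALSE) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  if (length(classes) != nrow(intensities)) {
    stop("need one class label per species")
  }
  if (anyNA(classes) || any(!nzchar(classes))) {
    stop("species without class label: ",
         paste(rownames(intensities)[is.na(classes) | !nzchar(classes)],
               collapse = ", "))
  }
  if (strict_vocabulary) {
    bad <- setdiff(unique(classes), lipid_class_vocabulary())
    if (length(bad)) {
      stop("class label(s) outside the lipid-class vocabulary: ",
           paste(bad, collapse = ", "))
    }
  }
  miss <- setdiff(colnames(intensities), names(groups))
  if (length(miss)) stop("sample(s) without group label: ",
                         paste(miss, collapse = ", "))
  groups <- groups[colnames(intensities)]
  lv <- unique(groups)
  if (length(lv) != 2L) {
    stop("exactly 2 groups required, got ", length(lv), ": ",
         paste(lv, collapse = ", "))
  }
  if (any(is.finite(intensities) & intensities < 0)) {
    stop("negative intensities are not allowed")
  }
  structure(list(intensities = intensities,
                 classes = stats::setNames(classes, rownames(intensities)),
                 groups = groups),
            class = "tdl_lipid_table")
}

#' @export
print.tdl_lipid_table <- function(x, ...) {
  cat(sprintf("tdl lipid table: %d species (%d classes), %d samples (%s)\n",
              nrow(x$intensities), length(unique(x$classes)),
              ncol(x$intensities),
              paste(sprintf("%s n=%d", unique(x$groups),
                            table(x$groups)[unique(x$groups)]),
                    collapse = ", ")))
  invisible(x)
}

#' Read a measured lipid table from TSV
#'
#' Expects a TSV with columns `species`, `class`, then one column per sample;
#' the literal `NA` marks an absent lipid. Sample groups come either from a
#' two-column TSV (`sample`, `group`) or a named character vector.
#'
#' @param path lipid TSV path.
#' @param groups path to a groups TSV, or a named character vector
#'   sample -> group.
#' @param strict_vocabulary passed to [lipid_table()].
#' @return a `tdl_lipid_table`.
#' @export
read_lipid_table <- function(path, groups, strict_vocabulary = FALSE) {
  df <- .read_tsv(path, c("species", "class"))
  sample_cols <- setdiff(names(df), c("species", "class"))
  if (length(sample_cols) < 2L) stop("parse error: no sample columns in ", path)
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$species
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    g <- .read_tsv(groups, c("sample", "group"))
    groups <- stats::setNames(g$group, g$sample)
  }
  lipid_table(m, df$class, groups, strict_vocabulary = strict_vocabulary)
}

#' Write a measured lipid table to TSV
#'
#' @param table a `tdl_lipid_table`.
#' @param path output TSV; a companion `<path>.groups.tsv` is written unless
#'   `groups_path` is given.
#' @param groups_path optional explicit path for the groups TSV.
#' @return `path`, invisibly.
#' @export
write_lipid_table <- function(table, path,
                              groups_path = paste0(path, ".groups.tsv")) {
  stopifnot(inherits(table, "tdl_lipid_table"))
  df <- data.frame(species = rownames(table$intensities),
                   class = unname(table$classes),
                   table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(data.frame(sample = names(table$groups),
                        group = unname(table$groups)), groups_path)
  invisible(path)
}

#' Read a differential-expression table from TSV
#'
#' Columns: `gene`, `fc` (signed linear fold change), `p`, `q`, `direction`.
#' Gene symbols are normalized; basic range/consistency checks are applied.
#'
#' @param path TSV path.
#' @return a `data.frame` DE table as produced by [run_de()].
#' @export
read_de_table <- function(path) {
  df <- .read_tsv(path, c("gene", "fc", "p", "q", "direction"))
  df$gene <- normalize_genes(df$gene)
  if (anyDuplicated(df$gene)) {
    stop("validation error: duplicate gene symbols in ", path)
  }
  if (any(df$q < 0 | df$q > 1, na.rm = TRUE)) {
    stop("validation error: q outside [0,1] in ", path)
  }
  df
}

#' Read an expression matrix and sample groups from TSV
#'
#' Matrix TSV: column `gene` then one column per sample (log-scale values);
#' groups TSV: columns `sample`, `group`.
#'
#' @param matrix_path expression TSV.
#' @param groups_path groups TSV.
#' @return list with `matrix` (genes x samples) and `groups` (named character).
#' @export
read_expression <- function(matrix_path, groups_path) {
  df <- .read_tsv(matrix_path, "gene")
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- normalize_genes(df$gene)
  g <- .read_tsv(groups_path, c("sample", "group"))
  list(matrix = m, groups = stats::setNames(g$group, g$sample))
}

#' Read a lipid-gene annotation table (LMPD-style)
#'
#' Columns: `gene`, `level` (`"species"` or `"class"`), `name` (lipid species
#' or class label), `source`.
#'
#' @param path TSV path.
#' @return data.frame with normalized gene symbols.
#' @export
read_lipid_gene_annotation <- function(path) {
  df <- .read_tsv(path, c("gene", "level", "name", "source"))
  df$gene <- normalize_genes(df$gene)
  bad <- !df$level %in% c("species", "class")
  if (any(bad)) stop("validation error: level must be species/class, got: ",
                     paste(unique(df$level[bad]), collapse = ", "))
  df
}

#' Read a pathway annotation table (Reactome-style)
#'
#' Columns: `gene`, `pathway_id`, `pathway_name`, `lipid_relevant`
#' (TRUE/FALSE); an optional `class` column gives the lipid class a
#' lipid-relevant pathway maps to (defaults to `pathway_name`).
#'
#' @param path TSV path.
#' @return data.frame with normalized gene symbols and logical
#'   `lipid_relevant`.
#' @export
read_pathway_annotation <- function(path) {
  df <- .read_tsv(path, c("gene", "pathway_id", "pathway_name", "lipid_relevant"))
  df$gene <- normalize_genes(df$gene)
  df$lipid_relevant <- as.logical(df$lipid_relevant)
  if (anyNA(df$lipid_relevant)) {
    stop("validation error: lipid_relevant must be TRUE/FALSE in ", path)
  }
  if (!"class" %in% names(df)) df$class <- df$pathway_name
  df
}
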