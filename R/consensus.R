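.BRANCHES <- c(GEM = "G", LMPD = "L", PATHWAY = "R")

#' Branch-support string
#'
#' Renders a subset of branches as a fixed-width mask in G/L/R order (GEM,
#' lipid-gene database, pathway database), e.g. `"GLR"`, `"-L-"`.
#'
#' @param branches character vector, subset of `c("GEM","LMPD","PATHWAY")`.
#' @return single character mask.
#' @export
branch_mask <- function(branches) {
  paste(ifelse(names(.BRANCHES) %in% branches, .BRANCHES, "-"), collapse = "")
}

#' Merge branch predictions into a consensus predicted lipidome
#'
#' Deduplicates predicted entities by level + name across branches and
#' records, per entity, which branches predicted it directly and the driver
#' genes per branch. A species-level prediction additionally marks its parent
#' class as having *implied* support from that branch (kept separate from
#' direct support so class-level evaluation can run in strict or permissive
#' mode). The merge is order-invariant.
#'
#' @param predictions list of [branch_prediction()] objects, at most one per
#'   branch.
#' @return an object of class `tdl_consensus`: list with `entities`
#'   (data.frame: `level`, `name`, `class`, `branches` direct mask,
#'   `implied_branches` mask, `driver_genes` pipe-joined by branch) and
#'   `support` (named list keyed `"<level>:<name>"` with per-branch direct and
#'   implied flags and drivers).
#' @export
merge_branches <- function(predictions) {
  stopifnot(is.list(predictions),
            all(vapply(predictions, inherits, NA, "tdl_branch")))
  tags <- vapply(predictions, function(p) p$branch, "")
  if (anyDuplicated(tags)) {
    stop("duplicate branch tag: ", paste(tags[duplicated(tags)], collapse = ", "))
  }
  predictions <- predictions[order(match(tags, names(.BRANCHES)))]

  sup <- list() # key -> list(level, name, class, direct=chr, implied=chr, drivers=list)
  touch <- function(key, level, name, class) {
    if (is.null(sup[[key]])) {
      sup[[key]] <<- list(level = level, name = name, class = class,
                          direct = character(), implied = character(),
                          drivers = list())
    } else if (is.na(sup[[key]]$class) && !is.na(class)) {
      sup[[key]]$class <<- class
    }
  }
  for (p in predictions) {
    for (i in seq_len(nrow(p$entities))) {
      e <- p$entities[i, ]
      key <- paste0(e$level, ":", e$name)
      touch(key, e$level, e$name, e$class)
      sup[[key]]$direct <- union(sup[[key]]$direct, p$branch)
      drv <- p$gene_support[[key]]
      sup[[key]]$drivers[[p$branch]] <-
        sort(union(sup[[key]]$drivers[[p$branch]], drv))
      if (e$level == "species" && !is.na(e$class)) {
        ckey <- paste0("class:", e$class)
        touch(ckey, "class", e$class, e$class)
        sup[[ckey]]$implied <- union(sup[[ckey]]$implied, p$branch)
        sup[[ckey]]$drivers[[p$branch]] <-
          sort(union(sup[[ckey]]$drivers[[p$branch]], drv))
      }
    }
  }
  ord <- order(vapply(sup, function(s) paste0(s$level, ":", s$name), ""))
  sup <- sup[ord]
  ent <- data.frame(
    level = vapply(sup, `[[`, "", "level"),
    name = vapply(sup, `[[`, "", "name"),
    class = vapply(sup, `[[`, "", "class"),
    branches = vapply(sup, function(s) branch_mask(s$direct), ""),
    implied_branches = vapply(sup, function(s) branch_mask(s$implied), ""),
    driver_genes = vapply(sup, function(s) {
      paste(vapply(names(s$drivers), function(b)
        paste0(b, "=", paste(s$drivers[[b]], collapse = ",")), ""),
        collapse = "|")
    }, ""),
    stringsAsFactors = FALSE)
  rownames(ent) <- NULL
  structure(list(entities = ent, support = sup), class = "tdl_consensus")
}

#' @export
print.tdl_consensus <- function(x, ...) {
  cat(sprintf("tdl consensus lipidome: %d entities (%d species-level, %d class-level)\n",
              nrow(x$entities), sum(x$entities$level == "species"),
              sum(x$entities$level == "class")))
  invisible(x)
}

#' Per-class branch support counts from a consensus
#'
#' @param consensus a `tdl_consensus`.
#' @param mode `"strict"` counts only direct class-level predictions;
#'   `"permissive"` also counts branches whose species-level predictions imply
#'   the class.
#' @return named integer vector, class -> number of supporting branches (0-3).
#' @export
class_branch_support <- function(consensus, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(consensus, "tdl_consensus"))
  cls_rows <- Filter(function(s) s$level == "class", consensus$support)
  counts <- vapply(cls_rows, function(s) {
    b <- if (mode == "strict") s$direct else union(s$direct, s$implied)
    length(b)
  }, 0L)
  stats::setNames(counts, vapply(cls_rows, `[[`, "", "name"))
}

#' Three-set Venn accounting of branch driver genes
#'
#' Computes all seven Venn regions for the driver-gene sets of the three
#' branches, plus the derived union and exactly-one / exactly-two / triple
#' counts, and the per-branch unique counts. Inclusion-exclusion holds by
#' construction since everything is counted from set memberships.
#'
#' @param gene_sets named list of exactly three character vectors.
#' @return an object of class `tdl_venn`: list with `totals`, `pairwise`,
#'   `triple`, `regions` (7 exclusive region sizes), `union`, `exactly_one`,
#'   `exactly_two`, `unique` (per-branch exclusive counts).
#' @export
venn_counts <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) == 3L,
            !is.null(names(gene_sets)))
  gene_sets <- lapply(gene_sets, unique)
  nm <- names(gene_sets)
  all_genes <- unique(unlist(gene_sets, use.names = FALSE))
  member <- vapply(gene_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1,
                                                dimnames = list(NULL, nm))
  k <- rowSums(member)
  region_key <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  all_keys <- c(nm,
                paste(nm[c(1, 1, 2)], nm[c(2, 3, 3)], sep = "&"),
                paste(nm, collapse = "&"))
  regions <- stats::setNames(integer(length(all_keys)), all_keys)
  tab <- table(region_key)
  regions[names(tab)] <- as.integer(tab)
  pairwise <- c(
    stats::setNames(length(intersect(gene_sets[[1]], gene_sets[[2]])),
                    paste(nm[1], nm[2], sep = "&")),
    stats::setNames(length(intersect(gene_sets[[1]], gene_sets[[3]])),
                    paste(nm[1], nm[3], sep = "&")),
    stats::setNames(length(intersect(gene_sets[[2]], gene_sets[[3]])),
                    paste(nm[2], nm[3], sep = "&")))
  structure(list(
    totals = vapply(gene_sets, length, 0L),
    pairwise = pairwise,
    triple = length(Reduce(intersect, gene_sets)),
    regions = regions,
    union = length(all_genes),
    exactly_one = sum(k == 1),
    exactly_two = sum(k == 2),
    unique = stats::setNames(regions[nm], nm)),
    class = "tdl_venn")
}

#' @export
print.tdl_venn <- function(x, ...) {
  cat("tdl Venn accounting\n")
  cat("  totals: ", paste(sprintf("%s=%d", names(x$totals), x$totals),
                          collapse = ", "), "\n")
  cat("  union =", x$union, "| exactly-one =", x$exactly_one,
      "| exactly-two =", x$exactly_two, "| triple =", x$triple, "\n")
  invisible(x)
}

#' Assemble the measurement panel
#'
#' The panel is what gets sent for lipidomics measurement: all predicted
#' species, all predicted classes, and the negative-control classes
#' (classes no branch predicted, measured to test specificity). Provenance
#' tags partition the panel; a control class with any branch support (direct
#' or implied) is an error.
#'
#' @param consensus a `tdl_consensus`.
#' @param control_classes character vector of negative-control class labels.
#' @return data.frame panel: `entity`, `level`, `class`, `branches`,
#'   `driver_genes`, `tag`.
#' @export
build_measurement_panel <- function(consensus, control_classes = character()) {
  stopifnot(inherits(consensus, "tdl_consensus"))
  ent <- consensus$entities
  supported <- unique(stats::na.omit(c(
    ent$class[ent$level == "class"],
    ent$class[ent$level == "species"])))
  clash <- intersect(control_classes, supported)
  if (length(clash)) {
    stop("negative-control class(es) predicted by a branch: ",
         paste(clash, collapse = ", "))
  }
  panel <- data.frame(
    entity = ent$name, level = ent$level, class = ent$class,
    branches = ent$branches, driver_genes = ent$driver_genes,
    tag = ifelse(ent$level == "species", "species-predicted",
                 "class-predicted"),
    stringsAsFactors = FALSE)
  if (length(control_classes)) {
    panel <- rbind(panel, data.frame(
      entity = control_classes, level = "class", class = control_classes,
      branches = "---", driver_genes = "", tag = "negative-control",
      stringsAsFactors = FALSE))
  }
  rownames(panel) <- NULL
  panel
}
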