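#' Validate a normalized expression matrix
#'
#' An expression matrix is a base numeric matrix of normalized, nonnegative
#' expression values with genes in rows and cells in columns; row and column
#' names carry the gene and cell identifiers. Identifiers are case-sensitive
#' exact strings and must be unique.
#'
#' @param expr Numeric matrix, genes x cells, with unique dimnames.
#' @return The validated matrix, invisibly usable downstream. Genes whose
#'   total expression is zero are retained; their ids are attached as the
#'   `"zero_genes"` attribute.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (genes x cells).")
  }
  genes <- rownames(expr)
  cells <- colnames(expr)
  if (is.null(genes) || is.null(cells)) {
    abort("`expr` must carry gene ids as rownames and cell ids as colnames.")
  }
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g)) {
    abort(sprintf("duplicate gene id(s): %s", paste(head(dup_g, 5), collapse = ", ")))
  }
  dup_c <- unique(cells[duplicated(cells)])
  if (length(dup_c)) {
    abort(sprintf("duplicate cell id(s): %s", paste(head(dup_c, 5), collapse = ", ")))
  }
  if (any(!is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite expression value at gene '%s', cell '%s'",
                  genes[bad[1]], cells[bad[2]]))
  }
  if (any(expr < 0)) {
    bad <- which(expr < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative expression value at gene '%s', cell '%s'",
                  genes[bad[1]], cells[bad[2]]))
  }
  zero <- genes[rowSums(expr) == 0]
  attr(expr, "zero_genes") <- zero
  expr
}

#' Validate cell group labels against an expression matrix
#'
#' Labels map each cell id to a cell-group name. Groups smaller than
#' `min_cells` after intersecting with the expression matrix are dropped with
#' a warning, mirroring the common practice of excluding groups too small to
#' support communication inference.
#'
#' @param labels Data frame with columns `cell` and `group`.
#' @param expr Validated expression matrix the labels refer to.
#' @param min_cells Minimum group size retained (default 10).
#' @return A tibble with columns `cell`, `group` (factor with the retained
#'   group levels, in first-appearance order).
#' @export
validate_labels <- function(labels, expr, min_cells = 10) {
  labels <- as_tibble(labels)
  if (!all(c("cell", "group") %in% names(labels))) {
    abort("`labels` must have columns `cell` and `group`.")
  }
  labels$cell <- as.character(labels$cell)
  labels$group <- as.character(labels$group)
  if (anyDuplicated(labels$cell)) {
    abort(sprintf("cell '%s' is labeled more than once",
                  labels$cell[duplicated(labels$cell)][1]))
  }
  missing <- setdiff(labels$cell, colnames(expr))
  if (length(missing)) {
    abort(sprintf("labeled cell(s) absent from the expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  sizes <- table(labels$group)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warn(sprintf("dropping group(s) with fewer than %d cells: %s",
                 min_cells, paste(small, collapse = ", ")))
    labels <- labels[!labels$group %in% small, , drop = FALSE]
  }
  if (nrow(labels) == 0L) abort("no groups remain after size filtering")
  labels$group <- factor(labels$group, levels = unique(labels$group))
  labels
}

#' Validate a ligand-receptor pair database
#'
#' @param lrdb Data frame with columns `pair`, `ligand`, `receptor`,
#'   `pathway`; multi-subunit ligands/receptors are `&`-joined gene lists.
#' @return A validated tibble.
#' @export
validate_lr_database <- function(lrdb) {
  lrdb <- as_tibble(lrdb)
  need <- c("pair", "ligand", "receptor", "pathway")
  if (!all(need %in% names(lrdb))) {
    abort(sprintf("`lrdb` must have columns: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(lrdb$pair)) {
    abort(sprintf("duplicate ligand-receptor pair id '%s'",
                  lrdb$pair[duplicated(lrdb$pair)][1]))
  }
  empty <- lrdb$pair[!nzchar(lrdb$ligand) | !nzchar(lrdb$receptor)]
  if (length(empty)) {
    abort(sprintf("pair '%s' has an empty ligand or receptor subunit set", empty[1]))
  }
  lrdb
}

#' Validate a directed prior edge list
#'
#' Prior edges connect receptors to TFs (`layer = "receptor_tf"`) or TFs to
#' target genes (`layer = "tf_target"`). Self-loops within a layer are
#' rejected. An optional `sign` column (+1/-1) and `confidence` grade are
#' carried through.
#'
#' @param edges Data frame with columns `source`, `target`, `layer`.
#' @return A validated tibble; a missing `sign` column defaults to +1.
#' @export
validate_prior_edges <- function(edges) {
  edges <- as_tibble(edges)
  if (!all(c("source", "target", "layer") %in% names(edges))) {
    abort("`edges` must have columns `source`, `target`, `layer`.")
  }
  bad_layer <- setdiff(unique(edges$layer), c("receptor_tf", "tf_target"))
  if (length(bad_layer)) {
    abort(sprintf("unknown prior layer tag '%s'", bad_layer[1]))
  }
  loops <- edges$source == edges$target
  if (any(loops)) {
    abort(sprintf("self-loop on gene '%s' in layer '%s'",
                  edges$source[loops][1], edges$layer[loops][1]))
  }
  if (!"sign" %in% names(edges)) edges$sign <- 1
  if (!all(edges$sign %in% c(-1, 1))) {
    abort("prior edge `sign` values must be -1 or +1")
  }
  edges
}

#' Build a binary prior mask from a TF-target edge list
#'
#' The mask N is a targets x TFs 0/1 matrix: 1 marks a known (prior) TF to
#' target-gene regulatory edge, 0 the absence of prior support.
#'
#' @param edges Prior edge list (only rows with `layer == "tf_target"` used;
#'   `source` = TF, `target` = target gene).
#' @param targets,tfs Ordered row (target) and column (TF) identifiers.
#' @return Binary matrix with `targets` rownames and `tfs` colnames.
#' @export
prior_mask <- function(edges, targets, tfs) {
  edges <- validate_prior_edges(edges)
  edges <- edges[edges$layer == "tf_target", , drop = FALSE]
  N <- matrix(0, length(targets), length(tfs), dimnames = list(targets, tfs))
  keepit <- edges$target %in% targets & edges$source %in% tfs
  e <- edges[keepit, , drop = FALSE]
  if (nrow(e)) N[cbind(e$target, e$source)] <- 1
  N
}
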