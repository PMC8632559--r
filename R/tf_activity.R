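#' Estimate per-cell TF activity from regulon target expression
#'
#' TF activity is hard to measure directly but can be read off the expression
#' of the TF's known targets (its regulon). The estimate used here is a
#' signed mean of z-scores: each regulon target's expression is z-scored
#' across cells, multiplied by the regulation sign (+1 activating, -1
#' repressing), and averaged over the TF's targets present in the matrix.
#' Activity matrices computed by an external regulon-activity method can be
#' supplied instead through [read_tf_activity()]; both routes feed the same
#' downstream regression.
#'
#' TFs with no regulon target in the expression matrix are dropped with a
#' message. Targets with zero variance across cells contribute 0.
#'
#' @param expr Expression matrix (genes x cells).
#' @param regulons Prior edge list restricted to `layer == "tf_target"`
#'   (`source` = TF, `target` = regulon target, optional `sign`).
#' @return Numeric matrix, TFs x cells (same cell order as `expr`).
#' @export
estimate_tf_activity <- function(expr, regulons) {
  expr <- validate_expression(expr)
  regulons <- validate_prior_edges(regulons)
  regulons <- regulons[regulons$layer == "tf_target", , drop = FALSE]
  if (!nrow(regulons)) abort("empty regulon set")
  present <- regulons$target %in% rownames(expr)
  dropped <- setdiff(unique(regulons$source), unique(regulons$source[present]))
  if (length(dropped)) {
    inform(sprintf("dropping %d TF(s) with no regulon target in the expression matrix: %s",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  regulons <- regulons[present, , drop = FALSE]
  if (!nrow(regulons)) abort("no TF has a regulon target in the expression matrix")

  targets <- unique(regulons$target)
  x <- expr[targets, , drop = FALSE]
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0

  tfs <- unique(regulons$source)
  act <- matrix(0, length(tfs), ncol(expr), dimnames = list(tfs, colnames(expr)))
  for (tf in tfs) {
    e <- regulons[regulons$source == tf, , drop = FALSE]
    act[tf, ] <- colMeans(z[e$target, , drop = FALSE] * e$sign)
  }
  act
}
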