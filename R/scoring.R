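#' Per-group mean expression with a detection-fraction floor
#'
#' Computes, for every gene and cell group, the arithmetic mean of normalized
#' expression over the group's cells. Means of genes detected (value > 0) in
#' fewer than `expr_frac_min` of the group's cells are set to 0, so that
#' rarely detected genes cannot drive communication scores.
#'
#' @param expr Validated expression matrix (genes x cells).
#' @param labels Validated cell labels (`cell`, `group`).
#' @param expr_frac_min Minimum detection fraction (default 0.1).
#' @return Numeric matrix, genes x groups.
#' @export
group_mean_expression <- function(expr, labels, expr_frac_min = 0.1) {
  groups <- levels(labels$group) %||% unique(labels$group)
  cells <- labels$cell
  grp <- factor(as.character(labels$group), levels = groups)
  if (any(table(grp) == 0)) abort("a cell group is empty after filtering")
  x <- expr[, cells, drop = FALSE]
  # rowsum works over rows; transpose so cells are rows
  sums <- t(rowsum(t(x), grp))
  det <- t(rowsum(t(x > 0) * 1, grp))
  n <- as.vector(table(grp))
  means <- sweep(sums, 2, n, "/")
  frac <- sweep(det, 2, n, "/")
  means[frac < expr_frac_min] <- 0
  means
}

score_tensor_probs <- function(gm, lig_sub, rec_sub, kh) {
  # gm: genes x groups means; lig_sub/rec_sub: list per pair of subunit genes
  groups <- colnames(gm)
  n_pair <- length(lig_sub)
  L <- matrix(0, length(groups), n_pair)  # sender x pair
  R <- matrix(0, length(groups), n_pair)
  for (k in seq_len(n_pair)) {
    L[, k] <- apply(gm[lig_sub[[k]], , drop = FALSE], 2, geom_mean)
    R[, k] <- apply(gm[rec_sub[[k]], , drop = FALSE], 2, geom_mean)
  }
  # P(s, r, k) = L(s,k) R(r,k) / (kh + L(s,k) R(r,k)), a Hill-type saturation
  out <- array(0, dim = c(length(groups), length(groups), n_pair))
  for (k in seq_len(n_pair)) {
    lr <- outer(L[, k], R[, k])
    out[, , k] <- lr / (kh + lr)
  }
  out
}

#' Score ligand-receptor communication between cell groups
#'
#' A self-contained communication scorer so the downstream comparison and
#' multiscale machinery can run on expression data alone; precomputed
#' communication tables from an external inference tool can be supplied
#' instead via [as_comm_tensor()] / [read_comm_tensor()].
#'
#' For each ligand-receptor pair the ligand score of a sender group is the
#' geometric mean of the ligand subunits' group means (a zero subunit zeroes
#' the complex, encoding the multi-subunit requirement of ligand-receptor
#' complexes), and likewise the receptor score of a receiver group. The
#' communication probability is the Hill-type saturation
#' `P = L*R / (kh + L*R)`, and significance is assessed by permuting group
#' labels across cells: the p-value is the fraction of permutations whose
#' recomputed probability reaches the observed one. Probabilities with
#' `pval > alpha` are zeroed.
#'
#' Pairs with no ligand or no receptor subunit present in the expression
#' matrix are skipped with a message; subunits absent from the matrix are
#' dropped from a pair's geometric mean.
#'
#' @param expr Expression matrix (genes x cells).
#' @param labels Cell labels (`cell`, `group`); validated against `expr`.
#' @param lrdb Ligand-receptor database tibble.
#' @param kh Half-saturation constant of the Hill response (default 0.5).
#' @param n_perm Number of label permutations (default 100; must be >= 1).
#' @param seed Integer seed for the permutations.
#' @param alpha Significance level (default 0.05).
#' @param expr_frac_min Detection-fraction floor for group means.
#' @param condition Condition label stored in the tensor.
#' @param min_cells Minimum group size (see [validate_labels()]).
#' @return A `comm_tensor`.
#' @export
score_communication <- function(expr, labels, lrdb, kh = 0.5, n_perm = 100,
                                seed = 0, alpha = 0.05, expr_frac_min = 0.1,
                                condition = "condition1", min_cells = 10) {
  expr <- validate_expression(expr)
  labels <- validate_labels(labels, expr, min_cells = min_cells)
  # canonical cell order makes scores AND permutation p-values independent of
  # the order cells arrive in
  labels <- labels[order(labels$cell), , drop = FALSE]
  lrdb <- validate_lr_database(lrdb)
  stopifnot_scalar_number(kh, "kh", positive = TRUE)
  if (!is.numeric(n_perm) || n_perm < 1) abort("`n_perm` must be >= 1")

  lig_all <- split_subunits(lrdb$ligand)
  rec_all <- split_subunits(lrdb$receptor)
  lig_sub <- map(lig_all, intersect, rownames(expr))
  rec_sub <- map(rec_all, intersect, rownames(expr))
  usable <- lengths(lig_sub) > 0 & lengths(rec_sub) > 0
  if (!all(usable)) {
    inform(sprintf("skipping %d ligand-receptor pair(s) with no subunit in the expression matrix: %s",
                   sum(!usable), paste(head(lrdb$pair[!usable], 5), collapse = ", ")))
  }
  lrdb <- lrdb[usable, , drop = FALSE]
  lig_sub <- lig_sub[usable]
  rec_sub <- rec_sub[usable]
  if (!nrow(lrdb)) abort("no usable ligand-receptor pair")

  genes_used <- unique(unlist(c(lig_sub, rec_sub)))
  sub_expr <- expr[genes_used, , drop = FALSE]
  groups <- levels(labels$group)

  gm <- group_mean_expression(sub_expr, labels, expr_frac_min)
  P <- score_tensor_probs(gm, lig_sub, rec_sub, kh)

  exceed <- array(0L, dim = dim(P))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_labels <- labels
      perm_labels$group <- sample(labels$group)
      gm_b <- group_mean_expression(sub_expr, perm_labels, expr_frac_min)
      P_b <- score_tensor_probs(gm_b, lig_sub, rec_sub, kh)
      exceed <- exceed + (P_b >= P)
    }
  })
  pval <- exceed / n_perm

  long <- crossing(k = seq_len(nrow(lrdb)),
                   receiver = groups, sender = groups) |>
    mutate(prob = P[cbind(match(.data$sender, groups),
                          match(.data$receiver, groups), .data$k)],
           pval = pval[cbind(match(.data$sender, groups),
                             match(.data$receiver, groups), .data$k)],
           pair = lrdb$pair[.data$k],
           pathway = lrdb$pathway[.data$k],
           ligand = lrdb$ligand[.data$k],
           receptor = lrdb$receptor[.data$k]) |>
    select("sender", "receiver", "pair", "pathway", "ligand", "receptor",
           "prob", "pval") |>
    arrange(.data$pair, .data$sender, .data$receiver)

  as_comm_tensor(long, condition = condition, groups = groups, alpha = alpha)
}
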