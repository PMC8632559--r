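#' One-vs-rest differential expression by Wilcoxon rank-sum test
#'
#' For every gene and cell group, the group's cells are compared with all
#' remaining cells: detection fractions in and out of the group, log2 fold
#' change of mean expression (pseudocount 1), a two-sided Wilcoxon rank-sum
#' p-value, and a multiplicity-adjusted p-value. A gene is called enriched in
#' a group when it is detected in at least `min_pct` of the group's cells,
#' its log fold change is at least `logfc_min` (hence positive), and the
#' adjusted p-value is below `alpha_adj`. Genes failing the detection or
#' fold-change pre-filters are not tested (their p-values are `NA`),
#' mirroring standard marker-gene practice.
#'
#' @param expr Expression matrix (genes x cells).
#' @param labels Cell labels (`cell`, `group`); >= 2 groups required. Groups
#'   with fewer than 3 cells are skipped with a warning.
#' @param min_pct Minimum in-group detection fraction (default 0.25).
#' @param logfc_min Minimum log2 fold change (default 0.25).
#' @param alpha_adj Adjusted-p significance level (default 0.05).
#' @param p_adjust Multiplicity adjustment, `"bonferroni"` (default) or
#'   `"BH"`; applied within each group across all its genes.
#' @return Tibble `gene`, `group`, `pct_in`, `pct_out`, `logfc`, `p_value`,
#'   `p_adj`, `enriched`.
#' @export
differential_enrichment <- function(expr, labels, min_pct = 0.25,
                                    logfc_min = 0.25, alpha_adj = 0.05,
                                    p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  labels <- as_tibble(labels)
  groups <- as.character(unique(labels$group))
  if (length(groups) < 2) abort("need at least two cell groups")
  sizes <- table(as.character(labels$group))
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warn(sprintf("skipping group(s) with fewer than 3 cells: %s",
                 paste(small, collapse = ", ")))
    groups <- setdiff(groups, small)
  }
  x <- expr[, labels$cell, drop = FALSE]
  out <- map(groups, function(g) {
    inside <- labels$group == g
    xin <- x[, inside, drop = FALSE]
    xout <- x[, !inside, drop = FALSE]
    pct_in <- rowMeans(xin > 0)
    pct_out <- rowMeans(xout > 0)
    logfc <- log2((rowMeans(xin) + 1) / (rowMeans(xout) + 1))
    test_it <- pct_in >= min_pct & logfc >= logfc_min
    p <- rep(NA_real_, nrow(x))
    for (i in which(test_it)) {
      p[i] <- wilcox.test(xin[i, ], xout[i, ], exact = FALSE)$p.value
    }
    padj <- p.adjust(p, method = if (p_adjust == "BH") "BH" else "bonferroni",
                     n = nrow(x))
    tibble(gene = rownames(x), group = g, pct_in = pct_in, pct_out = pct_out,
           logfc = logfc, p_value = p, p_adj = padj,
           enriched = test_it & !is.na(padj) & padj < alpha_adj & logfc > 0)
  })
  bind_rows(out)
}

#' Enriched TFs by differential activity
#'
#' The analogue of [differential_enrichment()] on a dense TF activity
#' matrix: activities have no meaningful detection fraction, so no detection
#' filter is applied, and the difference of group means (`delta`) replaces
#' the log fold change. Because activities are centered scores, `delta` is
#' unchanged by adding a constant to a TF's activity profile.
#'
#' @param activity TF activity matrix (TFs x cells).
#' @param labels Cell labels.
#' @param delta_min Minimum mean-activity difference (default 0.25).
#' @param alpha_adj Adjusted-p level (default 0.05).
#' @param p_adjust As in [differential_enrichment()].
#' @return Tibble `tf`, `group`, `delta`, `p_value`, `p_adj`, `enriched`.
#' @export
enriched_tfs <- function(activity, labels, delta_min = 0.25, alpha_adj = 0.05,
                         p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  labels <- as_tibble(labels)
  groups <- as.character(unique(labels$group))
  if (length(groups) < 2) abort("need at least two cell groups")
  sizes <- table(as.character(labels$group))
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warn(sprintf("skipping group(s) with fewer than 3 cells: %s",
                 paste(small, collapse = ", ")))
    groups <- setdiff(groups, small)
  }
  x <- activity[, labels$cell, drop = FALSE]
  out <- map(groups, function(g) {
    inside <- labels$group == g
    xin <- x[, inside, drop = FALSE]
    xout <- x[, !inside, drop = FALSE]
    delta <- rowMeans(xin) - rowMeans(xout)
    test_it <- delta >= delta_min
    p <- rep(NA_real_, nrow(x))
    for (i in which(test_it)) {
      p[i] <- wilcox.test(xin[i, ], xout[i, ], exact = FALSE)$p.value
    }
    padj <- p.adjust(p, method = if (p_adjust == "BH") "BH" else "bonferroni",
                     n = nrow(x))
    tibble(tf = rownames(x), group = g, delta = delta, p_value = p,
           p_adj = padj,
           enriched = test_it & !is.na(padj) & padj < alpha_adj & delta > 0)
  })
  bind_rows(out)
}

#' Restrict the receptor-TF prior to active receptors and modeled TFs
#'
#' Retains only receptor-TF edges whose receptor takes part in the
#' intercellular communication network and whose TF appears in the TF-target
#' regulatory network.
#'
#' @param prior Prior edge list (rows with `layer == "receptor_tf"` used).
#' @param active_receptors Receptors present in the communication network.
#' @param active_tfs TFs present in the TF-target network.
#' @return Filtered prior edge list tibble.
#' @export
subset_receptor_tf <- function(prior, active_receptors, active_tfs) {
  prior <- validate_prior_edges(prior)
  prior |>
    filter(.data$layer == "receptor_tf",
           .data$source %in% active_receptors,
           .data$target %in% active_tfs)
}

new_multiscale_graph <- function(edges, sender, receiver, condition) {
  structure(as_tibble(edges)[, c("from", "to", "layer", "weight", "sign")],
            class = c("multiscale_graph", class(tibble())),
            sender = sender, receiver = receiver, condition = condition)
}

#' @export
print.multiscale_graph <- function(x, ...) {
  cat(sprintf("<multiscale_graph> %s -> %s (%s): %d edges (%d LR, %d receptor-TF, %d TF-target)\n",
              attr(x, "sender"), attr(x, "receiver"), attr(x, "condition"),
              nrow(x), sum(x$layer == "ligand_receptor"),
              sum(x$layer == "receptor_tf"), sum(x$layer == "tf_target")))
  NextMethod()
}

#' Nodes of a multiscale graph with their layer roles
#'
#' @param g A `multiscale_graph`.
#' @return Tibble `node`, `role` (`ligand`, `receptor`, `tf`, `target`).
#' @export
graph_nodes <- function(g) {
  e <- as_tibble(g)
  bind_rows(
    tibble(node = e$from[e$layer == "ligand_receptor"], role = "ligand"),
    tibble(node = e$to[e$layer == "ligand_receptor"], role = "receptor"),
    tibble(node = unique(c(e$to[e$layer == "receptor_tf"],
                           e$from[e$layer == "tf_target"])), role = "tf"),
    tibble(node = e$to[e$layer == "tf_target"], role = "target")
  ) |>
    distinct() |>
    arrange(factor(.data$role, levels = c("ligand", "receptor", "tf", "target")),
            .data$node)
}

prune_unreachable <- function(edges) {
  # keep only edges on a ligand-rooted path; layers are strictly ordered, so
  # one forward sweep suffices
  lr <- edges[edges$layer == "ligand_receptor", , drop = FALSE]
  receptors <- unique(lr$to)
  rt <- edges[edges$layer == "receptor_tf" & edges$from %in% receptors, , drop = FALSE]
  tfs <- unique(rt$to)
  tt <- edges[edges$layer == "tf_target" & edges$from %in% tfs, , drop = FALSE]
  bind_rows(lr, rt, tt)
}

#' Assemble the multiscale ligand-receptor-TF-target signaling network
#'
#' Integrates the three layers for one (sender, receiver) cell-group pair:
#' significant ligand-receptor edges from the sender to the receiver (weight
#' = communication probability; multi-subunit receptors are expanded to one
#' edge per subunit gene so receptor genes can match the receptor-TF prior),
#' receptor-TF prior edges restricted to those receptors (unit weight, the
#' prior being unweighted), and TF-target edges from the inferred weight
#' matrix restricted to TFs reached by layer 2 (weight = `|X_new|`, sign
#' annotated). Nodes unreachable from any ligand are pruned, so every edge of
#' the result lies on a ligand-rooted path.
#'
#' @param ct A `comm_tensor` (significance-filtered).
#' @param sender,receiver Cell-group names present in `ct`.
#' @param rt_edges Receptor-TF prior edge list.
#' @param X_new Inferred TF-target weight matrix (targets x TFs), e.g.
#'   `infer_grn(...)$X_new`.
#' @param min_weight Minimum `|X_new|` for a TF-target edge (default 0,
#'   keeping all nonzero entries).
#' @return A `multiscale_graph` (empty, with a warning, when the pair has no
#'   significant ligand-receptor communication).
#' @export
assemble_multiscale <- function(ct, sender, receiver, rt_edges, X_new,
                                min_weight = 0) {
  groups <- comm_groups(ct)
  if (!sender %in% groups) abort(sprintf("sender group '%s' not in the tensor", sender))
  if (!receiver %in% groups) abort(sprintf("receiver group '%s' not in the tensor", receiver))
  condition <- ct$condition[1] %||% ""
  lr_rows <- filter(as_tibble(ct), .data$sender == !!sender,
                    .data$receiver == !!receiver, .data$prob > 0)
  empty <- tibble(from = character(), to = character(), layer = character(),
                  weight = numeric(), sign = integer())
  if (!nrow(lr_rows)) {
    warn(sprintf("no significant ligand-receptor pair from '%s' to '%s'", sender, receiver))
    return(new_multiscale_graph(empty, sender, receiver, condition))
  }
  lr <- lr_rows |>
    mutate(rec_sub = split_subunits(.data$receptor)) |>
    tidyr::unnest("rec_sub") |>
    dplyr::transmute(from = .data$ligand, to = .data$rec_sub,
                     layer = "ligand_receptor", weight = .data$prob,
                     sign = 1L) |>
    distinct()

  rt_edges <- validate_prior_edges(rt_edges)
  rt <- rt_edges |>
    filter(.data$layer == "receptor_tf", .data$source %in% lr$to,
           .data$target %in% colnames(X_new)) |>
    dplyr::transmute(from = .data$source, to = .data$target,
                     layer = "receptor_tf", weight = 1, sign = 1L) |>
    distinct()

  tt_idx <- which(abs(X_new) > min_weight & X_new != 0, arr.ind = TRUE)
  tt <- tibble(from = colnames(X_new)[tt_idx[, 2]],
               to = rownames(X_new)[tt_idx[, 1]],
               layer = "tf_target",
               weight = abs(X_new[tt_idx]),
               sign = as.integer(sign(X_new[tt_idx]))) |>
    filter(.data$from %in% rt$to)

  edges <- prune_unreachable(bind_rows(lr, rt, tt))
  new_multiscale_graph(edges, sender, receiver, condition)
}

#' Cell-type-specific multiscale network
#'
#' Restricts the intracellular layers of an assembled multiscale graph to
#' regulators and targets enriched in the receiving cell type: TF nodes are
#' intersected with `enriched_tf_set` (capped at the `top_tfs` first
#' entries, which should come ranked by enrichment), target nodes with
#' `enriched_target_set` (capped at `top_markers`), and only the
#' `top_k_edges` highest-weight TF-target edges are retained (ties at the
#' boundary broken by lexicographic (from, to) order for determinism).
#' Reachability pruning is re-applied afterwards.
#'
#' @param g A `multiscale_graph`.
#' @param enriched_tf_set Character vector of enriched TFs, ranked.
#' @param enriched_target_set Character vector of enriched target genes
#'   (marker genes), ranked.
#' @param top_k_edges TF-target edge cap (default 25).
#' @param top_markers Marker-gene cap (default 20).
#' @param top_tfs TF cap (default 50).
#' @return The restricted `multiscale_graph`.
#' @export
celltype_specific <- function(g, enriched_tf_set, enriched_target_set,
                              top_k_edges = 25, top_markers = 20, top_tfs = 50) {
  if (!length(enriched_tf_set) || !length(enriched_target_set)) {
    warn("empty enriched TF or target set: intracellular layers will be empty")
  }
  keep_tfs <- head(enriched_tf_set, top_tfs)
  keep_targets <- head(enriched_target_set, top_markers)
  e <- as_tibble(g)
  lr <- filter(e, .data$layer == "ligand_receptor")
  rt <- filter(e, .data$layer == "receptor_tf", .data$to %in% keep_tfs)
  tt <- filter(e, .data$layer == "tf_target", .data$from %in% keep_tfs,
               .data$to %in% keep_targets) |>
    arrange(desc(.data$weight), .data$from, .data$to) |>
    head(top_k_edges)
  edges <- prune_unreachable(bind_rows(lr, rt, tt))
  new_multiscale_graph(edges, attr(g, "sender"), attr(g, "receiver"),
                       attr(g, "condition"))
}
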