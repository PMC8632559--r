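#' Generate a fully synthetic pipeline fixture with planted ground truth
#'
#' Produces every input the pipeline consumes — per-condition expression
#' matrices with cell-group labels, a ligand-receptor database, regulons,
#' receptor-TF and TF-target priors with a binary mask — together with the
#' planted truth used to validate each stage:
#'
#' * a sparse TF-target weight matrix `X_true` (density `grn_density`,
#'   weights of magnitude Uniform(0.5, 2) and random sign);
#' * per-cell TF activities with group-specific mean shifts for one
#'   designated enriched TF per group;
#' * target expression `A = X_true B + Gaussian(0, noise_sd)`, shifted
#'   nonnegative;
#' * ligand/receptor genes with elevated means in the planted sender and
#'   receiver groups for the planted pathway, multiplied by
#'   `planted_pathway_boost` in the designated (last) condition only;
#' * planted marker genes per group and pure-noise null genes for
#'   differential-expression checks;
#' * a prior mask containing a fraction `prior_tp_frac` of the true edges
#'   plus `prior_fp_frac * |true|` spurious edges.
#'
#' The same seed reproduces the bundle exactly.
#'
#' @param n_groups Number of cell groups (default 4).
#' @param n_conditions Number of conditions (default 3).
#' @param cells_per_group Cells per group and condition (default 150).
#' @param n_tfs,n_targets TF and target-gene counts (defaults 10, 50).
#' @param n_lr_pairs Ligand-receptor pairs (default 12).
#' @param n_pathways Signaling pathways the pairs are spread over (default 4).
#' @param grn_density Density of `X_true` (default 0.1).
#' @param prior_tp_frac,prior_fp_frac True/spurious edge fractions of the
#'   prior mask (defaults 0.7, 0.1).
#' @param noise_sd Gaussian noise on target expression (default 0.5).
#' @param planted_pathway_boost Multiplier on the planted pathway's
#'   ligand/receptor elevation in the boosted condition (default 3).
#' @param group_shift Group mean shift, in activity/expression SD units, for
#'   enriched TFs and marker genes (default 1.5).
#' @param n_markers_per_group,n_null_genes Planted marker and null gene
#'   counts (defaults 3, 10).
#' @param boosted_condition Index of the boosted condition (default: last).
#' @param seed Integer seed (default 0).
#' @return A `ccc_fixture` list: `expr` and `labels` and `activity` and
#'   `target_expr` (per-condition lists), `lrdb`, `regulons`, `rt_prior`,
#'   `tf_target_prior`, `prior_mask`, and `truth` (planted structure).
#' @export
generate_fixture <- function(n_groups = 4, n_conditions = 3,
                             cells_per_group = 150, n_tfs = 10, n_targets = 50,
                             n_lr_pairs = 12, n_pathways = 4,
                             grn_density = 0.1, prior_tp_frac = 0.7,
                             prior_fp_frac = 0.1, noise_sd = 0.5,
                             planted_pathway_boost = 3, group_shift = 1.5,
                             n_markers_per_group = 3, n_null_genes = 10,
                             boosted_condition = n_conditions, seed = 0) {
  sizes <- c(n_groups, n_conditions, cells_per_group, n_tfs, n_targets,
             n_lr_pairs, n_pathways)
  if (any(sizes < 1)) abort("all fixture sizes must be >= 1")
  fracs <- c(grn_density, prior_tp_frac, prior_fp_frac)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (boosted_condition < 1 || boosted_condition > n_conditions) {
    abort("`boosted_condition` must index a condition")
  }
  withr::with_seed(seed, {
    groups <- paste0("G", seq_len(n_groups))
    conditions <- paste0("cond", seq_len(n_conditions))
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    targets <- sprintf("TG%02d", seq_len(n_targets))
    ligands <- sprintf("LG%02d", seq_len(n_lr_pairs))
    receptors <- sprintf("RG%02d", seq_len(n_lr_pairs))
    pathways <- paste0("PW", ((seq_len(n_lr_pairs) - 1) %% n_pathways) + 1)

    # planted intercellular signal: pathway PW1 from G1 to G2
    planted_pathway <- "PW1"
    planted_sender <- groups[1]
    planted_receiver <- groups[min(2, n_groups)]
    planted_pairs <- which(pathways == planted_pathway)

    # ground-truth TF-target network
    support <- matrix(rbinom(n_targets * n_tfs, 1, grn_density), n_targets, n_tfs)
    if (sum(support) == 0) support[1, 1] <- 1
    X_true <- support * matrix(sample(c(-1, 1), n_targets * n_tfs, TRUE) *
                                 runif(n_targets * n_tfs, 0.5, 2),
                               n_targets, n_tfs)
    dimnames(X_true) <- list(targets, tfs)

    # designated enriched TF for each group (round-robin over TFs)
    enriched_tf <- tibble(tf = tfs[((seq_len(n_groups) - 1) %% n_tfs) + 1],
                          group = groups)

    n_cells <- n_groups * cells_per_group
    group_of_cell <- rep(groups, each = cells_per_group)

    marker_genes <- if (n_markers_per_group > 0) {
      crossing(group = groups, i = seq_len(n_markers_per_group)) |>
        mutate(gene = sprintf("MK_%s_%d", .data$group, .data$i)) |>
        select("gene", "group")
    } else tibble(gene = character(), group = character())
    null_genes <- if (n_null_genes > 0) sprintf("NULL%02d", seq_len(n_null_genes)) else character()

    per_condition <- map(seq_len(n_conditions), function(ci) {
      cells <- sprintf("%s_c%04d", conditions[ci], seq_len(n_cells))
      labels <- tibble(cell = cells, group = group_of_cell)

      # TF activities: standard normal + group shift for the designated TFs
      B <- matrix(rnorm(n_tfs * n_cells), n_tfs, n_cells,
                  dimnames = list(tfs, cells))
      for (gi in seq_len(n_groups)) {
        B[enriched_tf$tf[gi], group_of_cell == groups[gi]] <-
          B[enriched_tf$tf[gi], group_of_cell == groups[gi]] + group_shift
      }

      # target expression from the linear activity model, each target shifted
      # nonnegative by its own offset; a single global offset would dwarf the
      # regulatory group contrasts on the log fold-change scale
      A <- X_true %*% B + matrix(rnorm(n_targets * n_cells, 0, noise_sd),
                                 n_targets, n_cells)
      A <- A - pmin(apply(A, 1, min), 0)
      dimnames(A) <- list(targets, cells)

      boost <- if (ci == boosted_condition) planted_pathway_boost else 1
      # low baseline abundance keeps the Hill response well below saturation,
      # so the boosted condition visibly raises the planted pathway's flow
      lig_expr <- matrix(rgamma(n_lr_pairs * n_cells, shape = 2, scale = 0.15),
                         n_lr_pairs, n_cells, dimnames = list(ligands, cells))
      rec_expr <- matrix(rgamma(n_lr_pairs * n_cells, shape = 2, scale = 0.15),
                         n_lr_pairs, n_cells, dimnames = list(receptors, cells))
      # elevation stays well below ~8x the baseline mean: past that point the
      # permutation null (whose group means rise with the planted shift)
      # overtakes the observed cross-group scores and masks the signal
      lr_elev <- 0.4 * boost
      for (k in planted_pairs) {
        send_cells <- group_of_cell == planted_sender
        recv_cells <- group_of_cell == planted_receiver
        lig_expr[k, send_cells] <- lig_expr[k, send_cells] + lr_elev
        rec_expr[k, recv_cells] <- rec_expr[k, recv_cells] + lr_elev
      }

      # TF genes observable in expression: min-shifted activity plus noise
      tf_expr <- B - min(B, 0) +
        matrix(abs(rnorm(n_tfs * n_cells, 0, 0.1)), n_tfs, n_cells)
      dimnames(tf_expr) <- list(tfs, cells)

      mk_expr <- matrix(pmax(rnorm(nrow(marker_genes) * n_cells, 0.5, 0.3), 0),
                        nrow(marker_genes), n_cells,
                        dimnames = list(marker_genes$gene, cells))
      for (mi in seq_len(nrow(marker_genes))) {
        sel <- group_of_cell == marker_genes$group[mi]
        mk_expr[mi, sel] <- mk_expr[mi, sel] + group_shift * 0.3
      }
      nl_expr <- matrix(pmax(rnorm(length(null_genes) * n_cells, 0.5, 0.3), 0),
                        length(null_genes), n_cells,
                        dimnames = list(null_genes, cells))

      expr <- rbind(lig_expr, rec_expr, tf_expr, A, mk_expr, nl_expr)
      list(expr = expr, labels = labels, activity = B, target_expr = A)
    })
    names(per_condition) <- conditions

    lrdb <- tibble(pair = sprintf("%s_%s", ligands, receptors),
                   ligand = ligands, receptor = receptors, pathway = pathways)

    regulons <- as_tibble(as.data.frame.table(X_true, responseName = "w",
                                              stringsAsFactors = FALSE)) |>
      rename(target = "Var1", source = "Var2") |>
      filter(.data$w != 0) |>
      mutate(layer = "tf_target", sign = sign(.data$w)) |>
      select("source", "target", "layer", "sign")

    # receptor-TF prior: two TFs per receptor; the planted pathway's
    # receptors always reach the receiver group's enriched TF so a full
    # ligand->receptor->TF->target chain exists
    receiver_tf <- enriched_tf$tf[enriched_tf$group == planted_receiver]
    rt_prior <- bind_rows(map(seq_len(n_lr_pairs), function(k) {
      linked <- sample(tfs, min(2, n_tfs))
      if (k %in% planted_pairs) linked <- unique(c(receiver_tf, linked))[seq_len(min(2, n_tfs))]
      tibble(source = receptors[k], target = linked, layer = "receptor_tf",
             sign = 1)
    }))

    true_edges <- which(X_true != 0)
    n_tp <- round(prior_tp_frac * length(true_edges))
    tp <- sort(sample(true_edges, n_tp))
    non_edges <- setdiff(seq_along(X_true), true_edges)
    n_fp <- min(round(prior_fp_frac * length(true_edges)), length(non_edges))
    fp <- sort(sample(non_edges, n_fp))
    N <- matrix(0, n_targets, n_tfs, dimnames = dimnames(X_true))
    N[c(tp, fp)] <- 1
    idx <- which(N == 1, arr.ind = TRUE)
    tf_target_prior <- tibble(source = tfs[idx[, 2]], target = targets[idx[, 1]],
                              layer = "tf_target", sign = 1) |>
      arrange(.data$source, .data$target)

    truth <- list(X_true = X_true,
                  planted = list(sender = planted_sender,
                                 receiver = planted_receiver,
                                 pathway = planted_pathway,
                                 boosted_condition = conditions[boosted_condition]),
                  enriched_tfs = enriched_tf,
                  marker_genes = marker_genes,
                  null_genes = null_genes,
                  prior_true_edges = length(tp),
                  prior_spurious_edges = length(fp))

    structure(list(expr = map(per_condition, "expr"),
                   labels = map(per_condition, "labels"),
                   activity = map(per_condition, "activity"),
                   target_expr = map(per_condition, "target_expr"),
                   lrdb = lrdb, regulons = regulons, rt_prior = rt_prior,
                   tf_target_prior = tf_target_prior, prior_mask = N,
                   truth = truth,
                   config = list(n_groups = n_groups, n_conditions = n_conditions,
                                 cells_per_group = cells_per_group,
                                 n_tfs = n_tfs, n_targets = n_targets,
                                 n_lr_pairs = n_lr_pairs, n_pathways = n_pathways,
                                 grn_density = grn_density,
                                 prior_tp_frac = prior_tp_frac,
                                 prior_fp_frac = prior_fp_frac,
                                 noise_sd = noise_sd,
                                 planted_pathway_boost = planted_pathway_boost,
                                 group_shift = group_shift,
                                 n_markers_per_group = n_markers_per_group,
                                 n_null_genes = n_null_genes,
                                 boosted_condition = boosted_condition,
                                 seed = seed)),
              class = "ccc_fixture")
  })
}

#' @export
print.ccc_fixture <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ccc_fixture> %d conditions x %d groups x %d cells/group; %d TFs, %d targets, %d LR pairs (seed %d)\n",
              cfg$n_conditions, cfg$n_groups, cfg$cells_per_group,
              cfg$n_tfs, cfg$n_targets, cfg$n_lr_pairs, cfg$seed))
  invisible(x)
}

#' Machine-readable description of a fixture's planted ground truth
#'
#' @param bundle A `ccc_fixture`.
#' @return Tibble `kind`, `item`, `context`, `value` listing true TF-target
#'   edges, the planted communication signal, enriched TFs, marker genes and
#'   null genes.
#' @export
describe_ground_truth <- function(bundle) {
  truth <- bundle$truth
  edges <- which(truth$X_true != 0, arr.ind = TRUE)
  bind_rows(
    tibble(kind = "tf_target_edge",
           item = paste(colnames(truth$X_true)[edges[, 2]],
                        rownames(truth$X_true)[edges[, 1]], sep = "->"),
           context = "grn",
           value = truth$X_true[edges]),
    tibble(kind = "planted_communication",
           item = truth$planted$pathway,
           context = paste(truth$planted$sender, truth$planted$receiver, sep = "->"),
           value = NA_real_),
    tibble(kind = "boosted_condition", item = truth$planted$boosted_condition,
           context = truth$planted$pathway, value = NA_real_),
    tibble(kind = "enriched_tf", item = truth$enriched_tfs$tf,
           context = truth$enriched_tfs$group, value = NA_real_),
    tibble(kind = "marker_gene", item = truth$marker_genes$gene,
           context = truth$marker_genes$group, value = NA_real_),
    tibble(kind = "null_gene", item = truth$null_genes, context = "none",
           value = NA_real_)
  ) |>
    arrange(.data$kind, .data$item)
}

#' Write every fixture input in its standard on-disk format
#'
#' @param bundle A `ccc_fixture`.
#' @param directory Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(bundle, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  imap(bundle$expr, function(e, cond) {
    write_expression(e, file.path(directory, paste0("expr_", cond, ".tsv")))
    write_labels(bundle$labels[[cond]], file.path(directory, paste0("labels_", cond, ".tsv")))
    write_tf_activity(bundle$activity[[cond]], file.path(directory, paste0("activity_", cond, ".tsv")))
  })
  write_lr_database(bundle$lrdb, file.path(directory, "lr_database.tsv"))
  write_prior_edges(bundle$regulons, file.path(directory, "regulons.tsv"))
  write_prior_edges(bind_rows(bundle$rt_prior, bundle$tf_target_prior),
                    file.path(directory, "prior_edges.tsv"))
  readr::write_tsv(describe_ground_truth(bundle),
                   file.path(directory, "ground_truth.tsv"), progress = FALSE)
  invisible(directory)
}
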