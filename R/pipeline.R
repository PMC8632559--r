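#' Default pipeline configuration
#'
#' Nested list mirroring every stage flag; [run_pipeline()] merges a user
#' config (R list or YAML file) over these defaults. Either `simulate` is
#' enabled, or `inputs` must name the per-condition expression/label files
#' plus the ligand-receptor database and prior files.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 0,
    simulate = list(enabled = TRUE),
    score = list(kh = 0.5, n_perm = 100, alpha = 0.05, expr_frac_min = 0.1,
                 min_cells = 10),
    compare = list(n_clusters = 2),
    grn = list(lambda1 = 50, lambda2 = 10, t = 1, omega = 0.7,
               mask_convention = "penalize-nonprior", max_iter = 3000,
               condition = NULL, use_true_activity = FALSE),
    multiscale = list(sender = NULL, receiver = NULL, top_edges = 25,
                      top_markers = 20, top_tfs = 50),
    inputs = list()
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

load_inputs <- function(inputs, score_cfg) {
  need <- c("expr", "labels", "lrdb", "priors")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) {
    abort(sprintf("config `inputs` is missing: %s", paste(miss, collapse = ", ")))
  }
  conds <- names(inputs$expr)
  if (is.null(conds)) abort("config `inputs$expr` must be a named (condition) list of paths")
  for (p in c(unlist(inputs$expr), unlist(inputs$labels),
              inputs$lrdb, inputs$priors, inputs$regulons)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  priors <- read_prior_edges(inputs$priors)
  list(expr = map(inputs$expr, read_expression),
       labels = map(inputs$labels, read_labels),
       lrdb = read_lr_database(inputs$lrdb),
       regulons = if (!is.null(inputs$regulons)) read_prior_edges(inputs$regulons)
                  else priors[priors$layer == "tf_target", ],
       rt_prior = priors[priors$layer == "receptor_tf", ],
       tf_target_prior = priors[priors$layer == "tf_target", ])
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full pipeline: score, compare, activity, GRN, multiscale
#'
#' Executes communication scoring for every condition, the multi-condition
#' comparison tables and network embedding, TF activity estimation, the
#' prior-regularized TF-target regression with proportionality ensemble, and
#' the multiscale graph assembly, writing every output table plus a manifest
#' (parameters, seed, file checksums) under `out_dir`. Reruns with the same
#' config produce identical manifests.
#'
#' @param config R list, or path to a YAML file, merged over
#'   [default_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("commdelta_run")) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  data <- run_stage("inputs", {
    if (isTRUE(cfg$simulate$enabled)) {
      sim_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
      sim_args$seed <- sim_args$seed %||% cfg$seed
      bundle <- do.call(generate_fixture, sim_args)
      list(expr = bundle$expr, labels = bundle$labels, lrdb = bundle$lrdb,
           regulons = bundle$regulons, rt_prior = bundle$rt_prior,
           tf_target_prior = bundle$tf_target_prior, bundle = bundle)
    } else {
      load_inputs(cfg$inputs, cfg$score)
    }
  })

  tensors <- run_stage("score", {
    imap(data$expr, function(e, cond) {
      score_communication(e, data$labels[[cond]], data$lrdb,
                          kh = cfg$score$kh, n_perm = cfg$score$n_perm,
                          seed = cfg$seed, alpha = cfg$score$alpha,
                          expr_frac_min = cfg$score$expr_frac_min,
                          condition = cond, min_cells = cfg$score$min_cells)
    })
  })
  walk(names(tensors), function(cond) {
    write_comm_tensor(tensors[[cond]], file.path(out_dir, paste0("tensor_", cond, ".tsv")))
  })

  comparison <- NULL
  embedding <- NULL
  if (length(tensors) >= 2) {
    comparison <- run_stage("compare", compare_conditions(unname(tensors)))
    write_tables(comparison, file.path(out_dir, "comparison"))
    embedding <- run_stage("compare", tryCatch(
      embed_networks(tensors, n_clusters = cfg$compare$n_clusters, seed = cfg$seed),
      error = function(e) NULL))
    if (!is.null(embedding)) {
      readr::write_tsv(as_tibble(embedding), file.path(out_dir, "embedding.tsv"),
                       progress = FALSE)
    }
  }

  grn_cond <- cfg$grn$condition %||% names(data$expr)[1]
  activity <- run_stage("activity", {
    if (isTRUE(cfg$grn$use_true_activity) && !is.null(data$bundle)) {
      data$bundle$activity[[grn_cond]]
    } else {
      estimate_tf_activity(data$expr[[grn_cond]], data$regulons)
    }
  })
  write_tf_activity(activity, file.path(out_dir, "tf_activity.tsv"))

  grn <- run_stage("grn", {
    targets <- unique(data$regulons$target)
    targets <- intersect(rownames(data$expr[[grn_cond]]), targets)
    A <- data$expr[[grn_cond]][targets, , drop = FALSE]
    N <- prior_mask(data$tf_target_prior, targets, rownames(activity))
    scfg <- solver_config(lambda1 = cfg$grn$lambda1, lambda2 = cfg$grn$lambda2,
                          t = cfg$grn$t, max_iter = cfg$grn$max_iter,
                          mask_convention = cfg$grn$mask_convention,
                          omega = cfg$grn$omega)
    infer_grn(A, activity, N, scfg)
  })
  readr::write_tsv(tidy(grn), file.path(out_dir, "grn_edges.tsv"), progress = FALSE)

  graph <- run_stage("multiscale", {
    ct <- tensors[[grn_cond]]
    sender <- cfg$multiscale$sender %||%
      (if (!is.null(data$bundle)) data$bundle$truth$planted$sender else comm_groups(ct)[1])
    receiver <- cfg$multiscale$receiver %||%
      (if (!is.null(data$bundle)) data$bundle$truth$planted$receiver else comm_groups(ct)[2])
    g <- assemble_multiscale(ct, sender, receiver, data$rt_prior, grn$X_new)
    de <- differential_enrichment(data$expr[[grn_cond]], data$labels[[grn_cond]])
    tf_enr <- enriched_tfs(activity, data$labels[[grn_cond]])
    mk <- de |> filter(.data$enriched, .data$group == receiver) |>
      arrange(.data$p_adj, desc(.data$logfc)) |> pull("gene")
    tf_set <- tf_enr |> filter(.data$enriched, .data$group == receiver) |>
      arrange(.data$p_adj, desc(.data$delta)) |> pull("tf")
    celltype_specific(g, tf_set, mk,
                      top_k_edges = cfg$multiscale$top_edges,
                      top_markers = cfg$multiscale$top_markers,
                      top_tfs = cfg$multiscale$top_tfs)
  })
  write_graph(graph, file.path(out_dir, "multiscale_graph.tsv"))
  write_graph(graph, file.path(out_dir, "multiscale_graph.txt"), format = "graphtxt")

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.yaml")
  manifest <- list(package = "commdelta",
                   version = as.character(utils::packageVersion("commdelta")),
                   seed = cfg$seed,
                   parameters = cfg[c("score", "compare", "grn", "multiscale")],
                   outputs = as.list(setNames(
                     unname(tools::md5sum(file.path(out_dir, files))), files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(tensors = tensors, comparison = comparison,
                 embedding = embedding, activity = activity, grn = grn,
                 graph = graph, manifest = manifest, out_dir = out_dir))
}
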