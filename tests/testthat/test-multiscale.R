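de_fixture <- function(seed = 0, n_per = 30) {
  withr::with_seed(seed, {
    cells <- paste0("c", seq_len(3 * n_per))
    grp <- rep(c("A", "B", "C"), each = n_per)
    marker <- c(rep(5, n_per), rep(0, 2 * n_per))
    rare <- ifelse(seq_along(cells) <= 0.1 * n_per, 10, 0)  # 10% of A only
    null1 <- runif(3 * n_per, 0, 2)
    expr <- rbind(marker = marker, rare = rare, null1 = null1)
    colnames(expr) <- cells
    list(expr = expr, labels = tibble::tibble(cell = cells, group = grp))
  })
}

test_that("an exclusive gene is enriched only in its group", {
  fx <- de_fixture()
  de <- differential_enrichment(fx$expr, fx$labels)
  m <- dplyr::filter(de, gene == "marker")
  expect_true(m$enriched[m$group == "A"])
  expect_false(any(m$enriched[m$group != "A"]))
})

test_that("the detection-fraction filter vetoes rarely detected genes", {
  fx <- de_fixture()
  de <- differential_enrichment(fx$expr, fx$labels, min_pct = 0.25)
  r <- dplyr::filter(de, gene == "rare", group == "A")
  # detected in 10% of A: excluded before testing, whatever its effect size
  expect_false(r$enriched)
  expect_true(is.na(r$p_value))
  de_loose <- differential_enrichment(fx$expr, fx$labels, min_pct = 0.05)
  expect_true(dplyr::filter(de_loose, gene == "rare", group == "A")$enriched)
})

test_that("identically distributed genes are not called enriched", {
  hits <- 0L
  for (seed in 1:5) {
    fx <- de_fixture(seed)
    de <- differential_enrichment(fx$expr, fx$labels)
    hits <- hits + sum(dplyr::filter(de, gene == "null1")$enriched)
  }
  expect_equal(hits, 0L)
})

test_that("tightening any DE threshold never adds genes", {
  fx <- default_fixture(0)
  idx <- seq(1, ncol(fx$expr[[1]]), by = 4)
  expr <- fx$expr[[1]][, idx]
  labels <- fx$labels[[1]][idx, ]
  base <- differential_enrichment(expr, labels)
  tight_pct <- differential_enrichment(expr, labels, min_pct = 0.5)
  tight_fc <- differential_enrichment(expr, labels, logfc_min = 0.5)
  tight_p <- differential_enrichment(expr, labels, alpha_adj = 0.001)
  key <- function(d) paste(d$gene, d$group)[d$enriched]
  expect_true(all(key(tight_pct) %in% key(base)))
  expect_true(all(key(tight_fc) %in% key(base)))
  expect_true(all(key(tight_p) %in% key(base)))
})

test_that("TF enrichment finds planted activity shifts and ignores global offsets", {
  withr::with_seed(1, {
    cells <- paste0("c", 1:90)
    grp <- rep(c("A", "B", "C"), each = 30)
    act <- rbind(TFup = rnorm(90) + (grp == "B") * 1.5,
                 TFnull = rnorm(90))
    colnames(act) <- cells
  })
  labels <- tibble::tibble(cell = cells, group = grp)
  enr <- enriched_tfs(act, labels)
  expect_true(dplyr::filter(enr, tf == "TFup", group == "B")$enriched)
  expect_false(any(dplyr::filter(enr, tf == "TFnull")$enriched))
  shifted <- enriched_tfs(act + 100, labels)
  expect_equal(enr$delta, shifted$delta)
  expect_equal(enr$enriched, shifted$enriched)
})

test_that("receptor-TF subsetting is an exact filter", {
  withr::with_seed(2, {
    edges <- tibble::tibble(source = sample(paste0("R", 1:6), 20, TRUE),
                            target = sample(paste0("TF", 1:5), 20, TRUE),
                            layer = "receptor_tf")
  })
  edges <- validate_prior_edges(dplyr::distinct(edges))
  recs <- c("R1", "R3")
  tfs <- c("TF2", "TF4", "TF5")
  sub <- subset_receptor_tf(edges, recs, tfs)
  oracle <- edges[edges$source %in% recs & edges$target %in% tfs, ]
  expect_equal(sub, oracle)
  expect_equal(nrow(subset_receptor_tf(edges, character(), tfs)), 0)
  expect_equal(subset_receptor_tf(edges, unique(edges$source),
                                  unique(edges$target)), edges)
})

chain_inputs <- function() {
  ct <- make_tensor(tibble::tibble(sender = "G1", receiver = "G2", pair = "p",
                                   pathway = "PW", ligand = "L",
                                   receptor = "R", prob = 0.6, pval = 0))
  rt <- tibble::tibble(source = "R", target = "TF1", layer = "receptor_tf")
  X <- matrix(c(0.8, -0.3), 2, 1, dimnames = list(c("T1", "T2"), "TF1"))
  list(ct = ct, rt = rt, X = X)
}

test_that("a single chain assembles into one edge per layer", {
  ci <- chain_inputs()
  g <- assemble_multiscale(ci$ct, "G1", "G2", ci$rt, ci$X[1, , drop = FALSE])
  expect_equal(nrow(g), 3)
  expect_equal(g$layer, c("ligand_receptor", "receptor_tf", "tf_target"))
  expect_equal(g$from, c("L", "R", "TF1"))
  expect_equal(g$to, c("R", "TF1", "T1"))
  expect_equal(g$weight, c(0.6, 1, 0.8))
  nodes <- graph_nodes(g)
  expect_equal(nodes$role, c("ligand", "receptor", "tf", "target"))
})

test_that("removing the receptor-TF link removes the whole downstream subtree", {
  ci <- chain_inputs()
  g <- assemble_multiscale(ci$ct, "G1", "G2", ci$rt[0, ], ci$X)
  expect_equal(nrow(g), 1)
  expect_equal(g$layer, "ligand_receptor")
  expect_false(any(c("TF1", "T1", "T2") %in% c(g$from, g$to)))
})

test_that("assembly with no significant pair yields an empty graph with warning", {
  ci <- chain_inputs()
  expect_warning(g <- assemble_multiscale(ci$ct, "G2", "G1", ci$rt, ci$X),
                 "no significant ligand-receptor pair")
  expect_equal(nrow(g), 0)
  expect_error(assemble_multiscale(ci$ct, "nope", "G2", ci$rt, ci$X),
               "sender group 'nope'")
})

test_that("assembled graphs equal a brute-force reachability filter", {
  fx <- default_fixture(0)
  ct <- score_communication(fx$expr[[1]], fx$labels[[1]], fx$lrdb, n_perm = 50,
                            seed = 0, condition = "cond1")
  fit <- infer_grn(fx$target_expr[[1]], fx$activity[[1]], fx$prior_mask)
  g <- assemble_multiscale(ct, fx$truth$planted$sender,
                           fx$truth$planted$receiver, fx$rt_prior, fit$X_new)
  expect_gt(nrow(g), 3)
  expect_equal(orphan_edges(g), 0)

  # oracle: rebuild the edge set independently
  df <- dplyr::filter(tibble::as_tibble(ct),
                      sender == fx$truth$planted$sender,
                      receiver == fx$truth$planted$receiver, prob > 0)
  receptors <- unique(df$receptor)
  rt <- fx$rt_prior[fx$rt_prior$source %in% receptors, ]
  tfs <- unique(rt$target)
  tt_oracle <- which(fit$X_new != 0, arr.ind = TRUE)
  tt_oracle <- tt_oracle[colnames(fit$X_new)[tt_oracle[, 2]] %in% tfs, , drop = FALSE]
  expect_equal(sum(g$layer == "ligand_receptor"), nrow(df))
  expect_equal(sum(g$layer == "receptor_tf"), nrow(dplyr::distinct(rt[, c("source", "target")])))
  expect_equal(sum(g$layer == "tf_target"), nrow(tt_oracle))
})

test_that("cell-type restriction enforces the top-edge and node caps exactly", {
  g <- big_graph()
  all_tfs <- paste0("TF", 1:60)
  all_targets <- paste0("T", 1:40)
  gs <- celltype_specific(g, all_tfs, all_targets)
  expect_equal(sum(gs$layer == "tf_target"), 25)
  nodes <- graph_nodes(gs)
  expect_lte(sum(nodes$role == "tf"), 50)
  expect_lte(sum(nodes$role == "target"), 20)
  expect_equal(orphan_edges(gs), 0)

  # oracle: sort-and-cut on the eligible TF-target edges
  e <- tibble::as_tibble(g)
  elig <- e[e$layer == "tf_target" & e$from %in% head(all_tfs, 50) &
              e$to %in% head(all_targets, 20), ]
  elig <- elig[order(-elig$weight, elig$from, elig$to), ]
  top <- head(elig, 25)
  got <- dplyr::filter(tibble::as_tibble(gs), layer == "tf_target")
  expect_equal(dplyr::arrange(got, from, to)[, c("from", "to", "weight")],
               dplyr::arrange(top, from, to)[, c("from", "to", "weight")])
})

test_that("top-edge ties at the boundary break deterministically", {
  ct <- make_tensor(tibble::tibble(sender = "G1", receiver = "G2", pair = "p",
                                   pathway = "PW", ligand = "L",
                                   receptor = "R", prob = 0.9, pval = 0))
  rt <- tibble::tibble(source = "R", target = c("TFa", "TFb"),
                       layer = "receptor_tf")
  X <- matrix(0.5, 3, 2, dimnames = list(c("Ta", "Tb", "Tc"), c("TFa", "TFb")))
  g <- assemble_multiscale(ct, "G1", "G2", rt, X)
  g1 <- celltype_specific(g, c("TFa", "TFb"), c("Ta", "Tb", "Tc"), top_k_edges = 3)
  g2 <- celltype_specific(g, c("TFa", "TFb"), c("Ta", "Tb", "Tc"), top_k_edges = 3)
  expect_equal(g1, g2)
  tt <- dplyr::filter(tibble::as_tibble(g1), layer == "tf_target")
  expect_equal(paste(tt$from, tt$to),
               c("TFa Ta", "TFa Tb", "TFa Tc"))
  expect_warning(celltype_specific(g, character(), character()), "empty enriched")
})
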