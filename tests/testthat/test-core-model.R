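test_that("dense expression TSV round-trips with matching ids", {
  expr <- tiny_expr()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, path)
  back <- read_expression(path)
  expect_identical(rownames(back), rownames(expr))
  expect_identical(colnames(back), colnames(expr))
  expect_equal(unclass(back)[, ], expr[, ], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("matrix-market triplet layout reads 1-based entries with sidecars", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.mtx")
  readr::write_lines(c("%%MatrixMarket matrix coordinate real general",
                       "3 2 1", "1 1 5.0"), path)
  readr::write_lines(c("g1", "g2", "g3"), file.path(dir, "m_genes.txt"))
  readr::write_lines(c("c1", "c2"), file.path(dir, "m_cells.txt"))
  m <- read_expression(path)
  expect_equal(sum(m != 0), 1)
  expect_equal(m["g1", "c1"], 5)

  # writer/reader round trip on a random sparse matrix
  expr <- withr::with_seed(0, {
    x <- matrix(rbinom(30, 1, 0.4) * runif(30), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
    x
  })
  p2 <- file.path(dir, "rt.mtx")
  write_expression(expr, p2, format = "mtx")
  back <- read_expression(p2)
  expect_equal(back[, ], expr[, ], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("validation rejects duplicate ids and negative values by name", {
  expr <- tiny_expr()
  rownames(expr) <- c("gA", "gA", "gC")
  expect_error(validate_expression(expr), "duplicate gene id.*gA")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = c("g1", "g1"), c1 = c(1, 2)), path)
  expect_error(read_expression(path), "duplicate gene id")

  expr2 <- tiny_expr()
  expr2["gB", "c2"] <- -1
  expect_error(validate_expression(expr2), "negative expression.*gB.*c2")
  expr3 <- tiny_expr()
  expr3["gC", "c1"] <- NaN
  expect_error(validate_expression(expr3), "non-finite")
})

test_that("zero-total genes are retained but flagged", {
  v <- validate_expression(tiny_expr())
  expect_true("gC" %in% rownames(v))
  expect_identical(attr(v, "zero_genes"), "gC")
})

test_that("label validation enforces membership and the min-cells floor", {
  expr <- tiny_expr()
  labels <- tiny_labels()
  expect_error(validate_labels(tibble::add_row(labels, cell = "ghost", group = "grp1"),
                               expr, min_cells = 1),
               "absent from the expression matrix: ghost")
  uneven <- tibble::tibble(cell = paste0("c", 1:6),
                           group = c("grp1", "grp1", "grp1", "grp1",
                                     "grp2", "grp2"))
  expect_warning(out <- validate_labels(uneven, expr, min_cells = 3),
                 "fewer than 3 cells: grp2")
  expect_equal(levels(out$group), "grp1")
  expect_error(suppressWarnings(validate_labels(labels, expr, min_cells = 10)),
               "no groups remain")
  ok <- validate_labels(labels, expr, min_cells = 3)
  expect_s3_class(ok, "tbl_df")
  expect_equal(levels(ok$group), c("grp1", "grp2"))
})

test_that("LR database and prior edge validation reject malformed records", {
  lrdb <- tibble::tibble(pair = c("p1", "p1"), ligand = "L1", receptor = "R1",
                         pathway = "PW")
  expect_error(validate_lr_database(lrdb), "duplicate ligand-receptor pair id 'p1'")
  lrdb2 <- tibble::tibble(pair = "p1", ligand = "", receptor = "R1", pathway = "PW")
  expect_error(validate_lr_database(lrdb2), "empty ligand or receptor")

  edges <- tibble::tibble(source = "TF1", target = "TF1", layer = "tf_target")
  expect_error(validate_prior_edges(edges), "self-loop on gene 'TF1'")
  edges2 <- tibble::tibble(source = "a", target = "b", layer = "nonsense")
  expect_error(validate_prior_edges(edges2), "unknown prior layer tag")
  edges3 <- validate_prior_edges(tibble::tibble(source = "a", target = "b",
                                                layer = "tf_target"))
  expect_equal(edges3$sign, 1)
})

test_that("labels, LR database, priors and tensors round-trip on disk", {
  dir <- withr::local_tempdir()
  labels <- tiny_labels()
  write_labels(labels, file.path(dir, "lab.tsv"))
  expect_equal(read_labels(file.path(dir, "lab.tsv")), labels)

  lrdb <- tibble::tibble(pair = c("a_b", "c_d"), ligand = c("A", "C1&C2"),
                         receptor = c("B1&B2", "D"), pathway = c("P1", "P2"))
  write_lr_database(lrdb, file.path(dir, "lr.tsv"))
  expect_equal(read_lr_database(file.path(dir, "lr.tsv")), lrdb)

  pri <- tibble::tibble(source = c("R1", "TF1"), target = c("TF1", "G1"),
                        layer = c("receptor_tf", "tf_target"), sign = c(1, -1))
  write_prior_edges(pri, file.path(dir, "pri.tsv"))
  expect_equal(read_prior_edges(file.path(dir, "pri.tsv")), pri)

  ct <- random_tensor(7)
  write_comm_tensor(ct, file.path(dir, "ct.tsv"))
  back <- read_comm_tensor(file.path(dir, "ct.tsv"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ct), tolerance = 1e-9)
})

test_that("graph writers round-trip the empty graph, a chain, and a random graph", {
  dir <- withr::local_tempdir()
  empty <- assemble_multiscale(
    suppressWarnings(make_tensor(tibble::tibble(
      sender = "G1", receiver = "G2", pair = "p", pathway = "PW",
      ligand = "L", receptor = "R", prob = 0, pval = 1))),
    "G1", "G2",
    tibble::tibble(source = character(), target = character(), layer = character()),
    matrix(0, 1, 1, dimnames = list("T1", "TF1"))) |> suppressWarnings()
  for (fmt in c("edgelist", "graphtxt")) {
    p <- file.path(dir, paste0("empty_", fmt))
    write_graph(empty, p, format = fmt)
    expect_equal(nrow(read_graph(p)), 0)
  }

  ct <- make_tensor(tibble::tibble(sender = "G1", receiver = "G2", pair = "p",
                                   pathway = "PW", ligand = "L", receptor = "R",
                                   prob = 0.6, pval = 0))
  rt <- tibble::tibble(source = "R", target = "TF1", layer = "receptor_tf")
  X <- matrix(0.8, 1, 1, dimnames = list("T1", "TF1"))
  chain <- assemble_multiscale(ct, "G1", "G2", rt, X)
  expect_equal(nrow(chain), 3)
  for (fmt in c("edgelist", "graphtxt")) {
    p <- file.path(dir, paste0("chain_", fmt))
    write_graph(chain, p, format = fmt)
    back <- read_graph(p)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(chain), tolerance = 1e-9)
    expect_identical(attr(back, "sender"), "G1")
    expect_identical(attr(back, "receiver"), "G2")
  }

  # random ~50-edge graph via a dense weight matrix
  X2 <- withr::with_seed(0, matrix(rnorm(48), 8, 6,
                                   dimnames = list(paste0("T", 1:8), paste0("TF", 1:6))))
  rt2 <- tibble::tibble(source = "R", target = paste0("TF", 1:6), layer = "receptor_tf")
  g2 <- assemble_multiscale(ct, "G1", "G2", rt2, X2)
  expect_gte(nrow(g2), 50)
  for (fmt in c("edgelist", "graphtxt")) {
    p <- file.path(dir, paste0("rand_", fmt))
    write_graph(g2, p, format = fmt)
    back <- read_graph(p)
    expect_equal(dplyr::arrange(tibble::as_tibble(back), from, to),
                 dplyr::arrange(tibble::as_tibble(g2), from, to), tolerance = 1e-9)
  }
})

test_that("comparison tables round-trip as one TSV per table", {
  dir <- withr::local_tempdir()
  cts <- list(random_tensor(1, condition = "a"), random_tensor(2, condition = "b"))
  tables <- compare_conditions(cts)
  write_tables(tables, dir)
  files <- list.files(dir, pattern = "\\.tsv$")
  expect_setequal(sub("\\.tsv$", "", files), names(tables))
  back <- read_tables(dir)
  for (nm in names(tables)) {
    expect_equal(tibble::as_tibble(back[[nm]]), tibble::as_tibble(tables[[nm]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  empty_dir <- withr::local_tempdir()
  write_tables(list(empty = tibble::tibble(a = numeric(), b = character())),
               empty_dir)
  expect_equal(nrow(read_tables(empty_dir)$empty), 0)
})
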