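# Readers and writers for every external format the tool touches.
# All delimited files are tab-separated, "." decimal, UTF-8.

matrix_to_tibble <- function(m, id_col) {
  out <- as_tibble(m, rownames = id_col)
  out
}

tibble_to_matrix <- function(df, id_col) {
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Read a normalized expression matrix
#'
#' Two on-disk layouts are supported: a dense TSV with gene ids in the first
#' column and cell ids in the header, and a matrix-market triplet file (1-based
#' indices, per that format's convention) with gene/cell id sidecar files
#' `<stem>_genes.txt` and `<stem>_cells.txt`.
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"auto"` (by extension), `"dense"` or `"mtx"`.
#' @return A validated expression matrix (genes x cells).
#' @export
read_expression <- function(path, format = c("auto", "dense", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  }
  if (format == "dense") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (anyDuplicated(df[[1]])) {
      abort(sprintf("duplicate gene id '%s' in %s",
                    df[[1]][duplicated(df[[1]])][1], path))
    }
    expr <- tibble_to_matrix(df, names(df)[1])
  } else {
    stem <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readr::read_lines(paste0(stem, "_genes.txt"), progress = FALSE)
    cells <- readr::read_lines(paste0(stem, "_cells.txt"), progress = FALSE)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      abort(sprintf("matrix-market dimensions of %s do not match its id sidecars", path))
    }
    dimnames(m) <- list(genes, cells)
    expr <- m
  }
  validate_expression(expr)
}

#' Write an expression matrix
#'
#' @param expr Expression matrix (genes x cells).
#' @param path Output path; `format = "mtx"` also writes the
#'   `<stem>_genes.txt` / `<stem>_cells.txt` sidecars.
#' @param format `"dense"` or `"mtx"`.
#' @export
write_expression <- function(expr, path, format = c("dense", "mtx")) {
  format <- match.arg(format)
  if (format == "dense") {
    readr::write_tsv(matrix_to_tibble(expr, "gene"), path, progress = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
    readr::write_lines(rownames(expr), paste0(stem, "_genes.txt"))
    readr::write_lines(colnames(expr), paste0(stem, "_cells.txt"))
  }
  invisible(path)
}

#' Read / write cell labels (two-column TSV: cell, group)
#' @param path File path.
#' @return `read_labels`: tibble with columns `cell`, `group`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(df)[1:2] <- c("cell", "group")
  df
}

#' @rdname read_labels
#' @param labels Tibble with columns `cell`, `group`.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels[, c("cell", "group")], path, progress = FALSE)
  invisible(path)
}

#' Read / write a ligand-receptor database (TSV with `&`-joined subunits)
#' @param path File path.
#' @return `read_lr_database`: validated tibble with columns `pair`,
#'   `ligand`, `receptor`, `pathway`.
#' @export
read_lr_database <- function(path) {
  validate_lr_database(readr::read_tsv(path, col_types = "cccc", progress = FALSE))
}

#' @rdname read_lr_database
#' @param lrdb Ligand-receptor database tibble.
#' @export
write_lr_database <- function(lrdb, path) {
  readr::write_tsv(validate_lr_database(lrdb), path, progress = FALSE)
  invisible(path)
}

#' Read / write a prior edge list (TSV: source, target, layer[, sign])
#' @param path File path.
#' @return `read_prior_edges`: validated tibble.
#' @export
read_prior_edges <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_prior_edges(df)
}

#' @rdname read_prior_edges
#' @param edges Prior edge list tibble.
#' @export
write_prior_edges <- function(edges, path) {
  readr::write_tsv(validate_prior_edges(edges), path, progress = FALSE)
  invisible(path)
}

#' Read / write a TF activity matrix (TSV: TFs x cells)
#'
#' @param path File path.
#' @param cells Optional cell ids the activity matrix must align to; a
#'   mismatch is an error.
#' @return `read_tf_activity`: numeric matrix, TFs in rows.
#' @export
read_tf_activity <- function(path, cells = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  act <- tibble_to_matrix(df, names(df)[1])
  if (anyDuplicated(rownames(act))) {
    abort(sprintf("duplicate TF id '%s' in %s",
                  rownames(act)[duplicated(rownames(act))][1], path))
  }
  if (any(!is.finite(act))) abort(sprintf("non-finite TF activity value in %s", path))
  if (!is.null(cells) && !identical(colnames(act), as.character(cells))) {
    abort("TF activity cells do not match the expression matrix cells (same ids, same order, required)")
  }
  act
}

#' @rdname read_tf_activity
#' @param activity TF activity matrix.
#' @export
write_tf_activity <- function(activity, path) {
  readr::write_tsv(matrix_to_tibble(activity, "tf"), path, progress = FALSE)
  invisible(path)
}

#' Read / write a scored communication tensor (long TSV)
#'
#' Columns: condition, sender, receiver, pair, pathway, ligand, receptor,
#' prob, pval.
#'
#' @param path File path.
#' @param alpha Significance level applied on read (entries with
#'   `pval > alpha` are zeroed).
#' @return `read_comm_tensor`: a `comm_tensor`.
#' @export
read_comm_tensor <- function(path, alpha = 0.05) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_comm_tensor(df, alpha = alpha)
}

#' @rdname read_comm_tensor
#' @param ct A `comm_tensor`.
#' @export
write_comm_tensor <- function(ct, path) {
  readr::write_tsv(as_tibble(ct), path, progress = FALSE)
  invisible(path)
}

#' Write / read a multiscale signaling graph
#'
#' Two plain-text formats: `"edgelist"`, a TSV of
#' (from, to, layer, weight, sign) with the sender/receiver/condition context
#' in `#`-prefixed header lines; and `"graphtxt"`, a structured text dump with
#' explicit NODE and EDGE records. Both round-trip losslessly.
#'
#' @param g A `multiscale_graph`.
#' @param path File path.
#' @param format `"edgelist"` or `"graphtxt"`.
#' @export
write_graph <- function(g, path, format = c("edgelist", "graphtxt")) {
  format <- match.arg(format)
  meta <- c(sender = attr(g, "sender") %||% "", receiver = attr(g, "receiver") %||% "",
            condition = attr(g, "condition") %||% "")
  edges <- as_tibble(g)
  if (format == "edgelist") {
    hdr <- sprintf("# %s=%s", names(meta), meta)
    body <- c(hdr, paste(c("from", "to", "layer", "weight", "sign"), collapse = "\t"))
    if (nrow(edges)) {
      body <- c(body, sprintf("%s\t%s\t%s\t%.17g\t%d", edges$from, edges$to,
                              edges$layer, edges$weight, as.integer(edges$sign)))
    }
    readr::write_lines(body, path)
  } else {
    nodes <- graph_nodes(g)
    body <- c("GRAPH multiscale",
              sprintf("META %s %s", names(meta), meta),
              sprintf("NODE %s %s", nodes$node, nodes$role))
    if (nrow(edges)) {
      body <- c(body, sprintf("EDGE %s %s %s %.17g %d", edges$from, edges$to,
                              edges$layer, edges$weight, as.integer(edges$sign)))
    }
    readr::write_lines(body, path)
  }
  invisible(path)
}

#' @rdname write_graph
#' @return `read_graph`: a `multiscale_graph`.
#' @export
read_graph <- function(path, format = c("auto", "edgelist", "graphtxt")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path, progress = FALSE)
  if (format == "auto") {
    format <- if (length(lines) && startsWith(lines[1], "GRAPH")) "graphtxt" else "edgelist"
  }
  if (format == "edgelist") {
    meta_lines <- grep("^# ", lines, value = TRUE)
    meta <- setNames(sub("^# [a-z]+=", "", meta_lines),
                     sub("=.*$", "", sub("^# ", "", meta_lines)))
    body <- lines[!grepl("^# ", lines)]
    con <- textConnection(body)
    on.exit(close(con))
    df <- utils::read.delim(con, sep = "\t", stringsAsFactors = FALSE)
    edges <- as_tibble(df)
  } else {
    meta_lines <- grep("^META ", lines, value = TRUE)
    parts <- strsplit(sub("^META ", "", meta_lines), " ")
    meta <- setNames(vapply(parts, function(p) paste(p[-1], collapse = " "), ""),
                     vapply(parts, `[[`, "", 1))
    edge_lines <- grep("^EDGE ", lines, value = TRUE)
    if (length(edge_lines)) {
      ep <- strsplit(sub("^EDGE ", "", edge_lines), " ")
      edges <- tibble(
        from = vapply(ep, `[[`, "", 1), to = vapply(ep, `[[`, "", 2),
        layer = vapply(ep, `[[`, "", 3),
        weight = as.numeric(vapply(ep, `[[`, "", 4)),
        sign = as.integer(vapply(ep, `[[`, "", 5)))
    } else {
      edges <- tibble(from = character(), to = character(), layer = character(),
                      weight = numeric(), sign = integer())
    }
  }
  if (!nrow(edges)) {
    edges <- tibble(from = character(), to = character(), layer = character(),
                    weight = numeric(), sign = integer())
  }
  new_multiscale_graph(edges,
                       sender = meta[["sender"]] %||% "",
                       receiver = meta[["receiver"]] %||% "",
                       condition = meta[["condition"]] %||% "")
}

#' Write / read a set of comparison tables
#'
#' Each element of a named list of tibbles is written to
#' `<directory>/<name>.tsv`; `read_tables()` restores the list.
#'
#' @param tables Named list of data frames.
#' @param directory Output directory (created if absent).
#' @export
write_tables <- function(tables, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  stopifnot(length(names(tables)) == length(tables))
  imap(tables, function(tb, nm) {
    readr::write_tsv(as_tibble(tb), file.path(directory, paste0(nm, ".tsv")),
                     progress = FALSE)
  })
  invisible(directory)
}

#' @rdname write_tables
#' @return `read_tables`: named list of tibbles.
#' @export
read_tables <- function(directory) {
  files <- sort(list.files(directory, pattern = "\\.tsv$", full.names = TRUE))
  out <- map(files, readr::read_tsv, show_col_types = FALSE, progress = FALSE)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
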