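#' Joint embedding and classification of pathway communication networks
#'
#' Every (pathway, condition) communication network is reduced to its set of
#' significant (sender, receiver) edges; pairwise Jaccard functional
#' similarity `S` gives a distance `D = 1 - S`, which is embedded in two
#' dimensions by classical metric scaling (deterministic, with a fixed sign
#' convention) and partitioned by k-means on the coordinates. Pathways whose
#' networks sit in different clusters, or far apart in the shared space,
#' changed their signaling sources and targets between conditions.
#'
#' @param cts List of `comm_tensor`s (one per condition) or a single tibble
#'   with columns `pathway`, `condition`, `sender`, `receiver`, `prob`.
#' @param n_clusters Number of network clusters (must not exceed the number
#'   of non-empty networks).
#' @param seed Integer seed for the k-means initialization.
#' @param variant Similarity variant passed to [functional_similarity()].
#' @return A `comm_embedding`: tibble `pathway`, `condition`, `dim1`, `dim2`,
#'   `cluster`, with the similarity and distance matrices as attributes.
#' @export
embed_networks <- function(cts, n_clusters = 2, seed = 0,
                           variant = "jaccard") {
  df <- if (is.data.frame(cts)) as_tibble(cts) else bind_rows(map(cts, as_tibble))
  need <- c("pathway", "condition", "sender", "receiver", "prob")
  if (!all(need %in% names(df))) {
    abort(sprintf("network table lacks column(s): %s",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  }
  nets <- df |>
    filter(.data$prob > 0) |>
    distinct(.data$pathway, .data$condition, .data$sender, .data$receiver)
  keys <- distinct(df, .data$pathway, .data$condition)
  edge_sets <- map(seq_len(nrow(keys)), function(i) {
    filter(nets, .data$pathway == keys$pathway[i],
           .data$condition == keys$condition[i])
  })
  empty <- map_dbl(edge_sets, nrow) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d network(s) without significant edges", sum(empty)))
    keys <- keys[!empty, , drop = FALSE]
    edge_sets <- edge_sets[!empty]
  }
  n <- nrow(keys)
  if (n < 2) abort("need at least two non-empty networks to embed")
  if (n_clusters > n) {
    abort(sprintf("n_clusters (%d) exceeds the number of networks (%d)", n_clusters, n))
  }
  S <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      S[i, j] <- S[j, i] <- functional_similarity(edge_sets[[i]], edge_sets[[j]],
                                                  variant = variant)
    }
  }
  nm <- paste(keys$pathway, keys$condition, sep = "|")
  dimnames(S) <- list(nm, nm)
  D <- 1 - S
  coords <- cmdscale(stats::as.dist(D), k = min(2, n - 1))
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  coords <- fix_signs(coords)
  cl <- withr::with_seed(seed, kmeans(coords, centers = n_clusters, nstart = 20))
  out <- tibble(pathway = keys$pathway, condition = keys$condition,
                dim1 = coords[, 1], dim2 = coords[, 2],
                cluster = as.integer(cl$cluster))
  structure(out, class = c("comm_embedding", class(tibble())),
            similarity = S, distance = D)
}

#' Shift of one pathway's network across conditions in the shared embedding
#'
#' Euclidean distance between the embedded coordinates of the same pathway
#' under two conditions: large distances flag pathways whose communication
#' architecture changed.
#'
#' @param embedding A `comm_embedding`.
#' @param pathway Pathway name (default: all pathways present).
#' @return Tibble `pathway`, `condition_a`, `condition_b`, `distance`.
#' @export
pathway_distance <- function(embedding, pathway = NULL) {
  df <- as_tibble(embedding)
  if (!is.null(pathway)) {
    df <- filter(df, .data$pathway %in% !!pathway)
    if (!nrow(df)) abort(sprintf("pathway '%s' not present in the embedding", pathway[1]))
  }
  base <- select(df, "pathway", "condition", "dim1", "dim2")
  dplyr::inner_join(base, base, by = "pathway", suffix = c("_a", "_b"),
                    relationship = "many-to-many") |>
    filter(.data$condition_a < .data$condition_b) |>
    mutate(distance = sqrt((.data$dim1_a - .data$dim1_b)^2 +
                             (.data$dim2_a - .data$dim2_b)^2)) |>
    select("pathway", "condition_a", "condition_b", "distance") |>
    arrange(.data$pathway, .data$condition_a, .data$condition_b)
}

#' @describeIn embed_networks Scatter plot of the shared two-dimensional
#'   embedding, colored by cluster and labeled by pathway.
#' @param object,x A `comm_embedding`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.comm_embedding <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$dim1, .data$dim2,
                               color = factor(.data$cluster),
                               shape = .data$condition)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$pathway),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "dim 1", y = "dim 2", color = "cluster",
                  shape = "condition") +
    ggplot2::theme_minimal()
}

#' @export
plot.comm_embedding <- function(x, ...) print(autoplot.comm_embedding(x, ...))
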