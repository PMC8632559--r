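# Multi-condition comparison analytics: counts, strengths, information flow,
# similarity, embedding, classification, per-pair contributions.

union_groups <- function(ct_a, ct_b) {
  union(comm_groups(ct_a), comm_groups(ct_b))
}

complete_grid <- function(df, groups, fill_col) {
  crossing(sender = groups, receiver = groups) |>
    left_join(df, by = c("sender", "receiver")) |>
    mutate(across(dplyr::all_of(fill_col), ~ replace_na(.x, 0)))
}

#' Count significant interactions between every pair of cell groups
#'
#' The entry (sender, receiver) is the number of ligand-receptor pairs with a
#' positive (significance-filtered) communication probability from the sender
#' to the receiver group.
#'
#' @param ct A `comm_tensor`.
#' @return Tibble with columns `sender`, `receiver`, `n` over the full group
#'   grid (groups without communication appear with 0).
#' @export
count_interactions <- function(ct) {
  groups <- comm_groups(ct)
  counts <- as_tibble(ct) |>
    filter(.data$prob > 0) |>
    dplyr::count(.data$sender, .data$receiver, name = "n")
  complete_grid(counts, groups, "n") |>
    mutate(n = as.integer(.data$n))
}

#' Differential interaction counts between two conditions
#'
#' Computes `count(ct_b) - count(ct_a)` after reconciling the two conditions'
#' group sets to their union (groups absent from one condition are padded
#' with zero counts, accommodating datasets whose cell-type compositions are
#' not identical). Positive entries mean increased signaling in the second
#' condition.
#'
#' @param ct_a,ct_b `comm_tensor`s of the two conditions.
#' @return Tibble `sender`, `receiver`, `delta_n`.
#' @export
differential_counts <- function(ct_a, ct_b) {
  groups <- union_groups(ct_a, ct_b)
  pad <- function(ct) {
    complete_grid(dplyr::count(filter(as_tibble(ct), .data$prob > 0),
                               .data$sender, .data$receiver, name = "n"),
                  groups, "n")
  }
  left_join(pad(ct_a), pad(ct_b), by = c("sender", "receiver"),
            suffix = c("_a", "_b")) |>
    mutate(delta_n = as.integer(.data$n_b - .data$n_a)) |>
    select("sender", "receiver", "delta_n")
}

#' Outgoing and incoming interaction strength per cell group
#'
#' Weighted degree centrality of the communication network: the outgoing
#' strength of a group is the sum of communication probabilities of all
#' signaling it sends (its out-degree in the weighted network), the incoming
#' strength the sum of all signaling it receives (in-degree); optionally
#' computed per signaling pathway.
#'
#' @param ct A `comm_tensor`.
#' @param per_pathway If `TRUE`, strengths are reported per pathway.
#' @return Tibble `group` (, `pathway`), `outgoing`, `incoming`.
#' @export
interaction_strength <- function(ct, per_pathway = FALSE) {
  groups <- comm_groups(ct)
  df <- as_tibble(ct)
  if (per_pathway) {
    pathways <- unique(df$pathway)
    out <- df |>
      group_by(group = .data$sender, pathway = .data$pathway) |>
      summarise(outgoing = sum(.data$prob), .groups = "drop")
    inc <- df |>
      group_by(group = .data$receiver, pathway = .data$pathway) |>
      summarise(incoming = sum(.data$prob), .groups = "drop")
    crossing(group = groups, pathway = pathways) |>
      left_join(out, by = c("group", "pathway")) |>
      left_join(inc, by = c("group", "pathway")) |>
      mutate(across(c("outgoing", "incoming"), ~ replace_na(.x, 0)))
  } else {
    out <- df |>
      group_by(group = .data$sender) |>
      summarise(outgoing = sum(.data$prob), .groups = "drop")
    inc <- df |>
      group_by(group = .data$receiver) |>
      summarise(incoming = sum(.data$prob), .groups = "drop")
    tibble(group = groups) |>
      left_join(out, by = "group") |>
      left_join(inc, by = "group") |>
      mutate(across(c("outgoing", "incoming"), ~ replace_na(.x, 0)))
  }
}

#' Differential interaction strength between two conditions
#'
#' `interaction_strength(ct_b) - interaction_strength(ct_a)` with the group
#' (and pathway) sets reconciled to their union. Positive differential
#' outgoing (incoming) strength marks a group more likely to act as a sender
#' (receiver) in the second condition.
#'
#' @inheritParams differential_counts
#' @param per_pathway If `TRUE`, per-pathway differentials.
#' @return Tibble `group` (, `pathway`), `delta_outgoing`, `delta_incoming`.
#' @export
differential_strength <- function(ct_a, ct_b, per_pathway = FALSE) {
  keys <- if (per_pathway) c("group", "pathway") else "group"
  pad <- function(st, template) {
    template |>
      left_join(st, by = keys) |>
      mutate(across(c("outgoing", "incoming"), ~ replace_na(.x, 0)))
  }
  st_a <- interaction_strength(ct_a, per_pathway)
  st_b <- interaction_strength(ct_b, per_pathway)
  template <- distinct(bind_rows(st_a[keys], st_b[keys]))
  full_join(pad(st_a, template), pad(st_b, template), by = keys,
            suffix = c("_a", "_b")) |>
    mutate(delta_outgoing = .data$outgoing_b - .data$outgoing_a,
           delta_incoming = .data$incoming_b - .data$incoming_a) |>
    select(dplyr::all_of(keys), "delta_outgoing", "delta_incoming")
}

#' Information flow of each signaling pathway
#'
#' The information flow of a pathway is the sum of communication
#' probabilities over all sender-receiver group pairs in its network, i.e.
#' the total edge weight of the pathway's communication network.
#'
#' @param ct A `comm_tensor`.
#' @return Tibble `pathway`, `flow`.
#' @export
information_flow <- function(ct) {
  as_tibble(ct) |>
    group_by(pathway = .data$pathway) |>
    summarise(flow = sum(.data$prob), .groups = "drop")
}

#' Relative information flow across conditions
#'
#' Each pathway's per-condition information flow divided by the pathway's
#' total flow summed over the supplied conditions; pathways with zero total
#' flow are flagged `undefined` (their relative flow is `NA`).
#'
#' @param cts List of `comm_tensor`s (>= 1), one per condition.
#' @return Tibble `pathway`, `condition`, `flow`, `rel_flow`, `undefined`.
#' @export
relative_information_flow <- function(cts) {
  flows <- bind_rows(map(cts, function(ct) {
    mutate(information_flow(ct), condition = ct$condition[1] %||% NA_character_)
  }))
  flows |>
    tidyr::complete(.data$pathway, .data$condition, fill = list(flow = 0)) |>
    group_by(.data$pathway) |>
    mutate(total = sum(.data$flow),
           undefined = .data$total == 0,
           rel_flow = ifelse(.data$undefined, NA_real_, .data$flow / .data$total)) |>
    ungroup() |>
    select("pathway", "condition", "flow", "rel_flow", "undefined")
}

#' Contribution of each ligand-receptor pair to a pathway's flow
#'
#' The fraction of the pathway's information flow carried by each of its
#' ligand-receptor pairs; fractions sum to 1 when the pathway has positive
#' flow.
#'
#' @param ct A `comm_tensor`.
#' @param pathway Pathway name.
#' @return Tibble `pair`, `flow`, `fraction`.
#' @export
pair_contribution <- function(ct, pathway) {
  df <- filter(as_tibble(ct), .data$pathway == !!pathway)
  if (!nrow(df)) abort(sprintf("pathway '%s' not present in the tensor", pathway))
  per_pair <- df |>
    group_by(pair = .data$pair) |>
    summarise(flow = sum(.data$prob), .groups = "drop")
  total <- sum(per_pair$flow)
  mutate(per_pair, fraction = if (total > 0) .data$flow / total else NA_real_)
}

#' Jaccard functional similarity of two communication networks
#'
#' Two pathway networks are compared through the overlap of their
#' (sender, receiver) communication edges: `|E(G) ∩ E(G')| / |E(G) ∪ E(G')|`.
#' High similarity means the two networks share their major senders and
#' receivers; low similarity flags a change in network architecture across
#' conditions.
#'
#' @param edges_a,edges_b Data frames with columns `sender`, `receiver`
#'   (rows with a `prob` column are first restricted to `prob > 0`).
#' @param variant `"jaccard"` (default) or `"odds"`, which divides the
#'   overlap by `|union| - |intersection|` instead (undefined for identical
#'   non-empty sets, returned as `Inf`).
#' @return Similarity in `[0, 1]` (`NA` with a warning when both edge sets
#'   are empty).
#' @export
functional_similarity <- function(edges_a, edges_b,
                                  variant = c("jaccard", "odds")) {
  variant <- match.arg(variant)
  key <- function(e) {
    e <- as_tibble(e)
    if ("prob" %in% names(e)) e <- filter(e, .data$prob > 0)
    unique(paste(e$sender, e$receiver, sep = "\r"))
  }
  a <- key(edges_a)
  b <- key(edges_b)
  if (!length(a) && !length(b)) {
    warn("both edge sets are empty; similarity undefined")
    return(NA_real_)
  }
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  switch(variant,
         jaccard = inter / uni,
         odds = if (uni == inter) Inf else inter / (uni - inter))
}

#' Assemble the full set of comparison tables for >= 2 conditions
#'
#' Convenience wrapper producing interaction-count matrices per condition,
#' differential counts and strengths for consecutive condition pairs,
#' per-pathway strengths, and (relative) information flow.
#'
#' @param cts List of `comm_tensor`s (>= 2).
#' @return Named list of tibbles (class `comparison_tables`).
#' @export
compare_conditions <- function(cts) {
  if (length(cts) < 2) abort("need at least two conditions to compare")
  cond <- map_chr(cts, ~ .x$condition[1] %||% NA_character_)
  if (anyDuplicated(cond)) abort("condition labels must be distinct")
  names(cts) <- cond
  out <- list()
  for (i in seq_along(cts)) {
    out[[paste0("counts_", cond[i])]] <- count_interactions(cts[[i]])
    out[[paste0("strength_", cond[i])]] <- interaction_strength(cts[[i]], per_pathway = TRUE)
  }
  for (i in seq_len(length(cts) - 1)) {
    for (j in seq((i + 1), length(cts))) {
      tag <- paste0(cond[i], "_vs_", cond[j])
      out[[paste0("diff_counts_", tag)]] <- differential_counts(cts[[i]], cts[[j]])
      out[[paste0("diff_strength_", tag)]] <-
        differential_strength(cts[[i]], cts[[j]], per_pathway = TRUE)
    }
  }
  out[["information_flow"]] <- relative_information_flow(cts)
  class(out) <- c("comparison_tables", "list")
  out
}
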