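test_that("interaction counts match definition and enumeration", {
  zero <- make_tensor(tidyr::crossing(sender = c("a", "b"), receiver = c("a", "b"),
                                      pair = paste0("p", 1:3)) |>
                        dplyr::mutate(prob = 0, pval = 1))
  expect_true(all(count_interactions(zero)$n == 0))

  # exactly 3 of 5 pairs active from g1 to g2
  df <- tidyr::crossing(sender = c("g1", "g2"), receiver = c("g1", "g2"),
                        pair = paste0("p", 1:5)) |>
    dplyr::mutate(prob = ifelse(sender == "g1" & receiver == "g2" &
                                  pair %in% c("p1", "p2", "p3"), 0.5, 0),
                  pval = 0)
  cnt <- count_interactions(make_tensor(df))
  expect_equal(dplyr::filter(cnt, sender == "g1", receiver == "g2")$n, 3L)
  expect_equal(sum(cnt$n), 3L)

  for (seed in 1:3) {
    ct <- random_tensor(seed)
    cnt <- count_interactions(ct)
    df <- tibble::as_tibble(ct)
    for (i in seq_len(nrow(cnt))) {
      expect_equal(cnt$n[i], sum(df$prob[df$sender == cnt$sender[i] &
                                           df$receiver == cnt$receiver[i]] > 0))
    }
  }
})

test_that("differential tables are antisymmetric and pad absent groups", {
  ct <- random_tensor(4)
  expect_true(all(differential_counts(ct, ct)$delta_n == 0))

  ct_a <- random_tensor(5, n_groups = 3)
  ct_b <- random_tensor(6, n_groups = 4)
  d_ab <- differential_counts(ct_a, ct_b)
  d_ba <- differential_counts(ct_b, ct_a)
  j <- dplyr::left_join(d_ab, d_ba, by = c("sender", "receiver"))
  expect_equal(j$delta_n.x, -j$delta_n.y)

  # group g4 exists only in ct_b: its rows must equal ct_b's counts
  cnt_b <- count_interactions(ct_b)
  only_b <- dplyr::filter(d_ab, sender == "g4")
  expect_equal(only_b$delta_n,
               dplyr::filter(cnt_b, sender == "g4")$n[
                 match(only_b$receiver, dplyr::filter(cnt_b, sender == "g4")$receiver)])

  s_ab <- differential_strength(ct_a, ct_b, per_pathway = TRUE)
  s_ba <- differential_strength(ct_b, ct_a, per_pathway = TRUE)
  js <- dplyr::left_join(s_ab, s_ba, by = c("group", "pathway"))
  expect_equal(js$delta_outgoing.x, -js$delta_outgoing.y)
  expect_equal(js$delta_incoming.x, -js$delta_incoming.y)
})

test_that("strengths satisfy the conservation identities", {
  single <- make_tensor(tibble::tibble(sender = "g1", receiver = "g2",
                                       pair = "p1", prob = 0.4, pval = 0),
                        groups = c("g1", "g2", "g3"))
  st <- interaction_strength(single)
  expect_equal(dplyr::filter(st, group == "g1")$outgoing, 0.4)
  expect_equal(dplyr::filter(st, group == "g2")$incoming, 0.4)
  expect_equal(sum(st$outgoing) - 0.4 + sum(st$incoming) - 0.4, 0)

  for (seed in 1:3) {
    ct <- random_tensor(seed)
    st <- interaction_strength(ct)
    fl <- information_flow(ct)
    total <- sum(tibble::as_tibble(ct)$prob)
    expect_equal(sum(st$outgoing), total)
    expect_equal(sum(st$incoming), total)
    expect_equal(sum(fl$flow), total)
    # per-pathway table marginalizes to the overall one
    stp <- interaction_strength(ct, per_pathway = TRUE)
    agg <- stp |> dplyr::group_by(group) |>
      dplyr::summarise(outgoing = sum(outgoing), incoming = sum(incoming))
    expect_equal(dplyr::arrange(agg, group),
                 dplyr::arrange(st, group))
  }
})

test_that("relative information flow normalizes per pathway", {
  ct <- random_tensor(8)
  one <- relative_information_flow(list(ct))
  expect_true(all(one$rel_flow[!one$undefined] == 1))

  df <- tibble::tibble(sender = "a", receiver = "b", pair = "p1",
                       pathway = "PW", prob = 0.3, pval = 0)
  ct1 <- make_tensor(df, condition = "c1")
  ct2 <- make_tensor(df, condition = "c2")
  two <- relative_information_flow(list(ct1, ct2))
  expect_equal(two$rel_flow, c(0.5, 0.5))

  dead <- make_tensor(dplyr::mutate(df, prob = 0), condition = "c1")
  dead2 <- make_tensor(dplyr::mutate(df, prob = 0), condition = "c2")
  z <- relative_information_flow(list(dead, dead2))
  expect_true(all(z$undefined))
  expect_true(all(is.na(z$rel_flow)))

  for (seed in 1:2) {
    cts <- list(random_tensor(seed, condition = "c1"),
                random_tensor(seed + 10, condition = "c2"))
    rel <- relative_information_flow(cts)
    sums <- rel |> dplyr::filter(!undefined) |> dplyr::group_by(pathway) |>
      dplyr::summarise(s = sum(rel_flow))
    expect_true(all(abs(sums$s - 1) < 1e-12))
  }
})

test_that("pair contributions are fractions of the pathway flow summing to 1", {
  df <- tibble::tibble(sender = "a", receiver = "b", pair = c("p1", "p2"),
                       pathway = c("solo", "duo"), prob = c(0.7, 0.2), pval = 0)
  ct <- make_tensor(df)
  expect_equal(pair_contribution(ct, "solo")$fraction, 1)

  df2 <- tibble::tibble(sender = "a", receiver = "b", pair = c("p1", "p2"),
                        pathway = "PW", prob = c(0.3, 0.3), pval = 0)
  expect_equal(pair_contribution(make_tensor(df2), "PW")$fraction, c(0.5, 0.5))

  ct3 <- random_tensor(9)
  for (pw in unique(ct3$pathway)) {
    contr <- pair_contribution(ct3, pw)
    if (sum(contr$flow) > 0) expect_equal(sum(contr$fraction), 1)
    # oracle: direct ratio
    df <- dplyr::filter(tibble::as_tibble(ct3), pathway == pw)
    for (p in unique(df$pair)) {
      expect_equal(contr$fraction[contr$pair == p],
                   sum(df$prob[df$pair == p]) / sum(df$prob))
    }
  }
  expect_error(pair_contribution(ct3, "missing_pathway"), "not present")
})

test_that("functional similarity is a bounded symmetric Jaccard index", {
  ee <- function(...) tibble::tibble(sender = c(...), receiver = "r")
  abc <- ee("a", "b", "c")
  bcd <- ee("b", "c", "d")
  expect_equal(functional_similarity(abc, abc), 1)
  expect_equal(functional_similarity(abc, ee("x", "y")), 0)
  expect_equal(functional_similarity(abc, bcd), 0.5)
  expect_equal(functional_similarity(abc, bcd), functional_similarity(bcd, abc))
  expect_warning(v <- functional_similarity(abc[0, ], abc[0, ]), "undefined")
  expect_true(is.na(v))
  # as-printed odds variant: intersection over union minus intersection
  expect_equal(functional_similarity(abc, bcd, variant = "odds"), 1)
  expect_equal(functional_similarity(abc, abc, variant = "odds"), Inf)
  for (seed in 1:5) {
    a <- tibble::as_tibble(random_tensor(seed))
    b <- tibble::as_tibble(random_tensor(seed + 5))
    s <- functional_similarity(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, functional_similarity(b, a))
  }
})

toy_networks <- function() {
  # three networks with known pairwise Jaccard distances
  dplyr::bind_rows(
    tibble::tibble(pathway = "A", condition = "c1",
                   sender = c("e1", "e2"), receiver = "r", prob = 1),
    tibble::tibble(pathway = "A", condition = "c2",
                   sender = c("e2", "e3"), receiver = "r", prob = 1),
    tibble::tibble(pathway = "B", condition = "c1",
                   sender = c("e1", "e2", "e3"), receiver = "r", prob = 1))
}

test_that("classical scaling reproduces known distances and is deterministic", {
  emb <- embed_networks(toy_networks(), n_clusters = 2, seed = 1)
  D <- attr(emb, "distance")
  expect_equal(D[1, 2], 2 / 3)   # {e1,e2} vs {e2,e3}
  expect_equal(D[1, 3], 1 / 3)   # {e1,e2} vs {e1,e2,e3}
  expect_equal(D[2, 3], 1 / 3)
  coords <- as.matrix(tibble::as_tibble(emb)[, c("dim1", "dim2")])
  embedded_d <- as.matrix(stats::dist(coords))
  expect_equal(embedded_d[upper.tri(embedded_d)], D[upper.tri(D)],
               tolerance = 1e-6)

  emb2 <- embed_networks(toy_networks(), n_clusters = 2, seed = 1)
  expect_equal(emb$cluster, emb2$cluster)

  # a duplicated network sits at distance zero from its twin
  dup <- dplyr::bind_rows(toy_networks(),
                          tibble::tibble(pathway = "B", condition = "c2",
                                         sender = c("e1", "e2", "e3"),
                                         receiver = "r", prob = 1))
  emb3 <- embed_networks(dup, n_clusters = 2, seed = 1)
  D3 <- attr(emb3, "distance")
  expect_equal(D3["B|c1", "B|c2"], 0)
  expect_error(embed_networks(toy_networks(), n_clusters = 5),
               "exceeds the number of networks")
})

test_that("pathway embedding distances are Euclidean", {
  emb <- structure(tibble::tibble(pathway = c("A", "A", "B", "B"),
                                  condition = c("c1", "c2", "c1", "c2"),
                                  dim1 = c(0, 3, 1, 1), dim2 = c(0, 4, 2, 2),
                                  cluster = 1L),
                   class = c("comm_embedding", class(tibble::tibble())))
  d <- pathway_distance(emb, "A")
  expect_equal(d$distance, 5)
  dB <- pathway_distance(emb, "B")
  expect_equal(dB$distance, 0)
  all_d <- pathway_distance(emb)
  expect_equal(nrow(all_d), 2)
})

test_that("comparison results do not depend on condition input order", {
  cts <- list(random_tensor(11, condition = "c1"),
              random_tensor(12, condition = "c2"),
              random_tensor(13, condition = "c3"))
  rel <- relative_information_flow(cts)
  rel_rev <- relative_information_flow(rev(cts))
  expect_equal(dplyr::arrange(rel, pathway, condition),
               dplyr::arrange(rel_rev, pathway, condition))
})
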