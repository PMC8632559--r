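# shared fixtures and independent oracles, built in code at test time

# small deterministic expression matrix with two groups
tiny_expr <- function() {
  m <- matrix(c(2, 2, 2, 2, 0, 0,
                1, 0, 0, 0, 3, 3,
                0, 0, 0, 0, 0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              paste0("c", 1:6)))
  m
}

tiny_labels <- function() {
  tibble::tibble(cell = paste0("c", 1:6),
                 group = rep(c("grp1", "grp2"), each = 3))
}

# build a comm_tensor from a compact entry table (everything significant)
make_tensor <- function(entries, condition = "cond1", groups = NULL,
                        pathway_of = NULL) {
  df <- tibble::as_tibble(entries)
  if (!"pathway" %in% names(df)) {
    df$pathway <- if (is.null(pathway_of)) "PWX" else pathway_of[df$pair]
  }
  df$pval <- df$pval %||% 0
  as_comm_tensor(df, condition = condition, groups = groups)
}

`%||%` <- rlang::`%||%`

# random significance-filtered tensor for property tests
random_tensor <- function(seed, n_groups = 4, n_pairs = 6, n_pathways = 3,
                          condition = "cond1") {
  withr::with_seed(seed, {
    groups <- paste0("g", seq_len(n_groups))
    pairs <- paste0("p", seq_len(n_pairs))
    pw <- paste0("PW", ((seq_len(n_pairs) - 1) %% n_pathways) + 1)
    df <- tidyr::crossing(sender = groups, receiver = groups, pair = pairs)
    df$pathway <- pw[match(df$pair, pairs)]
    df$prob <- round(stats::runif(nrow(df)) * stats::rbinom(nrow(df), 1, 0.4), 4)
    df$pval <- 0
    as_comm_tensor(df, condition = condition, groups = groups)
  })
}

# random seeded regression instance
random_instance <- function(seed, m = 8, q = 5, n = 30, density = 0.3,
                            noise_sd = 0.1) {
  withr::with_seed(seed, {
    B <- matrix(stats::rnorm(q * n), q, n)
    X_true <- matrix(stats::rbinom(m * q, 1, density) * stats::rnorm(m * q), m, q)
    A <- X_true %*% B + matrix(stats::rnorm(m * n, 0, noise_sd), m, n)
    list(A = A, B = B, X_true = X_true,
         N = matrix(stats::rbinom(m * q, 1, 0.3), m, q))
  })
}

# independent generic minimizer of the regression objective: split X = P - Q
# (P, Q >= 0) so the l1 term is linear and L-BFGS-B applies, multi-start
oracle_minimize <- function(A, B, N_eff, lambda1, lambda2, n_starts = 3,
                            seed = 42) {
  m <- nrow(A); q <- nrow(B)
  BBt <- B %*% t(B)
  ABt <- A %*% t(B)
  fn <- function(par) {
    P <- matrix(par[1:(m * q)], m, q)
    Q <- matrix(par[-(1:(m * q))], m, q)
    X <- P - Q
    0.5 * sum((A - X %*% B)^2) + 0.5 * lambda1 * sum((X * N_eff)^2) +
      lambda2 * sum(P + Q)
  }
  gr <- function(par) {
    P <- matrix(par[1:(m * q)], m, q)
    Q <- matrix(par[-(1:(m * q))], m, q)
    X <- P - Q
    G <- X %*% BBt - ABt + lambda1 * (X * N_eff^2)
    c(as.vector(G + lambda2), as.vector(-G + lambda2))
  }
  best <- Inf
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      init <- if (s == 1) rep(0, 2 * m * q) else abs(stats::rnorm(2 * m * q, 0, 0.1))
      opt <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                          lower = 0, control = list(maxit = 2000, factr = 1e4))
      best <- min(best, opt$value)
    }
  })
  best
}

# brute-force reachability filter for multiscale graphs
orphan_edges <- function(g) {
  e <- tibble::as_tibble(g)
  ligands <- unique(e$from[e$layer == "ligand_receptor"])
  reach <- ligands
  repeat {
    nxt <- unique(c(reach, e$to[e$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  sum(!(e$from %in% reach))
}

# memoised default fixture shared across expensive tests
fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function(seed = 0) {
  key <- paste0("fx", seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- generate_fixture(seed = seed)
  }
  fixture_cache[[key]]
}

# oversized multiscale graph for cap-enforcement checks
big_graph <- function(n_tfs = 60, n_targets = 40) {
  ct <- make_tensor(tibble::tibble(sender = "G1", receiver = "G2", pair = "p",
                                   pathway = "PW", ligand = "L",
                                   receptor = "R", prob = 0.9, pval = 0))
  rt <- tibble::tibble(source = "R", target = paste0("TF", seq_len(n_tfs)),
                       layer = "receptor_tf")
  X <- withr::with_seed(5, matrix(rnorm(n_targets * n_tfs), n_targets, n_tfs,
                                  dimnames = list(paste0("T", seq_len(n_targets)),
                                                  paste0("TF", seq_len(n_tfs)))))
  assemble_multiscale(ct, "G1", "G2", rt, X)
}

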