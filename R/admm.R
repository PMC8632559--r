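#' Solver configuration for the prior-regularized TF-target regression
#'
#' The regression estimates a targets x TFs weight matrix X from target
#' expression A (targets x cells) and TF activity B (TFs x cells) by
#' minimizing
#' \deqn{\tfrac12\|A - XB\|_F^2 + \tfrac12\lambda_1\|X \circ N_{eff}\|_F^2 +
#'   \lambda_2 \sum_i \|X_{i,\cdot}\|_1,}
#' where the elementwise mask \eqn{N_{eff}} decides which entries the
#' quadratic penalty shrinks. Under the default convention
#' (`"penalize-nonprior"`) edges without prior support are penalized
#' (\eqn{N_{eff} = 1 - N}), so prior knowledge protects known regulatory
#' edges from shrinkage; `"penalize-prior"` applies the quadratic penalty to
#' the prior edges themselves (\eqn{N_{eff} = N}).
#'
#' @param lambda1 Quadratic (prior-mask) penalty weight, default 50.
#' @param lambda2 L1 sparsity penalty weight, default 10.
#' @param t ADMM penalty parameter, default 1.
#' @param eps_abs,eps_rel Absolute / relative stopping tolerances
#'   (defaults 1e-4 / 1e-3).
#' @param max_iter Iteration cap, default 3000.
#' @param mask_convention `"penalize-nonprior"` (default) or
#'   `"penalize-prior"`.
#' @param omega Ensemble weight of the regression estimate against the
#'   proportionality estimate, default 0.7.
#' @return A `solver_config` list.
#' @export
solver_config <- function(lambda1 = 50, lambda2 = 10, t = 1,
                          eps_abs = 1e-4, eps_rel = 1e-3, max_iter = 3000,
                          mask_convention = c("penalize-nonprior", "penalize-prior"),
                          omega = 0.7) {
  mask_convention <- match.arg(mask_convention)
  stopifnot_scalar_number(lambda1, "lambda1")
  stopifnot_scalar_number(lambda2, "lambda2")
  if (lambda1 < 0 || lambda2 < 0) abort("regularization parameters must be >= 0")
  stopifnot_scalar_number(t, "t", positive = TRUE)
  stopifnot_scalar_number(eps_abs, "eps_abs", positive = TRUE)
  stopifnot_scalar_number(eps_rel, "eps_rel", positive = TRUE)
  if (omega < 0 || omega > 1) abort("`omega` must lie in [0, 1]")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, t = t,
                 eps_abs = eps_abs, eps_rel = eps_rel,
                 max_iter = as.integer(max_iter),
                 mask_convention = mask_convention, omega = omega),
            class = "solver_config")
}

effective_mask <- function(N, mask_convention) {
  if (mask_convention == "penalize-nonprior") 1 - N else N
}

#' Objective value of the prior-regularized regression
#'
#' @param X Weight matrix (targets x TFs).
#' @param A Target expression (targets x cells).
#' @param B TF activity (TFs x cells).
#' @param N_eff Effective penalty mask (targets x TFs), already under the
#'   chosen convention.
#' @param lambda1,lambda2 Penalty weights.
#' @return The scalar objective
#'   `0.5*||A - XB||_F^2 + 0.5*lambda1*||X o N_eff||_F^2 + lambda2*sum|X|`.
#' @export
grn_objective <- function(X, A, B, N_eff, lambda1, lambda2) {
  if (nrow(A) != nrow(X) || ncol(X) != nrow(B) || ncol(A) != ncol(B) ||
      !all(dim(N_eff) == dim(X))) {
    abort("shape mismatch: need A (m x n_cells), B (q x n_cells), X and N_eff (m x q)")
  }
  0.5 * sum((A - X %*% B)^2) + 0.5 * lambda1 * sum((X * N_eff)^2) +
    lambda2 * sum(abs(X))
}

#' Elementwise soft-thresholding operator
#'
#' The proximal operator of the absolute value:
#' `sign(v) * max(|v| - kappa, 0)`.
#'
#' @param v Numeric vector or matrix.
#' @param kappa Nonnegative threshold.
#' @return Shrunken values, same shape as `v`.
#' @export
soft_threshold <- function(v, kappa) {
  if (any(kappa < 0)) abort("`kappa` must be nonnegative")
  sign(v) * pmax(abs(v) - kappa, 0)
}

#' Solve the prior-regularized sparse regression by ADMM
#'
#' The problem is split as `min_{X,Z} 0.5||A - XB||^2 +
#' 0.5*lambda1*||Z o N_eff||^2 + lambda2*sum|Z| s.t. X = Z` and solved by
#' alternating exact minimizations of the augmented Lagrangian with penalty
#' parameter `t`:
#'
#' * X-update: a linear solve against `B B' + t I` (positive definite for
#'   `t > 0`), `X = (A B' + t (Z - Y)) (B B' + t I)^{-1}`;
#' * Z-update: elementwise shrinkage combining the quadratic mask penalty
#'   with soft-thresholding,
#'   `Z_ij = S(t (X + Y)_ij, lambda2) / (t + lambda1 N_eff_ij)`;
#' * dual update `Y^k = Y^{k-1} + t (X^k - Z^k)`.
#'
#' Iteration stops when the primal residual `R^k = X^k - Z^k` and the dual
#' residual `S^k = -t (Z^k - Z^{k-1})` satisfy `||R^k||_F < eps_pri` and
#' `||S^k||_F < eps_dual` with `eps_pri = n*eps_abs +
#' eps_rel*max(||X^k||_F, ||Z^k||_F)` and `eps_dual = m*eps_abs +
#' eps_rel*||Y^k||_F` (m targets, n TFs). The exactly sparse block `Z` is
#' returned as the solution.
#'
#' @param A Target expression (targets x cells).
#' @param B TF activity (TFs x cells), cells aligned with `A`.
#' @param N Binary prior mask (targets x TFs); see [prior_mask()].
#' @param config A [solver_config()].
#' @return An `admm_fit` list: `X` (the sparse solution), `X_dense` (the
#'   smooth block), `history` (per-iteration residuals and tolerances),
#'   `iterations`, `converged`, `objective`, and the configuration.
#' @export
solve_admm <- function(A, B, N = NULL, config = solver_config()) {
  if (!inherits(config, "solver_config")) abort("`config` must come from solver_config()")
  if (ncol(A) != ncol(B)) abort("A and B must have the same cells (columns)")
  if (nrow(B) < 1) abort("need at least one TF")
  m <- nrow(A); q <- nrow(B)
  if (is.null(N)) N <- matrix(0, m, q)
  if (!all(dim(N) == c(m, q))) abort("prior mask N must be targets x TFs")
  if (!all(N %in% c(0, 1))) abort("prior mask N must be binary")
  N_eff <- effective_mask(N, config$mask_convention)

  t <- config$t
  ABt <- A %*% t(B)
  M <- B %*% t(B) + diag(t, q)
  Mc <- chol(M)

  X <- matrix(0, m, q)
  Z <- matrix(0, m, q)
  Y <- matrix(0, m, q)
  hist <- vector("list", config$max_iter)
  converged <- FALSE
  k <- 0L
  while (k < config$max_iter) {
    k <- k + 1L
    Z_prev <- Z
    # X-update: right-hand linear solve against (B B' + t I)
    X <- t(backsolve(Mc, forwardsolve(t(Mc), t(ABt + t * (Z - Y)))))
    # Z-update: quadratic mask penalty + l1 shrinkage, elementwise
    V <- X + Y
    Z <- soft_threshold(t * V, config$lambda2) / (t + config$lambda1 * N_eff)
    Y <- Y + t * (X - Z)
    if (!all(is.finite(X)) || !all(is.finite(Z)) || !all(is.finite(Y))) {
      abort(sprintf("non-finite values encountered at ADMM iteration %d", k))
    }
    r_norm <- frobenius(X - Z)
    s_norm <- frobenius(-t * (Z - Z_prev))
    eps_pri <- q * config$eps_abs + config$eps_rel * max(frobenius(X), frobenius(Z))
    eps_dual <- m * config$eps_abs + config$eps_rel * frobenius(Y)
    hist[[k]] <- c(iteration = k, r_norm = r_norm, s_norm = s_norm,
                   eps_pri = eps_pri, eps_dual = eps_dual)
    if (r_norm < eps_pri && s_norm < eps_dual) {
      converged <- TRUE
      break
    }
  }
  history <- as_tibble(do.call(rbind, hist[seq_len(k)]))
  if (!converged) {
    warn(sprintf("ADMM reached max_iter = %d without convergence (primal %.3g vs %.3g, dual %.3g vs %.3g)",
                 config$max_iter, history$r_norm[k], history$eps_pri[k],
                 history$s_norm[k], history$eps_dual[k]))
  }
  ids <- list(rownames(A) %||% paste0("target", seq_len(m)),
              rownames(B) %||% paste0("tf", seq_len(q)))
  dimnames(Z) <- dimnames(X) <- dimnames(N) <- ids
  structure(list(X = Z, X_dense = X, history = history,
                 iterations = k, converged = converged,
                 objective = grn_objective(Z, A, B, N_eff, config$lambda1, config$lambda2),
                 config = config, N = N, N_eff = N_eff),
            class = "admm_fit")
}

#' @export
print.admm_fit <- function(x, ...) {
  cat(sprintf("<admm_fit> %d x %d weights, %d iteration(s), %s, objective %.6g\n",
              nrow(x$X), ncol(x$X), x$iterations,
              if (x$converged) "converged" else "NOT converged", x$objective))
  invisible(x)
}

#' @describeIn solve_admm Tidy the fitted weights into one row per
#'   (target, tf) with the estimate and prior-support flag; set
#'   `nonzero_only = FALSE` to keep zero entries.
#' @param x An `admm_fit`.
#' @param nonzero_only Drop exact zeros (default `TRUE`).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.admm_fit <- function(x, nonzero_only = TRUE, ...) {
  out <- as_tibble(as.data.frame.table(x$X, responseName = "estimate",
                                       stringsAsFactors = FALSE)) |>
    rename(target = "Var1", tf = "Var2") |>
    mutate(prior = as.integer(x$N[cbind(.data$target, .data$tf)]))
  if (nonzero_only) out <- filter(out, .data$estimate != 0)
  arrange(out, desc(abs(.data$estimate)))
}

#' @describeIn solve_admm One-row fit summary (iterations, convergence,
#'   final residuals, objective, sparsity).
#' @exportS3Method generics::glance
glance.admm_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(iterations = x$iterations, converged = x$converged,
         r_norm = h$r_norm, s_norm = h$s_norm,
         eps_pri = h$eps_pri, eps_dual = h$eps_dual,
         objective = x$objective,
         n_nonzero = sum(x$X != 0),
         lambda1 = x$config$lambda1, lambda2 = x$config$lambda2)
}

#' @describeIn solve_admm Residual-convergence trace plot.
#' @param object An `admm_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.admm_fit <- function(object, ...) {
  df <- object$history |>
    select("iteration", primal = "r_norm", dual = "s_norm") |>
    pivot_longer(c("primal", "dual"), names_to = "residual", values_to = "norm")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$norm,
                                   color = .data$residual)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "residual Frobenius norm") +
    ggplot2::theme_minimal()
}
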