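#' Proportionality-based association between TF activities and target expression
#'
#' The proportionality coefficient of two per-cell profiles a (target) and b
#' (TF) is `1 - var(a - b) / (var(a) + var(b))`, i.e. `2 cov(a, b) /
#' (var(a) + var(b))`: it reaches 1 when the profiles differ only by an
#' additive constant, -1 when they are mirrored, and stays near 0 for
#' unrelated profiles. Profiles are the log-shifted values `log(x + shift)`;
#' activities may be negative and are min-shifted to nonnegative before the
#' log. Entries involving a zero-variance profile are set to 0 and flagged.
#'
#' @param B TF activity matrix (TFs x cells).
#' @param A Target expression matrix (targets x cells), same cells.
#' @param shift Positive pseudo-count for the log transform (default 1).
#' @param log_transform Apply the log-shift transform (default `TRUE`); set
#'   to `FALSE` to associate the raw profiles.
#' @return Numeric matrix, targets x TFs, values in `[-1, 1]`; the ids of
#'   zero-variance profiles are attached as attribute `"flat_profiles"`.
#' @export
propr_association <- function(B, A, shift = 1, log_transform = TRUE) {
  if (shift <= 0) abort("`shift` must be > 0")
  if (ncol(A) != ncol(B)) abort("A and B must share their cells (columns)")
  if (log_transform) {
    # profiles with negative entries (activities, centred expression) are
    # min-shifted to nonnegative before the log
    a <- log(A - min(A, 0) + shift)
    b <- log(B - min(B, 0) + shift)
  } else {
    a <- A
    b <- B
  }
  n <- ncol(a)
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  va <- rowSums(ac^2) / (n - 1)
  vb <- rowSums(bc^2) / (n - 1)
  cov_ab <- (ac %*% t(bc)) / (n - 1)
  denom <- outer(va, vb, "+")
  rho <- ifelse(denom > 0, 2 * cov_ab / denom, 0)
  flat <- c(rownames(A)[va == 0], rownames(B)[vb == 0])
  dimnames(rho) <- list(rownames(A), rownames(B))
  attr(rho, "flat_profiles") <- flat
  rho
}

#' Ensemble of the regression and proportionality estimates
#'
#' Both matrices are rescaled to unit maximum absolute value (so a regression
#' weight and a correlation-like measure live on a common scale), then
#' combined as `X_new = omega * X_model + (1 - omega) * X_propr`.
#'
#' @param X_model Regression weight matrix (targets x TFs).
#' @param X_propr Proportionality association matrix, same shape.
#' @param omega Ensemble weight in `[0, 1]` (default 0.7).
#' @return The combined matrix; all-zero inputs are flagged via attribute
#'   `"all_zero"`.
#' @export
ensemble_weights <- function(X_model, X_propr, omega = 0.7) {
  if (!all(dim(X_model) == dim(X_propr))) abort("X_model and X_propr must have the same shape")
  if (omega < 0 || omega > 1) abort("`omega` must lie in [0, 1]")
  all_zero <- character()
  rescale <- function(M, nm) {
    mx <- max(abs(M))
    if (mx == 0) {
      all_zero <<- c(all_zero, nm)
      return(M)
    }
    M / mx
  }
  Xm <- rescale(X_model, "X_model")
  Xp <- rescale(X_propr, "X_propr")
  if (length(all_zero)) {
    warn(sprintf("all-zero input(s) to the ensemble: %s", paste(all_zero, collapse = ", ")))
  }
  out <- omega * Xm + (1 - omega) * Xp
  attr(out, "all_zero") <- all_zero
  out
}

#' Infer the TF-target regulatory network
#'
#' Runs the ADMM regression ([solve_admm()]), the proportionality
#' association ([propr_association()]), and their ensemble
#' ([ensemble_weights()]) in one call.
#'
#' @param A Target expression matrix (targets x cells).
#' @param B TF activity matrix (TFs x cells).
#' @param N Binary prior mask (targets x TFs).
#' @param config A [solver_config()].
#' @return A `grn_fit` list: `X_model`, `X_propr`, `X_new`, the underlying
#'   `admm_fit`, and the configuration.
#' @export
infer_grn <- function(A, B, N = NULL, config = solver_config()) {
  fit <- solve_admm(A, B, N, config)
  X_propr <- propr_association(B, A)
  attr(X_propr, "flat_profiles") <- NULL
  X_new <- ensemble_weights(fit$X, X_propr, config$omega)
  structure(list(X_model = fit$X, X_propr = X_propr, X_new = X_new,
                 admm = fit, config = config),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("<grn_fit> %d targets x %d TFs; omega = %.2f; %d nonzero regression edges\n",
              nrow(x$X_new), ncol(x$X_new), x$config$omega, sum(x$X_model != 0)))
  invisible(x)
}

#' @describeIn infer_grn One row per (target, tf) with the three estimates.
#' @param x A `grn_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.grn_fit <- function(x, ...) {
  as_tibble(as.data.frame.table(x$X_new, responseName = "weight",
                                stringsAsFactors = FALSE)) |>
    rename(target = "Var1", tf = "Var2") |>
    mutate(model = as.vector(x$X_model), propr = as.vector(x$X_propr),
           sign = sign(.data$weight)) |>
    arrange(desc(abs(.data$weight)))
}

#' @describeIn infer_grn One-row summary of the fit.
#' @exportS3Method generics::glance
glance.grn_fit <- function(x, ...) {
  mutate(glance(x$admm), omega = x$config$omega)
}

#' ROC evaluation of an inferred network against a reference
#'
#' Entries of `|X|` are ranked and swept as the decision threshold against
#' the binary reference; ties in `|X|` are grouped so that tied entries enter
#' the curve together (equivalently, tied ranks are averaged). The AUC is the
#' area under the resulting TPR/FPR curve by the trapezoidal rule.
#'
#' @param X Inferred weight matrix.
#' @param reference Binary reference matrix of the same shape (must contain
#'   both positive and negative entries).
#' @return A `roc_eval` list: `roc` (tibble `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
evaluate_against_reference <- function(X, reference) {
  if (!all(dim(X) == dim(reference))) abort("X and reference must have the same shape")
  labels <- as.vector(reference)
  if (!all(labels %in% c(0, 1))) abort("reference must be binary")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("reference must contain both positive and negative entries")
  }
  score <- abs(as.vector(X))
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  l <- labels[ord]
  # group tied scores so tied entries cross the threshold together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- tibble(threshold = s[last], tpr = tp[last] / n_pos, fpr = fp[last] / n_neg)
  roc <- bind_rows(tibble(threshold = Inf, tpr = 0, fpr = 0), roc)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc), class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("<roc_eval> AUC = %.4f over %d thresholds\n", x$auc, nrow(x$roc)))
  invisible(x)
}

#' @describeIn evaluate_against_reference ROC curve plot.
#' @param object A `roc_eval`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Robustness of the regression to the regularization parameters
#'
#' For every (lambda1, lambda2) combination on the grid, cells are split into
#' folds, the regression is fit on the training cells, and the held-out
#' residual `||A_test - X B_test||_F` is averaged over folds. A flat residual
#' surface (small coefficient of variation) indicates the inference is
#' robust to the choice of regularization within the grid.
#'
#' @param A,B,N As in [solve_admm()].
#' @param grid_l1 Values of lambda1 (default 30, 40, 50, 60, 70).
#' @param grid_l2 Values of lambda2 (default 5, 10, 15).
#' @param folds Number of cross-validation folds (default 5, >= 2).
#' @param seed Integer seed for the fold split.
#' @param config Base [solver_config()] supplying all other settings.
#' @return Tibble `lambda1`, `lambda2`, `cv_residual` (one row per grid
#'   point), with the fold assignment as attribute `"folds"`.
#' @export
robustness_grid <- function(A, B, N = NULL,
                            grid_l1 = seq(30, 70, by = 10),
                            grid_l2 = c(5, 10, 15),
                            folds = 5, seed = 0, config = solver_config()) {
  if (folds < 2) abort("`folds` must be >= 2")
  n_cells <- ncol(A)
  if (n_cells < folds) abort("need at least as many cells as folds")
  fold_id <- withr::with_seed(seed,
                              sample(rep(seq_len(folds), length.out = n_cells)))
  grid <- crossing(lambda1 = grid_l1, lambda2 = grid_l2)
  res <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (!any(tr) || all(tr)) abort(sprintf("fold %d is degenerate", f))
    A_tr <- A[, tr, drop = FALSE]; B_tr <- B[, tr, drop = FALSE]
    A_te <- A[, !tr, drop = FALSE]; B_te <- B[, !tr, drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      cfg <- config
      cfg$lambda1 <- grid$lambda1[i]
      cfg$lambda2 <- grid$lambda2[i]
      fit <- solve_admm(A_tr, B_tr, N, cfg)
      res[i, f] <- frobenius(A_te - fit$X %*% B_te)
    }
  }
  out <- mutate(grid, cv_residual = rowMeans(res))
  attr(out, "folds") <- fold_id
  out
}
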