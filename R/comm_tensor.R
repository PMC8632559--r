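#' Construct a communication tensor
#'
#' A communication tensor holds, for one condition, the communication
#' probability of every (sender group, receiver group, ligand-receptor pair)
#' triple together with its permutation p-value and pathway annotation. It is
#' stored long as a tibble with columns `condition`, `sender`, `receiver`,
#' `pair`, `pathway`, `ligand`, `receptor`, `prob`, `pval`. Probabilities are
#' in `[0, 1)`; entries whose p-value exceeds `alpha` are zeroed before any
#' comparison analysis so that only significant communication contributes.
#'
#' @param x Data frame with at least `sender`, `receiver`, `pair`, `pathway`,
#'   `prob`, `pval` (optional `ligand`, `receptor`, `condition`).
#' @param condition Condition label (used when `x` lacks the column).
#' @param groups Full ordered set of cell groups (defaults to those present).
#' @param alpha Significance level; probabilities with `pval > alpha` are set
#'   to 0.
#' @return A `comm_tensor` tibble.
#' @export
as_comm_tensor <- function(x, condition = NULL, groups = NULL, alpha = 0.05) {
  x <- as_tibble(x)
  need <- c("sender", "receiver", "pair", "pathway", "prob", "pval")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("communication table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"condition" %in% names(x)) {
    x$condition <- condition %||% "condition1"
  }
  if (!"ligand" %in% names(x)) x$ligand <- NA_character_
  if (!"receptor" %in% names(x)) x$receptor <- NA_character_
  x$ligand <- as.character(x$ligand)
  x$receptor <- as.character(x$receptor)
  if (any(!is.finite(x$prob)) || any(x$prob < 0) || any(x$prob >= 1 + 1e-12)) {
    abort("communication probabilities must be finite and in [0, 1)")
  }
  if (any(x$pval < 0 | x$pval > 1, na.rm = TRUE)) {
    abort("permutation p-values must lie in [0, 1]")
  }
  x$prob[!is.na(x$pval) & x$pval > alpha] <- 0
  x <- x[, c("condition", "sender", "receiver", "pair", "pathway",
             "ligand", "receptor", "prob", "pval")]
  groups <- groups %||% unique(c(x$sender, x$receiver))
  structure(x,
            class = c("comm_tensor", class(tibble())),
            groups = as.character(groups),
            alpha = alpha)
}

#' @export
print.comm_tensor <- function(x, ...) {
  cat(sprintf("<comm_tensor> condition '%s': %d groups, %d LR pairs, %d significant entries\n",
              x$condition[1] %||% "?", length(comm_groups(x)),
              length(unique(x$pair)), sum(x$prob > 0)))
  NextMethod()
}

#' Cell groups of a communication tensor
#'
#' @param ct A `comm_tensor`.
#' @return Character vector of group names (including groups without any
#'   significant communication).
#' @export
comm_groups <- function(ct) {
  attr(ct, "groups") %||% unique(c(ct$sender, ct$receiver))
}

# keep attributes through dplyr verbs used internally
restore_tensor <- function(x, template) {
  structure(as_tibble(x),
            class = class(template),
            groups = attr(template, "groups"),
            alpha = attr(template, "alpha"))
}
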