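# Statistical layer: log-scale one-way ANOVA of remodeling scores against
# the untreated control, with Benjamini-Hochberg FDR control across the
# family of (condition x layer) comparisons.

#' Log-transform positive score values
#'
#' Scores are converted to the (natural) log scale before ANOVA because the
#' between-group variances of raw percent scores differ strongly (the base
#' does not affect F or p; natural log is used so intermediate tables are
#' reproducible).
#'
#' @param values Numeric vector of strictly positive values.
#' @param group_label Optional label used in the error message.
#' @return `log(values)`.
#' @export
log_transform <- function(values, group_label = NULL) {
  if (any(!is.finite(values) | values <= 0))
    stop("cannot log-transform non-positive value",
         if (!is.null(group_label)) paste0(" in group '", group_label, "'"),
         call. = FALSE)
  log(values)
}

#' Classical one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`, with the p-value from the F
#' distribution on `(k - 1, N - k)` degrees of freedom. Computed through
#' [stats::oneway.test()] with `var.equal = TRUE` (no Welch correction by
#' default, matching the plain ANOVA convention after log transform;
#' `welch = TRUE` switches it on).
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor), at least 2 groups with at
#'   least 2 observations each.
#' @param welch Apply the Welch variance correction (off by default).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(values, groups, welch = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw <= 0)
    stop("zero within-group variance: F is degenerate", call. = FALSE)
  ft <- stats::oneway.test(values ~ groups, var.equal = !welch)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values of the step-up procedure controlling the false
#' discovery rate: with p-values sorted ascending,
#' `adj_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1 and returned
#' in the input order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Compare inhibitor conditions against the untreated control
#'
#' For every layer, each condition is tested against the control by one-way
#' ANOVA on log-transformed scores; the Benjamini-Hochberg adjustment is
#' applied across the whole family of (condition x layer) comparisons of the
#' experiment (the family definition is configurable via `family`). Each
#' comparison is flagged `significant` when its raw p is at or below
#' `alpha_sig` (0.01) and `fdr_pass` when its adjusted p is at or below
#' `alpha_fdr` (0.05). The output mirrors the condition-by-layer layout of a
#' per-experiment summary table, with mean and standard error on the
#' original percent scale.
#'
#' @param scores Data.frame with columns `condition`, `layer`,
#'   `score_percent` (replicate fields as rows).
#' @param control Label of the untreated control condition.
#' @param alpha_sig Significance cutoff on the raw p-value.
#' @param alpha_fdr FDR level on the adjusted p-value.
#' @param family `"experiment"` adjusts across all condition x layer
#'   comparisons at once; `"layer"` adjusts within each layer separately.
#' @param log_scale Log-transform before ANOVA (default, recommended).
#' @return Data.frame with one row per (condition, layer): `n`, `mean`, `se`,
#'   `F`, `p`, `p_adj`, `significant`, `fdr_pass`.
#' @export
compare_conditions <- function(scores, control = "untreated",
                               alpha_sig = 0.01, alpha_fdr = 0.05,
                               family = c("experiment", "layer"),
                               log_scale = TRUE) {
  family <- match.arg(family)
  need <- c("condition", "layer", "score_percent")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!control %in% scores$condition)
    stop("control condition '", control, "' not present", call. = FALSE)
  layers <- intersect(c("top", "middle", "bottom"), unique(scores$layer))
  if (!length(layers)) layers <- unique(scores$layer)
  conditions <- setdiff(unique(scores$condition), control)
  rows <- list()
  for (layer in layers) {
    ctrl_v <- scores$score_percent[scores$condition == control &
                                     scores$layer == layer]
    if (length(ctrl_v) < 2L)
      stop("control has fewer than 2 replicates in layer '", layer, "'",
           call. = FALSE)
    for (cond in conditions) {
      v <- scores$score_percent[scores$condition == cond &
                                  scores$layer == layer]
      if (length(v) < 2L) next
      y <- if (log_scale) {
        c(log_transform(ctrl_v, control), log_transform(v, cond))
      } else c(ctrl_v, v)
      g <- rep(c(control, cond), c(length(ctrl_v), length(v)))
      ft <- one_way_anova(y, g)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, layer = layer, n = length(v),
        mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
        F = ft$F, p = ft$p)
    }
  }
  if (!length(rows)) stop("no testable comparisons", call. = FALSE)
  out <- do.call(rbind, rows)
  if (family == "experiment") {
    out$p_adj <- benjamini_hochberg(out$p)
  } else {
    out$p_adj <- NA_real_
    for (layer in unique(out$layer)) {
      sel <- out$layer == layer
      out$p_adj[sel] <- benjamini_hochberg(out$p[sel])
    }
  }
  out$significant <- out$p <= alpha_sig
  out$fdr_pass <- out$p_adj <= alpha_fdr
  out
}
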