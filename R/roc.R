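#' Built-in ROC sweep ranges for the mapped parameters
#'
#' The published sweep: reference IT cutoffs 0-100 % in steps of 2.5 %, and
#' predictor thresholds over 40 steps of 25/40 mV (UV, 0-25 mV), 0.3 mV
#' (BV, 0-12 mV), 2 % (LLS, -32-48 %) and 0.5 mm (WT, -5-15 mm).
#'
#' @return named list of `c(min, max)` ranges; all use `n = 40` steps.
#' @export
emm_roc_ranges <- function() {
  list(it = c(0, 100), uv = c(0, 25), bv = c(0, 12),
       lls = c(-32, 48), wt = c(-5, 15))
}

#' ROC sensitivity/specificity grid over reference cutoffs and thresholds
#'
#' Sweeps a 40 x 40 grid: for each reference cutoff \eqn{t_r} the positive
#' class is `ref >= t_r`; for each predictor threshold \eqn{t_p} the test is
#' positive when `pred <= t_p` (low voltage / shortening indicates disease;
#' set `direction = "ge"` for the opposite sense). Per cutoff, the ROC AUC is
#' the trapezoidal area over the swept (1 - specificity, sensitivity) points
#' with (0,0) and (1,1) anchors. The optimal operating point is the Youden-J
#' maximum (J = sens + spec - 1) at the cutoff with the largest AUC; ties
#' break toward the lower cutoff and lower threshold.
#'
#' Cutoffs with an empty positive or negative class are left missing; an
#' error is raised only if every cutoff is degenerate.
#'
#' @param pairs tibble/data frame with numeric columns `pred` and `ref`.
#' @param pred_range `c(min, max)` predictor sweep range.
#' @param ref_range `c(min, max)` reference sweep range.
#' @param n grid resolution per axis (default 40). Reference cutoffs are
#'   `min + step * (0:(n-1))`, predictor thresholds `min + step * (1:n)`,
#'   with `step = (max - min)/n`.
#' @param direction `"le"` (test-positive when `pred <= t`) or `"ge"`.
#' @return An object of class `roc_grid` with elements `ref_cutoffs`,
#'   `pred_thresholds`, `sens`, `spec` (n x n matrices), `auc` (per cutoff)
#'   and `best` (a one-row tibble).
#' @export
roc_grid <- function(pairs, pred_range, ref_range, n = 40,
                     direction = c("le", "ge")) {
  direction <- match.arg(direction)
  stopifnot(all(c("pred", "ref") %in% names(pairs)))
  ok <- is.finite(pairs$pred) & is.finite(pairs$ref)
  pred <- pairs$pred[ok]; ref <- pairs$ref[ok]
  if (length(pred) < 2) {
    abort("need at least 2 complete (pred, ref) pairs", class = "emmfuse_validation_error")
  }
  step_r <- diff(ref_range) / n
  step_p <- diff(pred_range) / n
  ref_cutoffs <- ref_range[1] + step_r * (0:(n - 1))
  pred_thresholds <- pred_range[1] + step_p * (1:n)

  sens <- spec <- matrix(NA_real_, n, n)
  auc <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    pos <- ref >= ref_cutoffs[r]
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) next
    for (p in seq_len(n)) {
      test_pos <- if (direction == "le") pred <= pred_thresholds[p] else pred >= pred_thresholds[p]
      sens[r, p] <- sum(test_pos & pos) / n_pos
      spec[r, p] <- sum(!test_pos & !pos) / n_neg
    }
    fpr <- c(0, sort(1 - spec[r, ]), 1)
    tpr <- c(0, sens[r, order(1 - spec[r, ])], 1)
    auc[r] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  if (all(is.na(auc))) {
    abort("every reference cutoff has an empty class; cannot build ROC grid",
          class = "emmfuse_validation_error")
  }
  r_best <- which.max(auc)
  j <- sens[r_best, ] + spec[r_best, ] - 1
  p_best <- which.max(j)
  best <- tibble::tibble(
    ref_cutoff = ref_cutoffs[r_best],
    pred_threshold = pred_thresholds[p_best],
    sens = sens[r_best, p_best],
    spec = spec[r_best, p_best],
    auc = auc[r_best]
  )
  structure(
    list(ref_cutoffs = ref_cutoffs, pred_thresholds = pred_thresholds,
         sens = sens, spec = spec, auc = auc, best = best,
         direction = direction, n_pairs = length(pred)),
    class = "roc_grid"
  )
}

#' @export
print.roc_grid <- function(x, ...) {
  cat(sprintf("<roc_grid> %d pairs, %d x %d grid\n", x$n_pairs,
              length(x$ref_cutoffs), length(x$pred_thresholds)))
  cat(sprintf("  best: ref >= %g, pred %s %.3g, AUC %.3f (sens %.2f, spec %.2f)\n",
              x$best$ref_cutoff, if (x$direction == "le") "<=" else ">=",
              x$best$pred_threshold, x$best$auc, x$best$sens, x$best$spec))
  invisible(x)
}

#' @rdname roc_grid
#' @param x a `roc_grid`.
#' @param ... unused.
#' @method tidy roc_grid
#' @export
tidy.roc_grid <- function(x, ...) {
  n <- length(x$ref_cutoffs)
  tibble::tibble(
    ref_cutoff = rep(x$ref_cutoffs, times = length(x$pred_thresholds)),
    pred_threshold = rep(x$pred_thresholds, each = n),
    sens = as.vector(x$sens),
    spec = as.vector(x$spec)
  )
}

#' @rdname roc_grid
#' @method glance roc_grid
#' @export
glance.roc_grid <- function(x, ...) {
  tibble::tibble(x$best, n_pairs = x$n_pairs, direction = x$direction)
}

#' @rdname roc_grid
#' @param object a `roc_grid`.
#' @method autoplot roc_grid
#' @export
autoplot.roc_grid <- function(object, ...) {
  r_best <- which.max(object$auc)
  df <- tibble::tibble(
    fpr = c(0, 1 - object$spec[r_best, ], 1),
    tpr = c(0, object$sens[r_best, ], 1)
  )
  df <- df[order(df$fpr, df$tpr), ]
  op <- object$best
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_path() +
    geom_point(data = tibble::tibble(fpr = 1 - op$spec, tpr = op$sens),
               colour = "red", size = 2) +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC at reference cutoff >= %g (AUC %.2f)",
                         op$ref_cutoff, op$auc)) +
    coord_equal() +
    theme_minimal()
}

#' Pair registered EMM points with a mesh reference channel
#'
#' Each included point is paired with the value of the named channel at its
#' closest mesh vertex; pairs with a missing channel value are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param emm registered, filtered EMM tibble.
#' @param mesh `surface_mesh` carrying the channel.
#' @param channel channel name (e.g. `"it"`, `"wt"`).
#' @return tibble `id, uv, bv, lls, ref` (one row per surviving point), with
#'   attribute `n_dropped`.
#' @export
pair_points_with_reference <- function(emm, mesh, channel = "it") {
  ch <- mesh$channels[[channel]]
  if (is.null(ch)) {
    abort(sprintf("mesh has no '%s' channel", channel),
          class = "emmfuse_validation_error")
  }
  inc <- if ("included" %in% names(emm)) emm$included else rep(TRUE, nrow(emm))
  sub <- emm[inc, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort("no included points to pair", class = "emmfuse_validation_error")
  }
  nn <- nearest_vertex(as_point_matrix(sub), mesh)
  ref <- ch[nn]
  keep <- !is.na(ref)
  if (!any(keep)) {
    abort("all paired reference values are missing", class = "emmfuse_validation_error")
  }
  out <- tibble::tibble(id = sub$id, uv = sub$uv, bv = sub$bv,
                        lls = sub$lls, ref = ref)[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
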