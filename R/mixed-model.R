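#' Variance explained by a covariate in a random-intercept mixed model
#'
#' Fits two Gaussian random-intercept models by maximum likelihood (ML, not
#' REML, so the variance components of the two fits are comparable): a null
#' model `outcome ~ 1 + (1 | group)` and a full model adding the fixed
#' covariate. With residual (within-group) variance \eqn{\sigma^2} and
#' random-intercept (between-group) variance \eqn{\tau_{00}} from each fit,
#' the proportion of outcome variance explained by the covariate is
#' \deqn{R^2 = 1 - \frac{\sigma^2_{full} + \tau_{00,full}}
#'   {\sigma^2_{null} + \tau_{00,null}}.}
#'
#' A singular full fit (between-group variance estimated at zero) proceeds
#' with \eqn{\tau_{00} = 0} and is flagged.
#'
#' @param data data frame with the outcome, covariate and grouping columns.
#' @param outcome,covariate,group column names (strings).
#' @return An object of class `mixed_model_r2`: `sigma2_null`, `tau00_null`,
#'   `sigma2_full`, `tau00_full`, `r2`, `singular`, `n_groups`, `n_obs`.
#' @export
mixed_model_r2 <- function(data, outcome, covariate, group = "animal") {
  for (col in c(outcome, covariate, group)) {
    if (!col %in% names(data)) {
      abort(sprintf("column '%s' not found", col), class = "emmfuse_format_error")
    }
  }
  data <- data[stats::complete.cases(data[c(outcome, covariate, group)]), ]
  tab <- table(data[[group]])
  if (length(tab) < 3) {
    abort("need at least 3 groups", class = "emmfuse_validation_error")
  }
  if (any(tab < 2)) {
    abort("every group needs at least 2 observations", class = "emmfuse_validation_error")
  }
  f_null <- stats::as.formula(sprintf("%s ~ 1 + (1 | %s)", outcome, group))
  f_full <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", outcome, covariate, group))
  fit_null <- suppressMessages(lme4::lmer(f_null, data = data, REML = FALSE))
  fit_full <- suppressMessages(
    withCallingHandlers(
      lme4::lmer(f_full, data = data, REML = FALSE),
      warning = function(w) invokeRestart("muffleWarning")
    )
  )
  if (!is.finite(stats::logLik(fit_full)) || !is.finite(stats::logLik(fit_null))) {
    abort("non-finite likelihood in mixed-model fit", class = "emmfuse_error")
  }
  vc <- function(fit) {
    v <- lme4::VarCorr(fit)
    list(sigma2 = attr(v, "sc")^2, tau00 = as.numeric(v[[group]][1, 1]))
  }
  vn <- vc(fit_null); vf <- vc(fit_full)
  r2 <- 1 - (vf$sigma2 + vf$tau00) / (vn$sigma2 + vn$tau00)
  structure(
    list(sigma2_null = vn$sigma2, tau00_null = vn$tau00,
         sigma2_full = vf$sigma2, tau00_full = vf$tau00,
         r2 = r2,
         singular = lme4::isSingular(fit_full) || lme4::isSingular(fit_null),
         n_groups = length(tab), n_obs = nrow(data),
         outcome = outcome, covariate = covariate),
    class = "mixed_model_r2"
  )
}

#' @export
print.mixed_model_r2 <- function(x, ...) {
  cat(sprintf("<mixed_model_r2> %s ~ %s: R2 = %.1f%%%s\n",
              x$outcome, x$covariate, 100 * x$r2,
              if (x$singular) " (singular fit)" else ""))
  cat(sprintf("  null: sigma2 %.3g, tau00 %.3g; full: sigma2 %.3g, tau00 %.3g\n",
              x$sigma2_null, x$tau00_null, x$sigma2_full, x$tau00_full))
  invisible(x)
}

#' @rdname mixed_model_r2
#' @param x a `mixed_model_r2`.
#' @param ... unused.
#' @method tidy mixed_model_r2
#' @export
tidy.mixed_model_r2 <- function(x, ...) {
  tibble::tibble(
    model = rep(c("null", "full"), each = 2),
    component = rep(c("sigma2", "tau00"), times = 2),
    estimate = c(x$sigma2_null, x$tau00_null, x$sigma2_full, x$tau00_full)
  )
}

#' @rdname mixed_model_r2
#' @method glance mixed_model_r2
#' @export
glance.mixed_model_r2 <- function(x, ...) {
  tibble::tibble(r2 = x$r2, singular = x$singular,
                 n_groups = x$n_groups, n_obs = x$n_obs)
}
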