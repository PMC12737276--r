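# Statistical comparison layer: random-intercept linear mixed models for
# before/after metric contrasts (REML, Wald z), and the Benjamini-Hochberg
# step-up FDR correction shared with the coherence module.

#' Fit the before/after random-intercept model for one metric
#'
#' REML fit of `value ~ time + (1 | mouse_id)` with `time` coded
#' Before = reference, so the reported effect is After minus Before.
#' With a single mouse the random intercept is unidentifiable and the fit
#' degrades (with a warning) to an ordinary linear model.
#'
#' @param table data.frame with columns `mouse_id`, `time` (levels
#'   `Before`/`After`) and `value`.
#' @return an `effect_estimate`: list with `beta`, `se`, `z`, `p`, `ci95`,
#'   `n_obs`, `n_groups`, `method`.
#' @export
fit_lmm <- function(table) {
  need <- c("mouse_id", "time", "value")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table) < 2) stop("need at least 2 observations")
  if (!all(table$time %in% c("Before", "After")))
    stop("time must have levels Before/After")
  if (stats::var(table$value) == 0) stop("metric is constant: nothing to fit")
  table$time <- factor(table$time, levels = c("Before", "After"))
  ng <- length(unique(table$mouse_id))
  if (ng < 2) {
    warning("single mouse: random intercept unidentifiable, using ordinary least squares")
    fit <- stats::lm(value ~ time, data = table)
    co <- summary(fit)$coefficients["timeAfter", ]
    beta <- co[1]; se <- co[2]
    method <- "lm"
  } else {
    fit <- lme4::lmer(value ~ time + (1 | mouse_id), data = table, REML = TRUE)
    co <- summary(fit)$coefficients["timeAfter", ]
    beta <- co[1]; se <- co[2]
    method <- "lmer-REML"
  }
  z <- beta / se
  structure(list(beta = unname(beta), se = unname(se), z = unname(z),
                 p = 2 * stats::pnorm(-abs(z)),
                 ci95 = unname(beta + c(-1, 1) * 1.96 * se),
                 n_obs = nrow(table), n_groups = ng, method = method),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "beta = %.4g +/- %.3g SE, z = %.3f, 95%% CI [%.4g, %.4g], p = %.3g (n = %d, %s)\n",
    x$beta, x$se, x$z, x$ci95[1], x$ci95[2], x$p, x$n_obs, x$method))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' For sorted p-values `p_(1) <= ... <= p_(m)`, the adjusted value of
#' `p_(k)` is `min(1, min_{i >= k} m p_(i) / i)`; the output is monotone in
#' the sorted order and never below the raw value.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[order(o)]
}

#' Fit the mixed model for every metric in a long table
#'
#' @param table data.frame with `mouse_id`, `time`, `metric`, `value`.
#' @return data.frame with one row per metric: `metric`, `beta`, `se`,
#'   `z`, `ci_lo`, `ci_hi`, `p`, `n_obs`.
#' @export
effects_table <- function(table) {
  out <- lapply(split(table, table$metric), function(g) {
    e <- fit_lmm(g)
    data.frame(metric = g$metric[1], beta = e$beta, se = e$se, z = e$z,
               ci_lo = e$ci95[1], ci_hi = e$ci95[2], p = e$p,
               n_obs = e$n_obs, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
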