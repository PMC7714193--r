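#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the fixed effects of a mixed-model fit
#'
#' @param x An `ln_fit`.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.ln_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- z_crit(conf_level)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    conf.low = unname(x$coefficients - z * se),
    conf.high = unname(x$coefficients + z * se))
}

#' One-row model summary
#'
#' @param x An `ln_fit`.
#' @param ... Unused.
#' @return A tibble with `nobs`, `logLik`, `AIC`, `df`, `family`,
#'   `random_structure`, `estimation`, `converged`, `singular`.
#' @export
glance.ln_fit <- function(x, ...) {
  ll <- logLik(x$model)
  tibble::tibble(
    nobs = x$n_obs,
    logLik = as.numeric(ll),
    AIC = AIC(x$model),
    df = attr(ll, "df"),
    family = x$spec$family,
    random_structure = x$spec$random,
    estimation = x$estimation,
    converged = x$converged,
    singular = x$singular)
}

#' Tidy a permutation-test result
#'
#' @param x An `islandiv_perm`.
#' @param ... Unused.
#' @return A one-row tibble with `observed`, `p_value`, `n_perm`, `tails`,
#'   `null_mean`, `null_q95`.
#' @export
tidy.islandiv_perm <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    p_value = x$p_value,
    n_perm = x$n_perm,
    tails = x$tails,
    null_mean = mean(x$null_values),
    null_q95 = unname(quantile(x$null_values, 0.95)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest-style plot of back-transformed land-use effects
#'
#' @param object An effects tibble from [percent_change_sqrt()] or
#'   [percent_change_log()] (rows from both can be combined with a `channel`
#'   column).
#' @param ... Unused.
#' @return A ggplot: percentage change versus baseline with asymmetric
#'   confidence bars, by land use and status.
#' @export
autoplot.islandiv_effects <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$land_use <- land_use_factor(df$land_use)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$land_use, y = .data$percent_change,
    colour = if ("status" %in% names(df)) .data$status else NULL)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "Change vs PriMin (%)", colour = NULL) +
    ggplot2::theme_minimal()
  if ("channel" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~channel, scales = "free_y")
  }
  p
}

#' Plot similarity contrasts versus the PriMin-PriMin baseline
#'
#' @param x A tibble from [similarity_contrast_table()].
#' @param ... Unused.
#' @return A ggplot of back-transformed similarity per contrast and status;
#'   unreliable contrasts (too few studies) are shown hollow.
#' @export
plot_similarity_contrasts <- function(x, ...) {
  df <- tibble::as_tibble(x)
  df <- df[!is.na(df$similarity), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$contrast, y = .data$similarity, colour = .data$status,
    shape = .data$reliable)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline_similarity,
                                     colour = .data$status),
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = NULL, y = "Compositional similarity",
                  colour = NULL, shape = ">= 3 studies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
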