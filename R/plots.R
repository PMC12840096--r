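#' Plot gene-level calls
#'
#' Posterior mean lCNR with credible intervals per gene, colored by call,
#' with dashed lines at the effect-size thresholds \eqn{\pm\log T}.
#'
#' @param object a `cnv_calls` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_calls <- function(object, ...) {
  cfg <- attr(object, "call_config")
  df <- as_tibble(object) |> dplyr::filter(!is.na(.data$mean_lcnr))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$mean_lcnr,
                                        color = .data$call)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "posterior mean lCNR (90% CrI)",
                  color = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(cfg))
    p <- p + ggplot2::geom_hline(
      yintercept = c(-1, 1) * log(cfg$ratio_threshold),
      linetype = "dashed", linewidth = 0.3)
  p
}

#' @export
plot.cnv_calls <- function(x, ...) print(autoplot(x, ...))

#' Plot the thermodynamic-integration path
#'
#' Per-temperature expected log likelihood \eqn{\hat\mu_\beta} against the
#' inverse temperature \eqn{\beta}, with Monte-Carlo error bars; the area
#' under this curve is the log evidence.
#'
#' @param object an `evidence_estimate`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.evidence_estimate <- function(object, ...) {
  ggplot2::ggplot(object$rungs,
                  ggplot2::aes(x = .data$beta, y = .data$mean_loglik)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_loglik - 2 * .data$se,
                                      ymax = .data$mean_loglik + 2 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(beta),
                  y = expression(hat(mu)[beta] == E[beta] * "[log p(x|" * theta * ")]"),
                  subtitle = sprintf("log Z = %.2f (MC se %.2f)",
                                     object$log_evidence, object$se)) +
    ggplot2::theme_minimal()
}

#' @export
plot.evidence_estimate <- function(x, ...) print(autoplot(x, ...))

#' Plot posterior gene-level lCNR densities
#'
#' @param object a `cnv_posterior`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_posterior <- function(object, ...) {
  mu_cols <- paste0("mu[", object$gene, "]")
  df <- object$draws |>
    dplyr::select(dplyr::all_of(mu_cols)) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "gene", values_to = "mu") |>
    dplyr::mutate(gene = sub("^mu\\[(.*)\\]$", "\\1", .data$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = expression(mu[g] ~ "(gene-level lCNR)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.cnv_posterior <- function(x, ...) print(autoplot(x, ...))
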