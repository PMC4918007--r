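# diagnostic ggplot2 methods

#' @export
autoplot.relative_warps <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis,
                                  y = .data$variance_fraction,
                                  fill = .data$retained)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "relative warp", y = "variance fraction",
                  title = "Shape variance by relative warp") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.divergence_vector <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$site_id, y = .data$score,
                               colour = .data$sulfidic)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = sprintf("divergence score (%s term)", object$term),
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pairwise_fst <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object$theta, rownames = "site_a"),
    -"site_a", names_to = "site_b", values_to = "theta"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$site_a, .data$site_b,
                                  fill = .data$theta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "F_ST") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatterplots of the divergence summary
#'
#' One panel per headline comparison: life-history vs morphological
#' divergence, combined phenotypic divergence vs F_ST, and vs H2S.
#'
#' @param object A `divergence_summary`.
#' @param ... Unused.
#' @export
autoplot.divergence_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$table[, c("system_id", "phen_pc1", "fst_nearest", "h2s_um")],
    c("fst_nearest", "h2s_um"), names_to = "axis", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$phen_pc1)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "phenotypic divergence (PC1)") +
    ggplot2::theme_minimal()
}
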