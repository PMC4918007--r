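# broom-style tidiers for the fitted objects

#' @export
tidy.mglm_fit <- function(x, ...) x$term_table

#' @export
glance.mglm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_responses = ncol(x$Y), dfe = x$dfe,
                 rank = x$rank,
                 n_terms = nrow(x$term_table))
}

#' @export
tidy.divergence_vector <- function(x, ...) {
  tibble::tibble(response = names(x$coefficients),
                 coefficient = as.numeric(x$coefficients))
}

#' @export
glance.divergence_vector <- function(x, ...) {
  tibble::tibble(term = x$term, eigenvalue = x$eigenvalue,
                 n_scored = nrow(x$scores), orientation = x$orientation)
}

#' @export
tidy.relative_warps <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$variance_fractions,
                 retained = seq_along(x$eigenvalues) <= x$n_keep)
}

#' @export
glance.relative_warps <- function(x, ...) {
  tibble::tibble(n_specimens = nrow(x$scores), n_keep = x$n_keep,
                 variance_retained =
                   sum(x$variance_fractions[seq_len(x$n_keep)]))
}

#' @export
tidy.pairwise_fst <- function(x, ...) x$pairs

#' @export
tidy.divergence_summary <- function(x, ...) x$correlations

#' @export
glance.divergence_summary <- function(x, ...) {
  tibble::tibble(n_systems = nrow(x$table),
                 pc1_eigenvalue = x$pca$eigenvalue,
                 pc1_variance_fraction = x$pca$variance_fraction)
}

#' @export
tidy.pipeline_report <- function(x, ...) x$correlations
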