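# Model pruning, site-level nested tests, canonical divergence vectors,
# projections, estimated marginal means, and the post-hoc ANCOVA.

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Stepwise pruning of non-significant interaction terms
#'
#' Repeatedly removes the highest-order interaction with the largest
#' p-value above `alpha`, refitting after each removal. A non-significant
#' interaction is retained when a higher-order interaction still in the
#' model involves all of its variables and is itself significant
#' (`p < alpha`). Main effects, covariates, and the site term are never
#' dropped.
#'
#' @param fit An `mglm_fit`.
#' @param alpha Retention threshold (default 0.1).
#' @return The refitted `mglm_fit` on the pruned specification (access the
#'   pruned model as `$spec`).
#' @export
prune_model <- function(fit, alpha = 0.1) {
  stopifnot(inherits(fit, "mglm_fit"))
  repeat {
    tt <- fit$term_table
    inter <- tt$term[tt$term %in% fit$spec$interactions]
    if (length(inter) == 0) break
    info <- tibble::tibble(
      term = inter,
      order = vapply(inter, function(t) length(term_vars(t)), integer(1)),
      p = tt$p_value[match(inter, tt$term)]
    )
    cand <- info[info$p > alpha, ]
    if (nrow(cand) == 0) break
    cand <- cand[order(-cand$order, -cand$p), ]
    dropped <- FALSE
    for (i in seq_len(nrow(cand))) {
      tm <- cand$term[i]
      vars <- term_vars(tm)
      protectors <- info$term[info$order > cand$order[i] &
                                info$p < alpha]
      protected <- any(vapply(protectors, function(pt)
        all(vars %in% term_vars(pt)), logical(1)))
      if (!protected) {
        spec <- fit$spec
        spec$interactions <- setdiff(spec$interactions, tm)
        fit <- fit_mglm(fit$data, spec)
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  fit
}

#' Site-level nested test for between-site fixed effects
#'
#' The field design treats site (nested in clade x habitat) as the unit of
#' replication for the clade, habitat, and clade x habitat effects. This
#' test aggregates the (covariate-adjusted) responses to site mean vectors
#' and runs a MANOVA of `clade * habitat` on them, so each effect is tested
#' against site-to-site variation within cells -- a documented site-means
#' approximation of the mixed-model REML/Kenward-Roger F-test. In balanced
#' univariate designs the statistic reduces to the classical nested-ANOVA
#' ratio `MS_term / MS_site(nested)` with denominator df
#' `n_sites - n_cells`.
#'
#' @param fit An `mglm_fit` whose spec has a site term.
#' @param term One of the between-site terms, e.g. `"clade"`, `"h2s"`, or
#'   `"clade:h2s"` (names as in the spec's factors).
#' @return A one-row tibble like a `term_table` row, with `approx =
#'   "site-means"`. Warns (and returns `NA` statistics) when every cell has
#'   a single site, leaving no site-level error.
#' @export
site_level_test <- function(fit, term) {
  stopifnot(inherits(fit, "mglm_fit"))
  spec <- fit$spec
  if (!isTRUE(spec$site_term)) stop("model has no site term")
  vars <- term_vars(term)
  if (!all(vars %in% spec$nest_within)) {
    stop("term must involve only the nesting factors: ",
         paste(spec$nest_within, collapse = ", "))
  }
  # covariate-adjust individual responses with the full-model coefficients
  y <- fit$Y
  des <- fit$design
  for (v in spec$covariates) {
    tid <- des$terms[[v]]$id
    cols <- which(des$assign == tid)
    cov_x <- des$x[, cols, drop = FALSE]
    cov_x <- sweep(cov_x, 2, colMeans(cov_x))
    y <- y - cov_x %*% fit$B[cols, , drop = FALSE]
  }
  d <- fit$data
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cbind(d[, c(spec$site_var,
                                                  spec$nest_within)],
                                            as.data.frame(y))),
                    dplyr::across(dplyr::all_of(c(spec$site_var,
                                                  spec$nest_within)))),
    dplyr::across(dplyr::all_of(colnames(y)), mean), .groups = "drop"
  )
  cells <- do.call(paste, c(lapply(spec$nest_within,
                                   function(v) as.character(agg[[v]])),
                            sep = "*"))
  if (length(unique(cells)) == nrow(agg)) {
    warning("every clade x habitat cell holds a single site; ",
            "term untestable at site level")
    return(tibble::tibble(term = term, wilks = NA_real_, f = NA_real_,
                          df1 = NA_real_, df2 = NA_real_,
                          p_value = NA_real_, partial_eta_sq = NA_real_,
                          approx = "site-means"))
  }
  site_spec <- mglm_spec(
    dependents = colnames(y), factors = spec$nest_within,
    covariates = character(),
    interactions = if (length(spec$nest_within) >= 2) {
      apply(combn(spec$nest_within, 2), 2, paste, collapse = ":")
    } else character(),
    site_term = FALSE
  )
  sfit <- fit_mglm(agg, site_spec)
  row <- sfit$term_table[sfit$term_table$term == term, ]
  if (nrow(row) == 0) stop("term not found in site-level model: ", term)
  row$relative_variance <- NULL
  row$approx <- "site-means"
  row
}

#' Canonical divergence vector for a model term
#'
#' The first eigenvector of `E^-1 H` for the focal term: the linear
#' combination of dependent variables showing the greatest difference
#' between the term's groups while controlling for the other model terms.
#' Coefficients are unit-norm and oriented so the pooled mean score of
#' sulfidic individuals is at least that of non-sulfidic individuals.
#' Individual scores are the responses adjusted for the covariates and the
#' non-focal main effects (allometry, developmental stage, clade, sex)
#' projected on the coefficients. Terms that themselves carry habitat-linked
#' between-site variation -- interactions involving the focal factor and the
#' nested site block -- are deliberately not removed: residualizing on them
#' would absorb every between-system difference in divergence magnitude and
#' collapse the per-system scores the integration stage consumes.
#'
#' @param fit An `mglm_fit`.
#' @param term Focal term (default `"h2s"`, the habitat factor).
#' @param orient Logical column of `fit$data` defining the positive pole
#'   (default `"sulfidic"`); `NULL` skips orientation.
#' @return An object of class `divergence_vector`: `coefficients`,
#'   `scores` (tibble with metadata and `score`), `eigenvalue`, `term`,
#'   plus the stored adjustment needed by [project_scores()].
#' @export
divergence_vector <- function(fit, term = "h2s", orient = "sulfidic") {
  stopifnot(inherits(fit, "mglm_fit"))
  if (!term %in% names(fit$design$terms)) {
    stop("term not in fitted model: ", term)
  }
  h <- fit$H[[term]]
  ev <- tryCatch(eigen(solve(fit$E, h)), error = function(e) {
    stop("singular error SSCP: cannot form E^-1 H (", conditionMessage(e), ")")
  })
  vals <- Re(ev$values)
  v <- Re(ev$vectors[, which.max(vals)])
  v <- v / vec_norm(v)

  focal_vars <- term_vars(term)
  adj_terms <- c(fit$spec$covariates, setdiff(fit$spec$factors, focal_vars))
  adj_ids <- c(0L, vapply(adj_terms, function(nm) fit$design$terms[[nm]]$id,
                          integer(1)))
  keep_cols <- fit$design$assign %in% adj_ids
  xr <- fit$design$x[, keep_cols, drop = FALSE]
  br <- qr.coef(qr(xr), fit$Y)
  y_adj <- fit$Y - xr %*% br
  scores <- as.numeric(y_adj %*% v)

  meta_cols <- intersect(c("individual_id", "specimen_id", "site_id",
                           "system_id", "clade", "genus", "sulfidic",
                           "h2s_um", "sex"), names(fit$data))
  if (!is.null(orient)) {
    grp <- fit$data[[orient]]
    if (is.null(grp)) stop("orientation column not found: ", orient)
    if (mean(scores[grp]) < mean(scores[!grp])) {
      v <- -v
      scores <- -scores
    }
  }
  names(v) <- fit$spec$dependents
  structure(list(
    coefficients = v,
    scores = dplyr::bind_cols(fit$data[, meta_cols],
                              tibble::tibble(score = scores)),
    eigenvalue = max(vals),
    term = term,
    orientation = if (is.null(orient)) NA_character_ else orient,
    dependents = fit$spec$dependents,
    spec = fit$spec,
    reduced_b = br,
    adjust_ids = adj_ids,
    design_template = fit$design,
    train_center = colMeans(fit$Y)
  ), class = "divergence_vector")
}

#' @export
print.divergence_vector <- function(x, ...) {
  cat(sprintf("<divergence_vector for term '%s' (%d responses)>\n",
              x$term, length(x$coefficients)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Project individuals onto a divergence vector
#'
#' With `adjust = "training"` the new data must carry the model variables;
#' the training model's non-focal coefficients are applied so the new
#' responses receive exactly the adjustment the training scores did
#' (projecting the training individuals reproduces their stored scores).
#' With `adjust = "center"` only the training grand mean is removed -- the
#' mode used for a second genus whose sites and clades the training model
#' never saw.
#'
#' @param vec A `divergence_vector`.
#' @param new_data Data frame with the response columns (and, for
#'   `"training"`, the model variables).
#' @param adjust `"training"` or `"center"`.
#' @return Numeric vector of scores.
#' @export
project_scores <- function(vec, new_data,
                           adjust = c("training", "center")) {
  adjust <- match.arg(adjust)
  new_data <- tibble::as_tibble(new_data)
  missing_resp <- setdiff(vec$dependents, names(new_data))
  if (length(missing_resp)) {
    stop("new data lacks response column(s): ",
         paste(missing_resp, collapse = ", "))
  }
  y <- as.matrix(new_data[, vec$dependents])
  if (adjust == "center") {
    return(as.numeric(sweep(y, 2, vec$train_center) %*% vec$coefficients))
  }
  des <- build_design(new_data, vec$spec, template = vec$design_template)
  xr <- des$x[, vec$design_template$assign %in% vec$adjust_ids, drop = FALSE]
  as.numeric((y - xr %*% vec$reduced_b) %*% vec$coefficients)
}

#' Estimated marginal means for a factor term
#'
#' Model-predicted response per level of the focal factor at fixed
#' covariate values (their observed means by default), averaged over the
#' other factors with equal weights -- under sum-to-zero coding this zeroes
#' every non-focal factor block, including the nested site block. Standard
#' errors come from the per-response residual variance and `(X'X)^-1`.
#'
#' @param fit An `mglm_fit`.
#' @param term A single factor named in the spec.
#' @param at Named list/vector of covariate values; defaults to covariate
#'   means. Values outside the observed range trigger a warning.
#' @return A tibble: `response, level, emm, se` plus the covariate setting.
#' @export
estimated_marginal_means <- function(fit, term, at = NULL) {
  stopifnot(inherits(fit, "mglm_fit"))
  spec <- fit$spec
  if (!term %in% spec$factors) stop("term must be a fixed factor")
  vb <- fit$design$var_blocks
  levels <- vb[[term]]$levels
  at_vals <- vapply(spec$covariates, function(v) {
    val <- if (!is.null(at) && v %in% names(at)) at[[v]] else
      mean(fit$data[[v]])
    rng <- range(fit$data[[v]])
    if (val < rng[1] || val > rng[2]) {
      warning("covariate ", v, " set outside its observed range")
    }
    val
  }, numeric(1))

  xtx_inv <- chol2inv(chol(crossprod(fit$design$x)))
  sigma2 <- diag(fit$E) / fit$dfe

  rows <- purrr::map(seq_along(levels), function(li) {
    # per-variable row vectors under the EMM averaging rules
    var_row <- function(v) {
      if (v %in% spec$covariates) {
        matrix(at_vals[[v]], 1, 1)
      } else if (v == term) {
        vb[[v]]$contrasts[li, , drop = FALSE]
      } else {
        matrix(0, 1, ncol(vb[[v]]$mat))
      }
    }
    x_row <- matrix(1, 1, 1)
    for (v in spec$covariates) x_row <- cbind(x_row, var_row(v))
    for (v in spec$factors) x_row <- cbind(x_row, var_row(v))
    for (tm in spec$interactions) {
      vars <- term_vars(tm)
      x_row <- cbind(x_row, interact_cols(lapply(vars, var_row)))
    }
    if ("site" %in% names(fit$design$terms)) {
      x_row <- cbind(x_row, matrix(0, 1, fit$design$terms$site$dfh))
    }
    pred <- as.numeric(x_row %*% fit$B)
    se <- sqrt(as.numeric(x_row %*% xtx_inv %*% t(x_row)) * sigma2)
    tibble::tibble(response = colnames(fit$Y), level = levels[li],
                   emm = pred, se = se)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "at") <- at_vals
  out
}

#' Post-hoc ANCOVA of life-history scores on shape scores by site
#'
#' Tests whether the within-site slope of life-history divergence scores on
#' body-shape divergence scores differs among sites: the interaction term
#' in `lh ~ site * shape`. All F ratios use the full-model residual mean
#' square as denominator. Sites with fewer than 3 individuals are excluded
#' with a warning.
#'
#' @param lh_scores,shape_scores Numeric vectors (same individuals).
#' @param site Site labels.
#' @return A tibble: `term, df1, df2, f, p_value` for site, the covariate,
#'   and site x covariate.
#' @export
ancova_slopes <- function(lh_scores, shape_scores, site) {
  d <- tibble::tibble(lh = lh_scores, shape = shape_scores,
                      site = factor(site))
  counts <- table(d$site)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning("excluding site(s) with < 3 individuals: ",
            paste(small, collapse = ", "))
    d <- droplevels(d[!d$site %in% small, ])
  }
  if (nlevels(d$site) < 2) stop("need at least two usable sites")
  sse <- function(fm) sum(stats::resid(fm)^2)
  m_full <- stats::lm(lh ~ site * shape, data = d)
  m_add <- stats::lm(lh ~ site + shape, data = d)
  m_site <- stats::lm(lh ~ site, data = d)
  m_shape <- stats::lm(lh ~ shape, data = d)
  df_full <- stats::df.residual(m_full)
  mse <- sse(m_full) / df_full
  k <- nlevels(d$site)
  comp <- list(
    site = c(sse(m_shape) - sse(m_add), k - 1),
    shape = c(sse(m_site) - sse(m_add), 1),
    `site:shape` = c(sse(m_add) - sse(m_full), k - 1)
  )
  dplyr::bind_rows(purrr::imap(comp, function(v, nm) {
    f <- (v[1] / v[2]) / mse
    tibble::tibble(term = nm, df1 = v[2], df2 = df_full, f = f,
                   p_value = pf(f, v[2], df_full, lower.tail = FALSE))
  }))
}
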