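# Multivariate linear model with Type-III SSCPs on a hand-built sum-to-zero
# design. The nested random site term of the field design -- site within
# clade x habitat -- is coded as a fixed block of within-cell contrasts;
# between-site fixed effects can then be re-tested against site-level
# variation with site_level_test().

#' Specify a (M)AN(C)OVA model
#'
#' @param dependents Character vector of response columns.
#' @param factors Character vector of fixed factors (e.g. clade, sex,
#'   habitat flag).
#' @param covariates Character vector of numeric covariates.
#' @param interactions `"auto"` for all 2- and 3-way interactions among the
#'   factors plus covariate-by-factor 2-ways, a character vector of terms
#'   like `"clade:h2s"`, or `NULL` for none.
#' @param site_term Include a site-within-cell block (`site_var` nested in
#'   the crossing of `nest_within`)?
#' @param site_var Column naming the site.
#' @param nest_within Factors whose crossing defines the nesting cells.
#' @return A list with class `mglm_spec`.
#' @export
mglm_spec <- function(dependents, factors, covariates = character(),
                      interactions = "auto", site_term = TRUE,
                      site_var = "site_id", nest_within = NULL) {
  if (identical(interactions, "auto")) {
    two_f <- if (length(factors) >= 2) {
      apply(combn(factors, 2), 2, paste, collapse = ":")
    } else character()
    three_f <- if (length(factors) >= 3) {
      apply(combn(factors, 3), 2, paste, collapse = ":")
    } else character()
    cov_f <- as.character(outer(covariates, factors, paste, sep = ":"))
    interactions <- c(two_f, cov_f, three_f)
  }
  nest_within <- nest_within %||% intersect(c("clade", "h2s", "sulfidic"),
                                            factors)
  structure(list(dependents = dependents, factors = factors,
                 covariates = covariates, interactions = interactions %||%
                   character(), site_term = site_term, site_var = site_var,
                 nest_within = nest_within),
            class = "mglm_spec")
}

# --- design construction -------------------------------------------------

# per-variable row coding: factors get sum-to-zero contrast rows, covariates
# their numeric value. `levels` fixes the factor levels (training replay).
var_block <- function(data, var, levels = NULL) {
  x <- data[[var]]
  if (is.null(x)) stop("model variable not found in data: ", var)
  if (is.numeric(x) && is.null(levels)) {
    return(list(type = "covariate", mat = matrix(x, ncol = 1,
                                                 dimnames = list(NULL, var))))
  }
  f <- factor(x, levels = levels %||% sort(unique(as.character(x))))
  if (anyNA(f)) {
    stop("variable ", var, " has values outside the stored levels")
  }
  if (nlevels(f) < 2) stop("factor ", var, " needs at least 2 levels")
  cm <- stats::contr.sum(nlevels(f))
  m <- cm[as.integer(f), , drop = FALSE]
  colnames(m) <- paste0(var, seq_len(ncol(m)))
  list(type = "factor", mat = m, levels = levels(f), contrasts = cm)
}

# columnwise Kronecker (row-by-row) product of blocks, fixed column order
interact_cols <- function(mats) {
  out <- mats[[1]]
  for (m in mats[-1]) {
    cols <- list()
    for (i in seq_len(ncol(out))) {
      for (j in seq_len(ncol(m))) {
        cols[[length(cols) + 1L]] <- out[, i] * m[, j]
      }
    }
    out <- do.call(cbind, cols)
  }
  out
}

# site-within-cell sum-coded block
site_block <- function(data, site_var, cell, cell_levels = NULL,
                       site_levels = NULL) {
  cell_f <- factor(cell, levels = cell_levels %||% sort(unique(cell)))
  site_f <- as.character(data[[site_var]])
  cols <- list()
  meta <- list()
  for (cl in levels(cell_f)) {
    in_cell <- cell_f == cl
    sts <- site_levels[[cl]] %||% sort(unique(site_f[in_cell]))
    k <- length(sts)
    meta[[cl]] <- sts
    if (k < 2) next
    for (j in seq_len(k - 1)) {
      v <- numeric(nrow(data))
      v[in_cell & site_f == sts[j]] <- 1
      v[in_cell & site_f == sts[k]] <- -1
      cols[[paste0("site_", cl, "_", j)]] <- v
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow(data), 0)
  list(type = "site", mat = mat, cells = levels(cell_f), site_levels = meta)
}

# Build the full design for `spec` on `data`. `template` (a prior build)
# replays stored factor/site levels on new data.
build_design <- function(data, spec, template = NULL) {
  tvb <- template$var_blocks
  var_blocks <- list()
  for (v in c(spec$factors, spec$covariates)) {
    var_blocks[[v]] <- var_block(data, v, levels = tvb[[v]]$levels)
  }
  terms <- list()
  mats <- list(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  assign <- 0L
  term_id <- 0L
  add_term <- function(name, mat, type) {
    term_id <<- term_id + 1L
    terms[[name]] <<- list(name = name, type = type, dfh = ncol(mat),
                           id = term_id)
    mats[[length(mats) + 1L]] <<- mat
    assign <<- c(assign, rep(term_id, ncol(mat)))
  }
  for (v in spec$covariates) add_term(v, var_blocks[[v]]$mat, "covariate")
  for (v in spec$factors) add_term(v, var_blocks[[v]]$mat, "factor")
  for (tm in spec$interactions) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    add_term(tm, interact_cols(lapply(vars, function(v) var_blocks[[v]]$mat)),
             "interaction")
  }
  site <- NULL
  if (isTRUE(spec$site_term)) {
    cell <- do.call(paste, c(lapply(spec$nest_within,
                                    function(v) as.character(data[[v]])),
                             sep = "*"))
    site <- site_block(data, spec$site_var, cell,
                       cell_levels = template$site$cells,
                       site_levels = template$site$site_levels)
    if (ncol(site$mat) > 0) {
      add_term("site", site$mat, "site")
    }
  }
  x <- do.call(cbind, mats)
  list(x = x, assign = assign, terms = terms, var_blocks = var_blocks,
       site = site)
}

# --- fitting -------------------------------------------------------------

#' Fit a multivariate linear model with Type-III term SSCPs
#'
#' Fits all responses jointly by least squares on a sum-to-zero coded design
#' and computes, for every term, the Type-III hypothesis SSCP `H` as the
#' difference between the residual SSCP of the model without that term's
#' columns and the full-model residual SSCP `E`. Wilks' lambda statistics
#' for each term (tested against `E`) are tabulated via [wilks_stats()].
#'
#' @param data Data frame holding responses and model variables; rows with
#'   missing values in any used column are dropped.
#' @param spec An [mglm_spec()].
#' @return An object of class `mglm_fit`: the design, coefficient matrix,
#'   `E`, `dfe`, per-term `H` matrices, and a `term_table` tibble with
#'   Wilks lambda, Rao F, dfs, p, partial eta squared, and relative
#'   variance (partial eta squared scaled to the model's strongest term).
#' @export
fit_mglm <- function(data, spec) {
  stopifnot(inherits(spec, "mglm_spec"))
  used <- unique(c(spec$dependents, spec$factors, spec$covariates,
                   if (spec$site_term) spec$site_var))
  data <- tibble::as_tibble(data)
  keep <- complete.cases(data[, used])
  data <- data[keep, ]
  y <- as.matrix(data[, spec$dependents])
  des <- build_design(data, spec)
  x <- des$x
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- unique(des$assign[qx$pivot[seq(qx$rank + 1, ncol(x))]])
    bad_names <- names(des$terms)[vapply(des$terms, function(t)
      t$id %in% bad, logical(1))]
    stop("design is rank deficient; aliased term(s): ",
         paste(bad_names, collapse = ", "))
  }
  b <- qr.coef(qx, y)
  res <- y - x %*% b
  e <- symm(crossprod(res))
  dfe <- nrow(x) - ncol(x)
  p <- ncol(y)

  hs <- list()
  rows <- list()
  for (nm in names(des$terms)) {
    t <- des$terms[[nm]]
    xr <- x[, des$assign != t$id, drop = FALSE]
    rr <- y - xr %*% qr.coef(qr(xr), y)
    h <- symm(crossprod(rr) - e)
    hs[[nm]] <- h
    ws <- wilks_stats(h, e, dfh = t$dfh, dfe = dfe, p = p)
    rows[[nm]] <- tibble::tibble(term = nm, !!!ws)
  }
  term_table <- dplyr::bind_rows(rows)
  term_table$relative_variance <-
    term_table$partial_eta_sq / max(term_table$partial_eta_sq)

  structure(list(spec = spec, data = data, Y = y, design = des, B = b,
                 E = e, dfe = dfe, H = hs, term_table = term_table,
                 n = nrow(x), rank = ncol(x)),
            class = "mglm_fit")
}

#' @export
print.mglm_fit <- function(x, ...) {
  cat(sprintf("<mglm_fit: %d obs, %d response(s), dfe = %d>\n",
              x$n, ncol(x$Y), x$dfe))
  print(x$term_table)
  invisible(x)
}

#' Wilks' lambda statistics for a hypothesis/error SSCP pair
#'
#' Computes `lambda = det(E) / det(H + E)`, the Rao F approximation with its
#' degrees of freedom (exact when `min(p, dfh) <= 2`), and partial eta
#' squared `1 - lambda^(1/s)` with `s = min(p, dfh)`.
#'
#' @param h Hypothesis SSCP matrix (p x p, PSD).
#' @param e Error SSCP matrix (p x p, positive definite).
#' @param dfh,dfe Hypothesis and error degrees of freedom.
#' @param p Number of responses (defaults to `nrow(e)`).
#' @return A named list: `wilks, f, df1, df2, p_value, partial_eta_sq`.
#' @export
wilks_stats <- function(h, e, dfh, dfe, p = nrow(as.matrix(e))) {
  h <- as.matrix(h)
  e <- as.matrix(e)
  det_e <- det(e)
  if (!is.finite(det_e) || det_e <= 0) {
    stop("error SSCP is singular; reduce the number of responses")
  }
  lam <- det_e / det(h + e)
  lam <- min(max(lam, .Machine$double.xmin), 1)
  q <- dfh
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- dfe + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * tt - (p * q) / 2 + 1
  lam_t <- lam^(1 / tt)
  f <- ((1 - lam_t) / lam_t) * (df2 / df1)
  s <- min(p, q)
  list(wilks = lam, f = f, df1 = df1, df2 = df2,
       p_value = pf(f, df1, df2, lower.tail = FALSE),
       partial_eta_sq = 1 - lam^(1 / s))
}
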