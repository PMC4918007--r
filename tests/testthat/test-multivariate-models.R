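# trait transforms, Type-III MANCOVA machinery, Wilks statistics,
# pruning, site-level tests, divergence vectors, EMMs, post-hoc ANCOVA

test_that("trait transforms apply the per-variable mapping then z-scale", {
  tr <- tibble::tibble(
    sl_mm = c(10, 100, 10^1.5), fecundity = c(4, 9, 16),
    fat_content = c(0, 1, 0.5), lean_weight_g = c(0.1, 0.2, 0.3),
    gsi_or_ra = c(0.1, 0.2, 0.3), embryo_lean_weight_mg = c(1, 2, 4),
    embryo_fat = c(0.1, 0.2, 0.3)
  )
  raw <- transform_traits(tr, z = FALSE)
  expect_equal(raw$sl_mm, c(1, 2, 1.5), tolerance = 1e-10)
  expect_equal(raw$fecundity, c(2, 3, 4))
  expect_equal(raw$fat_content[1:2], c(0, pi / 2))

  zt <- transform_traits(tr)
  for (v in names(tr)) {
    expect_equal(mean(zt[[v]]), 0, tolerance = 1e-12)
    expect_equal(sd(zt[[v]]), 1, tolerance = 1e-12)
  }
  expect_identical(attr(zt, "transform_state"), "transformed")
  expect_error(transform_traits(zt), "already transformed")
  expect_error(transform_traits(tibble::tibble(sl_mm = c(-1, 2, 3))),
               "non-positive")
  expect_error(transform_traits(tibble::tibble(fat_content = c(0.2, 1.4, 1))),
               "proportions")

  # stored mapping reproduces the training scale on new data
  new <- apply_transform(tr[2, ], attr(zt, "transform_map"))
  expect_equal(as.numeric(new[1, names(tr)]),
               as.numeric(zt[2, names(tr)]), tolerance = 1e-12)
})

test_that("residual SSCP matches hand-computed least-squares arithmetic", {
  # 4 observations, 2 responses, one factor with 2 levels
  d <- tibble::tibble(
    g = c("a", "a", "b", "b"),
    y1 = c(1, 3, 2, 6), y2 = c(2, 2, 5, 7)
  )
  fit <- fit_mglm(d, mglm_spec(dependents = c("y1", "y2"), factors = "g",
                               interactions = NULL, site_term = FALSE))
  # residuals about group means: y1 a:(-1,1), b:(-2,2); y2 a:(0,0), b:(-1,1)
  e_hand <- rbind(c(1 + 1 + 4 + 4, 2 + 2), c(2 + 2, 1 + 1))
  expect_equal(fit$E, e_hand, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fit$dfe, 2)

  # H and E symmetric PSD
  for (m in c(fit$H, list(fit$E))) {
    expect_equal(m, t(m), tolerance = 1e-10)
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("Type-III SSCPs equal sequential SSCPs in a balanced orthogonal
           design", {
  withr::with_seed(11, {
    d <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"),
                            rep = 1:6)
    d$y1 <- rnorm(nrow(d))
    d$y2 <- rnorm(nrow(d))
  })
  spec <- mglm_spec(dependents = c("y1", "y2"), factors = c("a", "b"),
                    interactions = "a:b", site_term = FALSE)
  fit <- fit_mglm(d, spec)
  # sequential: fit terms in order, difference of residual SSCPs
  e_of <- function(fo) {
    m <- lm(fo, data = d)
    crossprod(resid(m))
  }
  y <- cbind(d$y1, d$y2)
  seq_a <- e_of(y ~ 1) - e_of(y ~ a)
  seq_b <- e_of(y ~ a) - e_of(y ~ a + b)
  expect_equal(fit$H[["a"]], seq_a, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$H[["b"]], seq_b, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rank-deficient designs fail loudly naming the aliased term", {
  d <- tibble::tibble(a = c("x", "x", "y", "y"), b = c("p", "p", "q", "q"),
                      y1 = rnorm(4))
  expect_error(
    fit_mglm(d, mglm_spec(dependents = "y1", factors = c("a", "b"),
                          interactions = NULL, site_term = FALSE)),
    "aliased"
  )
})

test_that("wilks statistics match determinant arithmetic and reduce to the
           univariate F", {
  # printed toy SSCPs: lambda = det(E)/det(H+E) = 4/8
  out <- wilks_stats(h = rbind(c(2, 0), c(0, 0)), e = diag(2, 2),
                     dfh = 1, dfe = 4, p = 2)
  expect_equal(out$wilks, 0.5)
  expect_equal(out$f, 1.5)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 3)
  expect_equal(out$partial_eta_sq, 0.5)

  # null effect
  out0 <- wilks_stats(h = matrix(0, 2, 2), e = diag(2), dfh = 1, dfe = 5)
  expect_equal(out0$wilks, 1)
  expect_equal(out0$f, 0)
  expect_equal(out0$partial_eta_sq, 0)

  # p = 1 equals the ANOVA F
  h1 <- matrix(6)
  e1 <- matrix(12)
  for (q in 1:3) {
    out1 <- wilks_stats(h1, e1, dfh = q, dfe = 10, p = 1)
    expect_equal(out1$f, (6 / q) / (12 / 10), tolerance = 1e-12)
    expect_equal(out1$df2, 10)
  }
  expect_error(wilks_stats(diag(2), matrix(0, 2, 2), 1, 4), "singular")
})

test_that("wilks lambda agrees with car's Type-III MANOVA", {
  skip_if_not_installed("car")
  withr::with_seed(3, {
    d <- tibble::tibble(
      a = sample(c("a1", "a2"), 40, TRUE),
      b = sample(c("b1", "b2"), 40, TRUE)
    )
    d$y1 <- rnorm(40) + (d$a == "a2") * 0.8
    d$y2 <- rnorm(40)
  })
  fit <- fit_mglm(d, mglm_spec(dependents = c("y1", "y2"),
                               factors = c("a", "b"), interactions = "a:b",
                               site_term = FALSE))
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mv <- car::Manova(lm(cbind(y1, y2) ~ a * b, data = d), type = "III")
  for (tm in c("a", "b", "a:b")) {
    lam_car <- det(mv$SSPE) / det(mv$SSP[[tm]] + mv$SSPE)
    expect_equal(fit$term_table$wilks[fit$term_table$term == tm], lam_car,
                 tolerance = 1e-8)
  }
})

test_that("partial eta squared is 1 - lambda^(1/s) for every fitted term", {
  st <- small_study_traits(31, n_per_site = 10)
  fit <- fit_mglm(dplyr::filter(transform_traits(st$traits), pregnant),
                  offspring_spec())
  tt <- fit$term_table
  s <- pmin(ncol(fit$Y), vapply(fit$design$terms, function(t) t$dfh,
                                integer(1))[tt$term])
  expect_equal(tt$partial_eta_sq, 1 - tt$wilks^(1 / s), tolerance = 1e-12)
  expect_equal(max(tt$relative_variance), 1)
})

test_that("stepwise pruning drops by order and respects the hierarchy
           exception", {
  # strong main effects, pure-noise interactions
  withr::with_seed(17, {
    d <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"),
                            cc = c("c1", "c2"), rep = 1:8)
    d$y1 <- rnorm(nrow(d)) + 2 * (d$a == "a2")
    d$y2 <- rnorm(nrow(d)) + (d$b == "b2")
  })
  spec <- mglm_spec(dependents = c("y1", "y2"), factors = c("a", "b", "cc"),
                    interactions = "auto", site_term = FALSE)
  fit <- fit_mglm(d, spec)
  # the 3-way is pure noise: it must be removed before any 2-way
  first <- sulfidiv:::term_vars(setdiff(fit$spec$interactions,
                                        prune_model(fit)$spec$interactions)[1])
  pr <- prune_model(fit)
  expect_false("a:b:cc" %in% pr$spec$interactions)
  # main effects survive pruning regardless of p
  expect_true(all(c("a", "b", "cc") %in% pr$spec$factors))
  # all remaining interactions significant or protected
  tt <- pr$term_table
  rem <- intersect(tt$term, pr$spec$interactions)
  for (tm in rem) {
    p_self <- tt$p_value[tt$term == tm]
    protectors <- rem[vapply(rem, function(o)
      length(sulfidiv:::term_vars(o)) > length(sulfidiv:::term_vars(tm)) &&
        all(sulfidiv:::term_vars(tm) %in% sulfidiv:::term_vars(o)) &&
        tt$p_value[tt$term == o] < 0.1, logical(1))]
    expect_true(p_self <= 0.1 || length(protectors) > 0)
  }

  # fully significant model is untouched
  withr::with_seed(4, {
    d2 <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:10)
    d2$y1 <- rnorm(nrow(d2)) +
      3 * (d2$a == "a2") * (d2$b == "b2") + 2 * (d2$a == "a2")
  })
  spec2 <- mglm_spec(dependents = "y1", factors = c("a", "b"),
                     interactions = "a:b", site_term = FALSE)
  fit2 <- fit_mglm(d2, spec2)
  expect_true(all(fit2$term_table$p_value < 0.1))
  expect_identical(prune_model(fit2)$spec$interactions, "a:b")
})

test_that("a nonsignificant 2-way is retained under a significant 3-way", {
  # construct data where a:b alone is null but a:b:cc is strong
  withr::with_seed(23, {
    d <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"),
                            cc = c("c1", "c2"), rep = 1:10)
    sgn <- with(d, ifelse(cc == "c1", 1, -1))
    d$y1 <- rnorm(nrow(d), sd = 0.5) +
      2.5 * sgn * (d$a == "a2") * (d$b == "b2")
  })
  spec <- mglm_spec(dependents = "y1", factors = c("a", "b", "cc"),
                    interactions = c("a:b", "a:cc", "b:cc", "a:b:cc"),
                    site_term = FALSE)
  fit <- fit_mglm(d, spec)
  tt <- fit$term_table
  expect_gt(tt$p_value[tt$term == "a:b"], 0.1)
  expect_lt(tt$p_value[tt$term == "a:b:cc"], 0.1)
  pr <- prune_model(fit)
  expect_true("a:b" %in% pr$spec$interactions)
  expect_true("a:b:cc" %in% pr$spec$interactions)
})

test_that("site-level test reduces to the classical nested ANOVA closed
           form", {
  # balanced univariate design: 2 habitats x 4 sites x 5 individuals
  withr::with_seed(8, {
    d <- tidyr::expand_grid(h2s = c("NS", "S"), site_no = 1:4, rep = 1:5)
    d$site_id <- paste0(d$h2s, d$site_no)
    site_eff <- rnorm(8, sd = 0.8)[as.integer(factor(d$site_id))]
    d$y1 <- rnorm(nrow(d)) + site_eff + 1.2 * (d$h2s == "S")
    d$clade <- "one"
  })
  fit <- fit_mglm(d, mglm_spec(dependents = "y1", factors = "h2s",
                               interactions = NULL, site_term = TRUE,
                               nest_within = "h2s"))
  out <- site_level_test(fit, "h2s")
  # classical nested ANOVA from site means (balanced):
  sm <- tapply(d$y1, d$site_id, mean)
  hab <- substr(names(sm), 1, 2) == "S1" | startsWith(names(sm), "S")
  ms_term <- 5 * 4 * sum((tapply(sm, hab, mean) - mean(sm))^2) / 1 / 5
  ms_site <- 5 * sum((sm - ave(sm, hab))^2) / (8 - 2) / 5
  expect_equal(out$f, ms_term / ms_site, tolerance = 1e-10)
  expect_equal(out$df2, 8 - 2)
  expect_identical(out$approx, "site-means")

  # habitat means identical while sites still vary: F ~ 0
  d0 <- d
  mirrored <- c(1, -1, 0.5, -0.5)[d0$site_no]
  d0$y1 <- mirrored + rnorm(nrow(d0), sd = 1e-8)
  fit0 <- fit_mglm(d0, mglm_spec(dependents = "y1", factors = "h2s",
                                 interactions = NULL, site_term = TRUE,
                                 nest_within = "h2s"))
  out0 <- site_level_test(fit0, "h2s")
  expect_lt(out0$f, 1e-2)
  expect_gt(out0$p_value, 0.9)

  # single site per cell is untestable
  d1 <- d[d$site_no == 1, ]
  fit1 <- fit_mglm(d1, mglm_spec(dependents = "y1", factors = "h2s",
                                 interactions = NULL, site_term = TRUE,
                                 nest_within = "h2s"))
  expect_warning(site_level_test(fit1, "h2s"), "untestable")
})

test_that("divergence vector finds the discriminant direction", {
  # difference confined to response 1
  d <- two_group_toy(5, n = 150, delta = c(2, 0))
  fit <- fit_mglm(d, mglm_spec(dependents = c("y1", "y2"), factors = "h2s",
                               interactions = NULL, site_term = FALSE))
  dv <- divergence_vector(fit, "h2s")
  expect_gt(abs(dv$coefficients["y1"]), 0.95)
  # orientation: sulfidic pole has the larger mean score
  expect_gte(mean(dv$scores$score[dv$scores$sulfidic]),
             mean(dv$scores$score[!dv$scores$sulfidic]))

  # brute-force search over unit vectors: maximize between/within ratio
  d2 <- two_group_toy(6, n = 200, delta = c(1.5, 0.8),
                      sigma = rbind(c(1, 0.6), c(0.6, 1)))
  fit2 <- fit_mglm(d2, mglm_spec(dependents = c("y1", "y2"), factors = "h2s",
                                 interactions = NULL, site_term = FALSE))
  dv2 <- divergence_vector(fit2, "h2s")
  y <- as.matrix(d2[, c("y1", "y2")])
  grp <- d2$h2s
  ratio <- function(th) {
    v <- c(cos(th), sin(th))
    s <- y %*% v
    m <- tapply(s, grp, mean)
    n <- table(grp)
    between <- sum(n * (m - mean(s))^2)
    within <- sum((s - ave(as.numeric(s), grp))^2)
    between / within
  }
  grid <- seq(0, pi, length.out = 20001)
  best <- grid[which.max(vapply(grid, ratio, numeric(1)))]
  v_best <- c(cos(best), sin(best))
  ang <- acos(min(1, abs(sum(v_best * dv2$coefficients)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("no direction separates habitats better than the divergence
           vector", {
  d <- two_group_toy(9, n = 120, delta = c(1, 1.2),
                     sigma = rbind(c(1, -0.3), c(-0.3, 1)))
  fit <- fit_mglm(d, mglm_spec(dependents = c("y1", "y2"), factors = "h2s",
                               interactions = NULL, site_term = FALSE))
  dv <- divergence_vector(fit, "h2s")
  y <- as.matrix(d[, c("y1", "y2")])
  fratio <- function(v) {
    s <- as.numeric(y %*% v)
    m <- tapply(s, d$h2s, mean)
    n <- table(d$h2s)
    sum(n * (m - mean(s))^2) / sum((s - ave(s, d$h2s))^2)
  }
  best <- fratio(dv$coefficients)
  withr::with_seed(1, {
    for (i in 1:1000) {
      v <- rnorm(2)
      expect_lte(fratio(v / sqrt(sum(v^2))), best + 1e-10)
    }
  })
})

test_that("projection reproduces training scores, centers, and is linear", {
  st <- small_study_traits(19, n_per_site = 10)
  tt <- transform_traits(st$traits)
  preg <- dplyr::filter(tt, pregnant)
  fit <- fit_mglm(preg, offspring_spec())
  dv <- divergence_vector(fit, "h2s")

  # self-consistency on the training rows actually used by the fit
  used <- fit$data
  expect_lt(max(abs(project_scores(dv, used) - dv$scores$score)), 1e-10)

  # an individual at the adjusted grand mean scores 0 (centered mode)
  center_row <- tibble::as_tibble(as.list(dv$train_center))
  expect_equal(project_scores(dv, center_row, adjust = "center"), 0,
               tolerance = 1e-10)

  # linearity over random convex combinations
  withr::with_seed(2, {
    for (i in 1:5) {
      al <- runif(1)
      a <- used[sample(nrow(used), 1), ]
      b <- used[sample(nrow(used), 1), ]
      mix <- a
      for (v in dv$dependents) mix[[v]] <- al * a[[v]] + (1 - al) * b[[v]]
      expect_equal(project_scores(dv, mix, adjust = "center"),
                   al * project_scores(dv, a, adjust = "center") +
                     (1 - al) * project_scores(dv, b, adjust = "center"),
                   tolerance = 1e-10)
    }
  })
  expect_error(project_scores(dv, used[, "sl_mm"]), "lacks response")
})

test_that("estimated marginal means match closed-form least squares", {
  # balanced one-way: EMMs are the raw group means
  withr::with_seed(12, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 7),
                        y1 = rnorm(21))
  })
  fit <- fit_mglm(d, mglm_spec(dependents = "y1", factors = "g",
                               interactions = NULL, site_term = FALSE))
  emm <- estimated_marginal_means(fit, "g")
  expect_equal(emm$emm, as.numeric(tapply(d$y1, d$g, mean)),
               tolerance = 1e-10)

  # two groups with a covariate: hand-computed adjusted means
  d2 <- tibble::tibble(g = c("A", "A", "B", "B"), x = c(0, 2, 1, 3),
                       y1 = c(0, 2, 3, 5))
  fit2 <- fit_mglm(d2, mglm_spec(dependents = "y1", factors = "g",
                                 covariates = "x", interactions = NULL,
                                 site_term = FALSE))
  emm2 <- estimated_marginal_means(fit2, "g")
  expect_equal(emm2$emm[emm2$level == "A"], 1.5, tolerance = 1e-10)
  expect_equal(emm2$emm[emm2$level == "B"], 3.5, tolerance = 1e-10)

  # EMM differences invariant to shifting the covariate
  d3 <- d2
  d3$x <- d3$x + 100
  expect_warning(
    emm3 <- estimated_marginal_means(fit2, "g",
                                     at = list(x = mean(d3$x))),
    "outside"
  )
  fit3 <- fit_mglm(d3, mglm_spec(dependents = "y1", factors = "g",
                                 covariates = "x", interactions = NULL,
                                 site_term = FALSE))
  emm3b <- estimated_marginal_means(fit3, "g")
  expect_equal(diff(emm2$emm), diff(emm3b$emm), tolerance = 1e-10)
})

test_that("post-hoc ANCOVA detects slope heterogeneity and matches the
           extra-sum-of-squares F", {
  # two sites with slopes 0 and 1
  withr::with_seed(20, {
    x <- rep(seq(-2, 2, length.out = 12), 2)
    site <- rep(c("s1", "s2"), each = 12)
    y <- ifelse(site == "s1", 0, x) + rnorm(24, sd = 0.3)
  })
  tab <- ancova_slopes(y, x, site)
  d <- data.frame(y = y, x = x, site = site)
  sse <- function(m) sum(resid(m)^2)
  m_full <- lm(y ~ site * x, d)
  m_add <- lm(y ~ site + x, d)
  f_hand <- ((sse(m_add) - sse(m_full)) / 1) / (sse(m_full) / (24 - 4))
  expect_equal(tab$f[tab$term == "site:shape"], f_hand, tolerance = 1e-8)

  # homogeneous null: strip the interaction component, F collapses to 0
  y0 <- y - (fitted(m_full) - fitted(m_add))
  tab0 <- ancova_slopes(y0, x, site)
  expect_lt(tab0$f[tab0$term == "site:shape"], 1e-12)

  # invariant to z-scaling of the covariate
  tab_z <- ancova_slopes(y, scale(x)[, 1], site)
  expect_equal(tab$f, tab_z$f, tolerance = 1e-8)

  # small sites excluded with warning
  expect_warning(ancova_slopes(c(y, rnorm(2)), c(x, 0:1),
                               c(site, rep("s3", 2))),
                 "excluding")
})

test_that("injected habitat effects surface in the H2S term as effect size
           grows", {
  p_at <- function(mult) {
    st <- small_study_traits(
      77, effects = effect_config(
        embryo_mass_effect = 1.52 * mult, fecundity_effect = -5.89 * mult,
        effect_vs_h2s_slope = ifelse(mult == 0, 0, 1)
      ), n_per_site = 12
    )
    fit <- fit_mglm(dplyr::filter(transform_traits(st$traits), pregnant),
                    offspring_spec())
    fit$term_table$p_value[fit$term_table$term == "h2s"]
  }
  ps <- vapply(c(0, 0.5, 1, 2), p_at, numeric(1))
  expect_gt(ps[1], 0.001)
  expect_lt(ps[4], 1e-6)
  expect_true(ps[4] <= ps[2] + 1e-6)
})
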