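# composition, log-log regression, area estimates, stepwise removal, core scan

toy_comp <- function(A, a, code = 1L, label = "res") {
  tibble::tibble(animal_id = sprintf("a%02d", seq_along(A)),
                 estimator = "toy", core_pct = 100,
                 A_ha = A, code = code, label = label, a_ha = a)
}

test_that("composition rows mirror the geometry they came from", {
  ls <- resource_landscape()
  pop <- make_constrained_population(ls, I = 3, a_h = 0.4, code = 1,
                                     extra_ha = c(1, 2, 3), seed = 4)
  comp <- build_composition(pop$outlines, ls)
  expect_equal(nrow(comp), 3L) # one category
  expect_equal(comp$a_ha, rep(0.4, 3), tolerance = 1e-9)
  expect_equal(comp$A_ha, pop$truth$A_ha, tolerance = 1e-9)
  # zero areas are retained, not dropped
  m2 <- two_patch_map()
  o <- rada:::new_outline("far", "Xr", 100,
                          rada:::rect_poly(9000, 9100, 9000, 9100))
  expect_warning(comp2 <- build_composition(o, m2), "disjoint")
  expect_equal(nrow(comp2), 2L)
  expect_true(all(comp2$a_ha == 0))
  # duplicate animal under the same estimator/core errors
  expect_error(build_composition(rbind(o, o), ls), "duplicate")
})

test_that("log-log fit reproduces the exact hyperbola", {
  comp <- toy_comp(A = c(1, 2, 4), a = rep(0.5, 3))
  f <- fit_loglog(comp, 1L)
  expect_equal(f$b, -1, tolerance = 1e-12)
  expect_equal(f$r, -1, tolerance = 1e-12)
  expect_equal(f$c, log(0.5), tolerance = 1e-12)
  expect_equal(f$a_min, 0.5, tolerance = 1e-12)
})

test_that("constant proportion gives zero slope, zero-variance x is flagged", {
  comp <- toy_comp(A = c(1, 2, 4, 8), a = 0.3 * c(1, 2, 4, 8))
  f <- fit_loglog(comp, 1L)
  expect_equal(f$b, 0, tolerance = 1e-12)

  flat <- toy_comp(A = rep(2, 5), a = runif(5, 0.1, 1))
  f2 <- fit_loglog(flat, 1L)
  expect_false(f2$defined)
  expect_match(f2$reason, "zero variance")
})

test_that("fit equals an independent least-squares oracle to 1e-12", {
  # six arbitrary pairs
  A <- c(1.7, 2.9, 5.3, 8.1, 12.4, 20.2)
  a <- c(0.62, 0.55, 0.70, 0.48, 0.66, 0.52)
  f <- fit_loglog(toy_comp(A, a), 1L)
  x <- log(A); y <- log(a / A)
  ora <- stats::lm(y ~ x)
  expect_equal(f$b, unname(coef(ora)[2]), tolerance = 1e-12)
  expect_equal(f$c, unname(coef(ora)[1]), tolerance = 1e-12)
  expect_equal(f$se_b, summary(ora)$coefficients[2, 2], tolerance = 1e-12)
  expect_equal(f$r, unname(cor(x, y)), tolerance = 1e-12)
})

test_that("missing-category handling: omit drops, beta transforms", {
  A <- c(1, 2, 3, 4, 6)
  a <- c(0.5, 0, 0.4, 0.6, 0)
  f_omit <- fit_loglog(toy_comp(A, a), 1L, handling = "omit")
  expect_equal(f_omit$n, 3L)
  expect_equal(f_omit$pct_missing, 40)

  f_beta <- fit_loglog(toy_comp(A, a), 1L, handling = "beta")
  expect_equal(f_beta$n, 5L)
  # mean proportion = (0.5 + 0 + 0.133 + 0.15 + 0)/5 = 0.157 > 0.10 -> 0.01
  expect_equal(f_beta$beta, 0.01)
  y <- log(0.01 + a / A); x <- log(A)
  expect_equal(f_beta$b, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  # sparse category -> beta = 0.001
  a_sparse <- c(0.05, 0, 0.1, 0.12, 0)
  f_b2 <- fit_loglog(toy_comp(A, a_sparse), 1L, handling = "beta")
  expect_equal(f_b2$beta, 0.001)
  # explicit beta overrides the rule
  f_b3 <- fit_loglog(toy_comp(A, a), 1L, handling = "beta", beta = 0.5)
  expect_equal(f_b3$beta, 0.5)
})

test_that("minimum-area back-transform follows exp(-c/b)", {
  f1 <- fit_loglog(toy_comp(c(1, 2, 4), rep(0.5, 3)), 1L)
  expect_equal(min_area_estimate(f1)$a_min_ha, exp(f1$c), tolerance = 1e-9)

  # c = 0, b = -1 -> 1 ha; c = ln 4, b = -2 -> 2 ha (constructed fits)
  mk <- function(b, cc) {
    f <- f1; f$b <- b; f$c <- cc; f
  }
  expect_equal(min_area_estimate(mk(-1, 0))$a_min_ha, 1)
  expect_equal(min_area_estimate(mk(-2, log(4)))$a_min_ha, 2)

  # positive slope: no estimate, reason recorded
  up <- fit_loglog(toy_comp(c(1, 2, 4, 8), c(0.1, 0.3, 0.9, 2.7)), 1L)
  expect_gt(up$b, 0)
  am <- min_area_estimate(up)
  expect_true(is.na(am$a_min_ha))
  expect_match(am$reason, "non-negative")
})

test_that("confidence limits bracket the point estimate", {
  set.seed(19)
  A <- exp(runif(15, 0, 3))
  a <- pmin(0.5 * exp(rnorm(15, 0, 0.3)), A)
  f <- fit_loglog(toy_comp(A, a), 1L)
  am <- min_area_estimate(f)
  expect_true(am$lo < am$a_min_ha && am$a_min_ha < am$hi)
})

test_that("slope test against -1 matches a t-distribution oracle", {
  f <- fit_loglog(toy_comp(c(1, 2, 4), rep(0.5, 3)), 1L)
  sv <- slope_vs_minus1(f)
  expect_equal(sv$t, 0, tolerance = 1e-9)
  expect_false(sv$differs)

  # shallow slope with small SE: significant (large-sample case)
  f2 <- f; f2$b <- -0.23; f2$se_b <- 0.04; f2$n <- 15L
  sv2 <- slope_vs_minus1(f2)
  expect_true(sv2$differs)
  expect_lt(sv2$p_value, 0.001)
  # independent CDF oracle via pt on the same statistic
  t_ora <- (-0.23 + 1) / 0.04
  p_ora <- 2 * (1 - stats::pt(t_ora, 13))
  expect_equal(sv2$p_value, p_ora, tolerance = 1e-10)
})

test_that("geometric mean and CL equal the hand-computed t-interval", {
  expect_equal(geometric_mean_cl(rep(0.5, 4))$gm, 0.5)
  expect_equal(geometric_mean_cl(rep(0.5, 4))$lo, 0.5, tolerance = 1e-12)
  expect_equal(geometric_mean_cl(c(1, 100))$gm, 10, tolerance = 1e-12)

  set.seed(23)
  v <- exp(rnorm(15, log(0.5), 0.4))
  g <- geometric_mean_cl(v)
  lv <- log(v)
  tq <- qt(0.975, 14)
  expect_equal(g$gm, exp(mean(lv)), tolerance = 1e-12)
  expect_equal(g$lo, exp(mean(lv) - tq * sd(lv) / sqrt(15)), tolerance = 1e-12)
  expect_equal(g$hi, exp(mean(lv) + tq * sd(lv) / sqrt(15)), tolerance = 1e-12)

  expect_error(geometric_mean_cl(c(1, 0, 2), ids = c("a", "b", "c")), "b")
})

test_that("area estimate recommends the geometric mean when b departs from -1", {
  set.seed(29)
  A <- exp(runif(20, 0, 3))
  comp <- toy_comp(A, a = pmin(0.5 * A^0.7, 0.9 * A)) # shallow slope
  f <- fit_loglog(comp, 1L)
  est <- area_estimate(f, comp)
  expect_true(est$slope_differs)
  expect_equal(est$recommended, "a_bar")
  expect_equal(est$estimate, est$a_bar_ha)

  comp2 <- toy_comp(c(1, 2, 4, 8), rep(0.5, 4))
  est2 <- area_estimate(fit_loglog(comp2, 1L), comp2)
  expect_equal(est2$recommended, "a_min")
  expect_equal(est2$estimate, 0.5, tolerance = 1e-9)
})

# a significance stub for stepwise tests: parametric gate on r
stub_sig <- function(alpha = 0.05) {
  function(fit, step_comp, identified) {
    t <- fit$r * sqrt((fit$n - 2) / (1 - fit$r^2))
    list(significant = fit$r < 0 && 2 * stats::pt(t, fit$n - 2) < alpha)
  }
}

test_that("stepwise identifies the constrained category then stops", {
  set.seed(37)
  I <- 12
  A <- 0.5 + exp(runif(I, 0, 2.5))
  a1 <- rep(0.4, I)                           # area-constrained
  a2 <- 0.3 * (A - a1) * exp(rnorm(I, 0, 0.1)) # tracks the remainder
  comp <- dplyr::bind_rows(toy_comp(A, a1, 1L, "wood"),
                           toy_comp(A, a2, 2L, "grass"))
  sw <- stepwise_rada(comp, stub_sig())
  expect_equal(sw$identified, 1L)
  expect_equal(nrow(sw$steps), 1L)
  expect_match(sw$stop_reason, "no significant")
})

test_that("near-ties resolve to the most prevalent category", {
  # two categories, both perfectly constrained (r = -1 each), prevalences
  # ~38% vs ~5%: the more prevalent one must be picked first
  A <- c(1, 1.6, 2.6, 4.2, 6.8)
  comp <- dplyr::bind_rows(toy_comp(A, rep(0.38 * 2, 5), 1L, "wood"),
                           toy_comp(A, rep(0.053 * 2, 5), 2L, "wheat"))
  sw <- stepwise_rada(comp, stub_sig())
  expect_equal(sw$identified[1], 1L)
})

test_that("animals with zero remainder are excluded at the next step", {
  # animal a01's range is entirely category 1
  A <- c(1, 2, 3, 4, 5)
  a1 <- c(1, 0.5, 0.5, 0.5, 0.5)
  a2 <- c(0, 0.9, 1.2, 1.9, 2.4)
  comp <- dplyr::bind_rows(toy_comp(A, a1, 1L, "wood"),
                           toy_comp(A, a2, 2L, "grass"))
  seen <- list()
  spy <- function(fit, step_comp, identified) {
    seen[[length(seen) + 1L]] <<- unique(step_comp$animal_id)
    stub_sig()(fit, step_comp, identified)
  }
  sw <- stepwise_rada(comp, spy)
  expect_true(1L %in% sw$identified)
  later <- seen[-1]
  if (length(later))
    expect_false("a01" %in% unlist(later))
  if (nrow(sw$steps) > 1)
    expect_true("a01" %in% sw$steps$excluded[[2]])
})

test_that("core scan ratios and selection follow a/|b|", {
  fits <- tibble::tibble(core_pct = c(35, 65, 95),
                         a_ha = c(0.2, 13, 1),
                         b = c(-0.3, -0.5, -0.06))
  cs <- core_scan(fits)
  expect_equal(cs$scan$ratio, c(0.2 / 0.3, 26, 1 / 0.06), tolerance = 1e-12)
  expect_equal(cs$selected, 65)

  single <- core_scan(tibble::tibble(core_pct = 50, a_ha = 1, b = -1))
  expect_equal(single$selected, 50)

  # ties resolve to the largest core; non-negative slopes are skipped
  tied <- core_scan(tibble::tibble(core_pct = c(40, 60, 80),
                                   a_ha = c(1, 1, 2), b = c(-0.5, -0.5, 1)))
  expect_equal(tied$selected, 60)
  expect_error(core_scan(tibble::tibble(core_pct = 1, a_ha = 1, b = 0.5)),
               "negative slope")
})

test_that("r and b are scale-invariant; areas scale with the square", {
  ls <- resource_landscape(seed = 6)
  pop <- make_constrained_population(ls, I = 5, a_h = 0.5, code = 1,
                                     extra_ha = c(0.5, 1, 2, 3.5, 5), seed = 7)
  comp <- build_composition(pop$outlines, ls)
  f <- fit_loglog(comp, 1L)
  s <- 3 # scale all coordinates by s: areas scale by s^2
  comp2 <- dplyr::mutate(comp, A_ha = A_ha * s^2, a_ha = a_ha * s^2)
  f2 <- fit_loglog(comp2, 1L)
  expect_equal(f2$r, f$r, tolerance = 1e-12)
  expect_equal(f2$b, f$b, tolerance = 1e-12)
  expect_equal(f2$a_min, f$a_min * s^2, tolerance = 1e-9)
})

test_that("tidy and glance methods return broom-shaped tables", {
  f <- fit_loglog(toy_comp(c(1, 2, 4, 9), c(0.5, 0.52, 0.48, 0.5)), 1L)
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "ln(A)"))
  expect_equal(nrow(glance(f)), 1L)
  # tidy coefficients match lm on the same transformed data
  ora <- lm(f$y ~ f$x)
  expect_equal(td$estimate, unname(coef(ora)[1:2]), tolerance = 1e-10)
  expect_equal(td$std.error,
               unname(summary(ora)$coefficients[, 2]), tolerance = 1e-10)
})
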