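# RADA statistics: composition tables, the ln(a/A) ~ ln(A) regression,
# minimum-area and geometric-mean estimates, the slope-vs--1 assessment,
# stepwise masking removal and the core-size scan.

#' Build a composition table from outlines and a map
#'
#' One row per animal x category: the core area `A_ha` and the area `a_ha`
#' of each map category inside the outline. Zero areas are retained; they
#' carry the missing-category information the regression handling needs.
#'
#' @param outlines Outline tibble (one row per animal for a single
#'   estimator/core, or several estimator/core combinations).
#' @param map A `categorical_map`.
#' @return A composition tibble with columns `animal_id`, `estimator`,
#'   `core_pct`, `A_ha`, `code`, `label`, `a_ha`.
#' @export
build_composition <- function(outlines, map) {
  stopifnot(is.data.frame(outlines), nrow(outlines) >= 1L)
  key <- paste(outlines$animal_id, outlines$estimator, outlines$core_pct)
  if (anyDuplicated(key))
    stop("duplicate animal_id for the same estimator/core: ",
         key[duplicated(key)][1], call. = FALSE)
  purrr::map_dfr(seq_len(nrow(outlines)), function(i) {
    ca <- category_areas(outlines$geometry[[i]], map)
    tibble::tibble(
      animal_id = outlines$animal_id[i],
      estimator = outlines$estimator[i],
      core_pct = outlines$core_pct[i],
      A_ha = outlines$area_ha[i],
      code = ca$code, label = ca$label, a_ha = ca$area_ha
    )
  })
}

#' Log-log resource-area regression for one map category
#'
#' Ordinary least squares of `y = ln(a/A)` on `x = ln(A)` (natural logs,
#' areas in hectares) across animals, for category `code`. Ranges lacking
#' the category are either omitted (`handling = "omit"`) or retained through
#' the transform `y = ln(beta + a/A)` (`handling = "beta"`), with `beta`
#' 0.01 when the category's mean proportion exceeds 0.10 and 0.001
#' otherwise (evaluated on the supplied, possibly remainder-adjusted,
#' composition).
#'
#' A conserved absolute resource area shows as slope `b = -1` and Pearson
#' correlation -1; the x-axis intercept `exp(-c/b)` estimates the minimum
#' required area.
#'
#' @param comp A composition tibble (one estimator/core).
#' @param code Category code to fit.
#' @param handling `"omit"` or `"beta"`.
#' @param beta Optional explicit beta; default follows the mean-proportion
#'   rule.
#' @return A `rada_fit` object; `glance()` gives the one-row summary. When
#'   fewer than 3 usable rows remain or `ln(A)` has zero variance the fit is
#'   flagged undefined rather than raising an error.
#' @export
fit_loglog <- function(comp, code, handling = c("omit", "beta"), beta = NULL) {
  handling <- match.arg(handling)
  stopifnot(is.data.frame(comp), all(c("animal_id", "A_ha", "code", "a_ha")
                                     %in% names(comp)))
  rows <- comp[comp$code == code & comp$A_ha > 0, , drop = FALSE]
  lab <- if ("label" %in% names(comp) && nrow(rows))
    rows$label[1] else NA_character_
  pct_missing <- if (nrow(rows)) 100 * mean(rows$a_ha == 0) else NA_real_
  if (handling == "omit") {
    use <- rows[rows$a_ha > 0, , drop = FALSE]
    y <- log(use$a_ha / use$A_ha)
  } else {
    use <- rows
    if (is.null(beta))
      beta <- if (mean(rows$a_ha / rows$A_ha) > 0.10) 0.01 else 0.001
    y <- log(beta + use$a_ha / use$A_ha)
  }
  x <- log(use$A_ha)
  out <- list(category = code, label = lab, handling = handling,
              beta = if (handling == "beta") beta else NA_real_,
              pct_missing = pct_missing, n = length(x),
              animal_id = use$animal_id, x = x, y = y)
  if (length(x) < 3L) {
    out <- c(out, list(defined = FALSE, reason = "fewer than 3 usable ranges",
                       r = NA_real_, b = NA_real_, se_b = NA_real_,
                       c = NA_real_, a_min = NA_real_,
                       sxx = NA_real_, xbar = NA_real_, sigma2 = NA_real_))
    return(structure(out, class = "rada_fit"))
  }
  s <- ols_sums(x, y)
  if (s$sxx <= 0) {
    out <- c(out, list(defined = FALSE, reason = "zero variance in ln(A)",
                       r = NA_real_, b = NA_real_, se_b = NA_real_,
                       c = NA_real_, a_min = NA_real_,
                       sxx = s$sxx, xbar = s$xbar, sigma2 = NA_real_))
    return(structure(out, class = "rada_fit"))
  }
  out <- c(out, list(defined = TRUE, reason = NA_character_), s["r"], s["b"],
           s["se_b"], s["c"],
           list(a_min = if (s$b < 0) exp(-s$c / s$b) else NA_real_),
           s["sxx"], s["xbar"], s["sigma2"])
  structure(out, class = "rada_fit")
}

# closed-form OLS sums shared by fit_loglog and the vectorized null fits
ols_sums <- function(x, y) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  syy <- sum((y - ybar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  if (sxx <= 0)
    return(list(r = NA_real_, b = NA_real_, se_b = NA_real_, c = NA_real_,
                sxx = sxx, xbar = xbar, sigma2 = NA_real_))
  b <- sxy / sxx
  cc <- ybar - b * xbar
  sigma2 <- max(syy - b * sxy, 0) / max(n - 2, 1)
  se_b <- if (n > 2) sqrt(sigma2 / sxx) else NA_real_
  r <- if (syy > 1e-12) sxy / sqrt(sxx * syy) else NA_real_
  list(r = r, b = b, se_b = se_b, c = cc, sxx = sxx, xbar = xbar,
       sigma2 = sigma2)
}

#' @export
print.rada_fit <- function(x, ...) {
  cat(sprintf("<rada_fit: category %s (%s), n = %d>\n",
              x$category, x$label, x$n))
  if (!x$defined) {
    cat("  undefined fit:", x$reason, "\n")
  } else {
    cat(sprintf("  r = %.3f, b = %.3f (SE %.3f), c = %.3f\n",
                x$r, x$b, x$se_b, x$c))
    if (!is.na(x$a_min))
      cat(sprintf("  x-intercept estimate exp(-c/b) = %.4g ha\n", x$a_min))
    cat(sprintf("  %.0f%% of ranges lacked the category (handling: %s)\n",
                x$pct_missing, x$handling))
  }
  invisible(x)
}

#' @rdname fit_loglog
#' @param x A `rada_fit`.
#' @param ... Unused.
#' @export
tidy.rada_fit <- function(x, ...) {
  if (!x$defined)
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  se_c <- sqrt(x$sigma2 * (1 / x$n + x$xbar^2 / x$sxx))
  df <- x$n - 2
  est <- c(x$c, x$b); se <- c(se_c, x$se_b)
  tibble::tibble(
    term = c("(Intercept)", "ln(A)"),
    estimate = est, std.error = se, statistic = est / se,
    p.value = 2 * stats::pt(-abs(est / se), df)
  )
}

#' @rdname fit_loglog
#' @export
glance.rada_fit <- function(x, ...) {
  tibble::tibble(category = x$category, label = x$label, n = x$n,
                 r = x$r, b = x$b, se_b = x$se_b, c = x$c, a_min = x$a_min,
                 pct_missing = x$pct_missing, handling = x$handling,
                 beta = x$beta, defined = x$defined)
}

#' Minimum-area estimate with confidence limits
#'
#' Back-transforms the x-axis intercept `-c/b` of the log-log regression to
#' `a_min = exp(-c/b)` hectares, the estimated minimum category area an
#' animal requires. Confidence limits come from the delta method on `-c/b`
#' using the OLS covariance of `(c, b)`, then exponentiation.
#'
#' @param fit A defined `rada_fit` with negative slope.
#' @param level Confidence level.
#' @return One-row tibble `a_min_ha`, `lo`, `hi`, `level`; when `b >= 0` or
#'   the fit is undefined, `a_min_ha` is `NA` and `reason` records why.
#' @export
min_area_estimate <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rada_fit"))
  if (!fit$defined)
    return(tibble::tibble(a_min_ha = NA_real_, lo = NA_real_, hi = NA_real_,
                          level = level, reason = fit$reason))
  if (fit$b >= 0)
    return(tibble::tibble(a_min_ha = NA_real_, lo = NA_real_, hi = NA_real_,
                          level = level,
                          reason = "slope is non-negative: no x-intercept estimate"))
  x0 <- -fit$c / fit$b
  var_b <- fit$sigma2 / fit$sxx
  var_c <- fit$sigma2 * (1 / fit$n + fit$xbar^2 / fit$sxx)
  cov_cb <- -fit$sigma2 * fit$xbar / fit$sxx
  grad <- c(-1 / fit$b, fit$c / fit$b^2) # d(-c/b)/d(c, b)
  v <- grad[1]^2 * var_c + grad[2]^2 * var_b + 2 * grad[1] * grad[2] * cov_cb
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - 2)
  tibble::tibble(a_min_ha = exp(x0), lo = exp(x0 - tq * sqrt(v)),
                 hi = exp(x0 + tq * sqrt(v)), level = level,
                 reason = NA_character_)
}

#' Test the slope against -1
#'
#' A slope significantly different from -1 signals departure from the
#' perfect-hyperbola model (heterogeneous resource access or individual
#' variation), in which case the geometric mean of the observed category
#' areas is the preferred requirement estimate over the regression
#' intercept.
#'
#' @param fit A defined `rada_fit`.
#' @param alpha Two-tailed significance level.
#' @return One-row tibble `t`, `df`, `p_value`, `differs`.
#' @export
slope_vs_minus1 <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rada_fit"))
  if (!fit$defined || is.na(fit$se_b) || fit$se_b < 0 || fit$n <= 2)
    return(tibble::tibble(t = NA_real_, df = NA_integer_, p_value = NA_real_,
                          differs = NA))
  if (fit$se_b == 0) {
    # residual-free fit: the slope is known exactly
    t <- if (fit$b == -1) 0 else sign(fit$b + 1) * Inf
    return(tibble::tibble(t = t, df = fit$n - 2L,
                          p_value = if (t == 0) 1 else 0,
                          differs = t != 0))
  }
  t <- (fit$b + 1) / fit$se_b
  df <- fit$n - 2L
  p <- 2 * stats::pt(-abs(t), df)
  tibble::tibble(t = t, df = df, p_value = p, differs = p < alpha)
}

#' Geometric mean with confidence limits
#'
#' `exp(mean(ln v))` with a t-interval on the log scale, back-transformed.
#'
#' @param values Positive areas (ha).
#' @param level Confidence level.
#' @param ids Optional identifiers used in error messages.
#' @return One-row tibble `gm`, `lo`, `hi`, `n`.
#' @export
geometric_mean_cl <- function(values, level = 0.95, ids = NULL) {
  if (any(values <= 0)) {
    bad <- if (is.null(ids)) which(values <= 0)[1] else ids[values <= 0][1]
    stop("non-positive area for ", bad,
         ": geometric means need positive values", call. = FALSE)
  }
  lv <- log(values)
  n <- length(lv)
  gm <- exp(mean(lv))
  if (n < 2L)
    return(tibble::tibble(gm = gm, lo = NA_real_, hi = NA_real_, n = n))
  se <- stats::sd(lv) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  tibble::tibble(gm = gm, lo = exp(mean(lv) - tq * se),
                 hi = exp(mean(lv) + tq * se), n = n)
}

#' Combined area-requirement estimate for one category
#'
#' Joins the regression extrapolation (`a_min = exp(-c/b)` with delta-method
#' CL), the geometric mean of the observed category areas with t-interval
#' CL, and the slope-vs--1 verdict. The recommended estimator is the
#' geometric mean whenever the slope differs significantly from -1,
#' otherwise the regression intercept.
#'
#' @param fit A `rada_fit`.
#' @param comp The composition tibble the fit came from (for the observed
#'   areas).
#' @param level Confidence level.
#' @param alpha Significance level for the slope test.
#' @return One-row tibble with both estimates, the verdict and the
#'   recommended estimate (`estimate`, `lo`, `hi`).
#' @export
area_estimate <- function(fit, comp, level = 0.95, alpha = 0.05) {
  stopifnot(inherits(fit, "rada_fit"))
  am <- min_area_estimate(fit, level)
  obs <- comp$a_ha[comp$code == fit$category & comp$a_ha > 0]
  ab <- geometric_mean_cl(obs, level)
  sv <- slope_vs_minus1(fit, alpha)
  rec <- if (isTRUE(sv$differs) || is.na(am$a_min_ha)) "a_bar" else "a_min"
  tibble::tibble(
    category = fit$category, label = fit$label,
    a_min_ha = am$a_min_ha, a_min_lo = am$lo, a_min_hi = am$hi,
    a_bar_ha = ab$gm, a_bar_lo = ab$lo, a_bar_hi = ab$hi,
    slope_t = sv$t, slope_p = sv$p_value, slope_differs = sv$differs,
    recommended = rec,
    estimate = if (rec == "a_bar") ab$gm else am$a_min_ha,
    lo = if (rec == "a_bar") ab$lo else am$lo,
    hi = if (rec == "a_bar") ab$hi else am$hi
  )
}

#' Stepwise identification of required map categories
#'
#' Step 1 fits every category and selects the one with the strongest
#' significant negative correlation; near-ties (difference in r within
#' `tie_tol`) resolve to the most prevalent category, whose abundance could
#' mask the rarer one. Each later step removes the identified categories'
#' areas from every animal's core area (`-hA_i = A_i - a_{h,i}`), excludes
#' animals whose remainder is zero, and refits the remaining categories
#' against the remainder. The loop stops when no significant negative
#' correlation remains.
#'
#' @param comp Composition tibble for a single estimator/core.
#' @param significance_fn Function `(fit, step_comp, identified)` returning a
#'   list with at least `significant`; usually built by [rada_null_test()]
#'   so significance comes from the geometric randomization null.
#' @param alpha Significance level (the gate applied by `significance_fn`
#'   factories; recorded here).
#' @param tie_tol Tolerance on |r| for the prevalence tie-break.
#' @param handling Missing-category handling passed to [fit_loglog()].
#' @param remainder_tol Remainders at or below this (ha) are treated as zero.
#' @return A `rada_stepwise` object: tibble of identified steps (`tidy()`),
#'   per-step fits, excluded animals and the stop reason.
#' @export
stepwise_rada <- function(comp, significance_fn, alpha = 0.05, tie_tol = 0.05,
                          handling = "omit", remainder_tol = 1e-9) {
  codes <- unique(comp$code)
  if (length(codes) < 2L) stop("need at least 2 map categories", call. = FALSE)
  base <- comp[comp$code == codes[1], c("animal_id", "A_ha")]
  rem <- stats::setNames(base$A_ha, base$animal_id)
  identified <- integer(0)
  steps <- list()
  stop_reason <- "no significant negative correlation remained"
  for (step in seq_along(codes)) {
    cand <- setdiff(codes, identified)
    if (length(cand) == 0L) { stop_reason <- "all categories identified"; break }
    keep <- names(rem)[rem > remainder_tol]
    excluded <- setdiff(names(rem), keep)
    step_comp <- comp[comp$animal_id %in% keep, , drop = FALSE]
    step_comp$A_ha <- unname(rem[step_comp$animal_id])
    fits <- lapply(cand, function(cd) fit_loglog(step_comp, cd, handling))
    names(fits) <- as.character(cand)
    rvals <- vapply(fits, function(f) if (f$defined) f$r else NA_real_,
                    numeric(1))
    sig <- vapply(seq_along(fits), function(k) {
      f <- fits[[k]]
      if (!f$defined || is.na(rvals[k]) || rvals[k] >= 0) return(FALSE)
      res <- significance_fn(f, step_comp, identified)
      if (is.list(res)) isTRUE(res$significant) else isTRUE(res)
    }, logical(1))
    if (!any(sig)) {
      if (all(!vapply(fits, `[[`, logical(1), "defined")))
        stop_reason <- "all candidate fits undefined"
      break
    }
    r_sig <- rvals[sig]
    best_r <- min(r_sig)
    near <- which(sig & rvals <= best_r + tie_tol)
    if (length(near) > 1L) {
      prev <- vapply(cand[near], function(cd) {
        rows <- step_comp[step_comp$code == cd, ]
        mean(rows$a_ha / rows$A_ha)
      }, numeric(1))
      pick <- near[which.max(prev)]
    } else pick <- near[1]
    sel <- cand[pick]
    f_sel <- fits[[as.character(sel)]]
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, category = sel, label = f_sel$label,
      n = f_sel$n, r = f_sel$r, b = f_sel$b, se_b = f_sel$se_b, c = f_sel$c,
      a_min = f_sel$a_min, fit = list(f_sel),
      excluded = list(excluded)
    )
    identified <- c(identified, sel)
    sel_a <- comp[comp$code == sel, ]
    rem[sel_a$animal_id] <- rem[sel_a$animal_id] - sel_a$a_ha
  }
  structure(list(steps = dplyr::bind_rows(steps), identified = identified,
                 stop_reason = stop_reason, alpha = alpha, tie_tol = tie_tol,
                 handling = handling),
            class = "rada_stepwise")
}

#' @export
print.rada_stepwise <- function(x, ...) {
  cat(sprintf("<rada_stepwise: %d categor%s identified; %s>\n",
              length(x$identified),
              if (length(x$identified) == 1) "y" else "ies", x$stop_reason))
  if (nrow(x$steps))
    print(x$steps[, c("step", "category", "label", "n", "r", "b", "a_min")])
  invisible(x)
}

#' @rdname stepwise_rada
#' @param x A `rada_stepwise`.
#' @param ... Unused.
#' @export
tidy.rada_stepwise <- function(x, ...) {
  if (!nrow(x$steps)) return(x$steps)
  x$steps[, setdiff(names(x$steps), c("fit", "excluded"))]
}

#' Core-size scan: where does the area signal peak?
#'
#' For each core percentage, the ratio of the area estimate to the absolute
#' slope, `a / |b|`, indexes how strongly a conserved category area shows at
#' that core; the scan selects the core with the maximum ratio (ties go to
#' the largest core). Cores with non-negative slope are skipped.
#'
#' @param fits A data frame with columns `core_pct`, `b` and `a_ha` (the
#'   per-core area estimate, e.g. `a_min` or the geometric mean), typically
#'   one row per core for a single estimator and category.
#' @return A `rada_core_scan`: the scan table with `ratio`, and the selected
#'   core `selected`.
#' @export
core_scan <- function(fits) {
  stopifnot(is.data.frame(fits), all(c("core_pct", "b", "a_ha") %in% names(fits)))
  scan <- tibble::as_tibble(fits)
  scan$ratio <- ifelse(!is.na(scan$b) & scan$b < 0, scan$a_ha / abs(scan$b),
                       NA_real_)
  ok <- which(!is.na(scan$ratio))
  if (length(ok) == 0L)
    stop("no core with a defined negative slope", call. = FALSE)
  best <- max(scan$ratio[ok])
  sel <- max(scan$core_pct[ok][scan$ratio[ok] == best]) # ties: largest core
  structure(list(scan = scan, selected = sel), class = "rada_core_scan")
}

#' @export
print.rada_core_scan <- function(x, ...) {
  cat(sprintf("<rada_core_scan: selected core %g%%>\n", x$selected))
  print(x$scan)
  invisible(x)
}

#' @rdname core_scan
#' @param x A `rada_core_scan`.
#' @param ... Unused.
#' @export
tidy.rada_core_scan <- function(x, ...) x$scan
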