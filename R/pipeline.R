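# analysis driver: configuration, the estimator x core x category sweep with
# stepwise randomization-tested identification, core-size scans, placement
# tests, result persistence and the text report.

#' Pipeline configuration
#'
#' Defaults follow the method's guidance: investigate at most five
#' estimators, and when more than two are explored drop the significance
#' gate from 0.05 to 0.01 to limit type-I errors across the sweep.
#'
#' @param estimators Estimator codes (see [hr_outlines()]).
#' @param cores Core percentage grid.
#' @param n_rand Randomization replicates.
#' @param seed Master seed; per-estimator/core streams are derived from it.
#' @param alpha Significance gate; `NULL` picks 0.01 when more than two
#'   estimators are run, 0.05 otherwise.
#' @param missing_policy See [rada_rand_config()].
#' @param tie_tol Near-tie tolerance on |r| for the prevalence tie-break.
#' @param placement See [rada_rand_config()].
#' @param handling Missing-category handling for observed fits: `"omit"` or
#'   `"beta"`.
#' @return A list of class `rada_config`.
#' @export
rada_config <- function(estimators = c("Ejt", "Kf", "Xr", "Cxs", "Cxi"),
                        cores = seq(30, 100, by = 5), n_rand = 999, seed = 1,
                        alpha = NULL, missing_policy = "omit", tie_tol = 0.05,
                        placement = "centroid", handling = "omit") {
  stopifnot(length(estimators) >= 1, all(estimators %in% HR_ESTIMATORS))
  if (length(estimators) > 5)
    warning("more than five estimators invites type-I errors; ",
            "consider a smaller set")
  if (is.null(alpha)) alpha <- if (length(estimators) > 2) 0.01 else 0.05
  stopifnot(alpha > 0, alpha < 1)
  structure(list(estimators = estimators, cores = cores,
                 n_rand = as.integer(n_rand), seed = as.integer(seed),
                 alpha = alpha, missing_policy = missing_policy,
                 tie_tol = tie_tol, placement = placement,
                 handling = handling),
            class = "rada_config")
}

sig_fn_from_null <- function(null, alpha, handling) {
  raw <- null$raw
  function(fit, step_comp, identified = integer(0)) {
    nf <- null_fits_for_code(raw, fit$category, handling, identified)
    null_r <- nf$r[nf$defined]
    k <- sum(null_r < fit$r)
    p <- min(1, 2 * (k + 1) / (length(null_r) + 1))
    list(significant = is.finite(p) && p <= alpha && fit$r < 0, p = p,
         count_below = k, null_r = null_r)
  }
}

#' Run the full analysis
#'
#' For every estimator and core percentage: estimate outlines, build the
#' composition against the map, construct the randomization null (outlines
#' resampled, rotated and displaced within the estimator's study hull),
#' identify required categories stepwise, and record per-category fit and
#' placement statistics. Identified categories are then scanned across
#' cores for the a/|b| peak and their area requirements estimated at the
#' selected core.
#'
#' @param locs Locations data frame (`animal_id`, `x`, `y`), or an outline
#'   tibble already estimated (rows for each estimator/core in `config`).
#' @param map A `categorical_map`.
#' @param config A [rada_config()].
#' @return A `rada_result` with tibbles `detail` (per estimator x core x
#'   category), `placement`, `steps`, `scans`, `estimates`, plus the
#'   outlines, compositions and a run manifest.
#' @export
run_rada <- function(locs, map, config = rada_config()) {
  outlines <- if (is.data.frame(locs) && "geometry" %in% names(locs)) locs
  else hr_outlines(locs, config$estimators, config$cores)
  detail <- list(); placements <- list(); steps_all <- list()
  comps <- list()
  idx <- 0L
  for (est in config$estimators) {
    o_est <- outlines[outlines$estimator == est, , drop = FALSE]
    if (!nrow(o_est)) next
    hull <- study_hull(o_est[o_est$core_pct == max(o_est$core_pct), ])
    for (m in sort(unique(o_est$core_pct))) {
      idx <- idx + 1L
      o <- o_est[o_est$core_pct == m, , drop = FALSE]
      comp <- build_composition(o, map)
      comps[[length(comps) + 1L]] <- comp
      cfg <- rada_rand_config(n_rand = config$n_rand,
                              seed = config$seed + 1000L * idx,
                              missing_policy = config$missing_policy,
                              placement = config$placement)
      null <- build_null(o, map, hull, cfg)
      sigfn <- sig_fn_from_null(null, config$alpha, config$handling)
      sw <- stepwise_rada(comp, sigfn, alpha = config$alpha,
                          tie_tol = config$tie_tol,
                          handling = config$handling)
      steps_all[[length(steps_all) + 1L]] <-
        dplyr::mutate(tidy(sw), estimator = est, core_pct = m, .before = 1)
      for (cd in map$categories$code) {
        st <- match(cd, sw$identified)
        f <- if (!is.na(st)) sw$steps$fit[[st]]
        else fit_loglog(comp, cd, config$handling)
        nr <- null$replicates[null$replicates$code == cd &
                                null$replicates$defined, ]
        sig <- rand_significance(if (f$defined) f$r else NA_real_, nr$r)
        detail[[length(detail) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(estimator = est, core_pct = m, code = cd,
                         label = f$label, step = st, n = f$n,
                         b = f$b, se_b = f$se_b, c = f$c, a_min = f$a_min,
                         pct_missing = f$pct_missing),
          sig)
        pres <- comp[comp$code == cd, ]
        k <- sum(pres$a_ha > 0)
        p_hat <- null$first_throw$mean_prop[match(cd, null$first_throw$code)]
        placements[[length(placements) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(estimator = est, core_pct = m, code = cd,
                         label = f$label),
          placement_test(k, nrow(pres), min(max(p_hat, 0), 1)))
      }
    }
  }
  detail <- dplyr::bind_rows(detail)
  steps_all <- dplyr::bind_rows(steps_all)
  compositions <- dplyr::bind_rows(comps)
  scans <- list(); estimates <- list()
  if (nrow(steps_all)) {
    for (est in unique(steps_all$estimator)) {
      for (cd in unique(steps_all$category[steps_all$estimator == est])) {
        rows <- detail[detail$estimator == est & detail$code == cd &
                         !is.na(detail$b) & detail$b < 0 &
                         !is.na(detail$a_min), , drop = FALSE]
        if (!nrow(rows)) next
        cs <- core_scan(tibble::tibble(core_pct = rows$core_pct, b = rows$b,
                                       a_ha = rows$a_min))
        scans[[length(scans) + 1L]] <-
          dplyr::mutate(tidy(cs), estimator = est, code = cd,
                        selected = cs$selected, .before = 1)
        sel <- cs$selected
        comp_sel <- compositions[compositions$estimator == est &
                                   compositions$core_pct == sel, ]
        f_sel <- fit_loglog(comp_sel, cd, config$handling)
        if (f_sel$defined)
          estimates[[length(estimates) + 1L]] <-
            dplyr::mutate(area_estimate(f_sel, comp_sel,
                                        alpha = config$alpha),
                          estimator = est, core_pct = sel, .before = 1)
      }
    }
  }
  structure(list(
    config = config, outlines = outlines, compositions = compositions,
    detail = detail, placement = dplyr::bind_rows(placements),
    steps = steps_all, scans = dplyr::bind_rows(scans),
    estimates = dplyr::bind_rows(estimates),
    manifest = list(seed = config$seed,
                    package_version = as.character(utils::packageVersion("rada")),
                    config = unclass(config),
                    config_hash = rlang::hash(unclass(config)))
  ), class = "rada_result")
}

#' @export
print.rada_result <- function(x, ...) {
  cat(sprintf("<rada_result: %d estimators x %d cores, %d categories>\n",
              length(x$config$estimators), length(x$config$cores),
              length(unique(x$detail$code))))
  if (nrow(x$steps)) {
    cat("identified categories:\n")
    print(x$steps[, c("estimator", "core_pct", "step", "category", "label",
                      "r", "b")])
  } else cat("no category identified\n")
  if (nrow(x$estimates))
    print(x$estimates[, c("estimator", "core_pct", "category", "recommended",
                          "estimate", "lo", "hi")])
  invisible(x)
}

result_tables <- c("detail", "placement", "steps", "scans", "estimates",
                   "compositions")

#' Persist pipeline results
#'
#' Writes the result tables as CSV, the outlines as GeoJSON, and a JSON
#' results file (tables + manifest) from which the report can be
#' regenerated.
#'
#' @param result A `rada_result`.
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_rada_results <- function(result, outdir) {
  stopifnot(inherits(result, "rada_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in result_tables) {
    tb <- result[[nm]]
    if (nm == "steps" && nrow(tb)) tb <- tb[, setdiff(names(tb), "fit")]
    utils::write.csv(tb, file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  write_outlines_geojson(result$outlines, file.path(outdir, "outlines.geojson"))
  payload <- c(lapply(result[result_tables], function(tb) {
    if ("fit" %in% names(tb)) tb <- tb[, setdiff(names(tb), "fit")]
    tb
  }), list(manifest = result$manifest))
  jsonlite::write_json(payload, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(outdir)
}

load_rada_results <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(obj[setdiff(names(obj), "manifest")], tibble::as_tibble)
  out$manifest <- obj$manifest
  out
}

fmt_p <- function(band, p) {
  if (is.na(band) || identical(band, NA_character_)) {
    if (is.na(p)) "n/a" else sprintf("p=%.3g", p)
  } else band
}

#' Human-readable summary report
#'
#' One table per estimator: for each map category, the percentage of ranges
#' containing it, the core spread with significant area-dependence, the
#' observed r (random mean in parentheses) at peak significance, its p
#' band, and the placement percentages with the binomial p. Undefined
#' entries render as "n/a".
#'
#' @param result A `rada_result`, or the path to a `results.json` written by
#'   [write_rada_results()].
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly a character vector.
#' @export
write_rada_report <- function(result, path = NULL) {
  tabs <- if (inherits(result, "rada_result")) result
  else load_rada_results(result)
  detail <- tabs$detail; placement <- tabs$placement
  alpha <- if (inherits(result, "rada_result")) result$config$alpha
  else tabs$manifest$config$alpha
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  for (est in unique(detail$estimator)) {
    add("== Estimator %s ==", est)
    add("%-14s %8s %10s %16s %8s %14s %8s", "category", "% cores",
        "sig cores", "r obs(rand)", "P", "placement %", "P")
    d_est <- detail[detail$estimator == est, ]
    p_est <- placement[placement$estimator == est, ]
    for (cd in unique(d_est$code)) {
      d <- d_est[d_est$code == cd, ]
      pl <- p_est[p_est$code == cd, ]
      pres_pct <- round(mean(100 * pl$k / pl$I))
      sig <- d[!is.na(d$p) & d$p <= alpha & !is.na(d$observed_r) &
                 d$observed_r < 0, ]
      if (nrow(sig)) {
        spread <- if (nrow(sig) > 1)
          sprintf("%g-%g", min(sig$core_pct), max(sig$core_pct))
        else sprintf("%g", sig$core_pct[1])
        best <- sig[which.min(sig$p), ]
        rtxt <- sprintf("%.2f(%.2f)", best$observed_r, best$mean_r)
        ptxt <- fmt_p(best$p_band, best$p)
      } else {
        spread <- "ns"; rtxt <- "n/a"; ptxt <- ""
      }
      pl_sig <- pl[!is.na(pl$p_value) & pl$p_value <= 0.05, ]
      if (nrow(pl_sig)) {
        best_pl <- pl_sig[which.min(pl_sig$p_value), ]
        pltxt <- sprintf("%.0f(%.0f)", best_pl$observed_pct,
                         100 * best_pl$expected_prop)
        plp <- sprintf("%.3g", best_pl$p_value)
      } else {
        pltxt <- "n/a"; plp <- ""
      }
      add("%-14s %8s %10s %16s %8s %14s %8s",
          substr(d$label[1], 1, 14), pres_pct, spread, rtxt, ptxt, pltxt, plp)
    }
    est_rows <- tabs$estimates
    if (!is.null(est_rows) && nrow(est_rows)) {
      er <- est_rows[est_rows$estimator == est, ]
      for (i in seq_len(nrow(er)))
        add("category %s at core %g%%: %s = %.3g ha (%.3g-%.3g)",
            er$label[i], er$core_pct[i], er$recommended[i], er$estimate[i],
            er$lo[i], er$hi[i])
    }
    add("")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
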