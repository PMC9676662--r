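#' Moisture content on a wet-weight basis
#'
#' `MC = (Ww - Wd) * 100 / Ww`, in percent. Vectorised; scale-invariant
#' (multiplying both weights by a constant leaves MC unchanged).
#'
#' @param wet,dry Wet and dry weights in grams; `wet >= dry > 0`.
#' @return Moisture content in percent.
#' @export
moisture_content <- function(wet, dry) {
  if (any(dry <= 0) || any(wet <= 0)) {
    abort("weights must be positive", class = "hsisort_error_stats")
  }
  if (any(dry > wet)) {
    abort("dry weight exceeds wet weight", class = "hsisort_error_stats")
  }
  (wet - dry) * 100 / wet
}

#' One-way ANOVA
#'
#' Classical one-way decomposition via [stats::aov()], returning both mean
#' squares (between and within groups), the F statistic and the p value from
#' the F distribution, plus a significance flag at the 0.05 level. When the
#' groups are identical (zero between-group variation) the F statistic is
#' reported as 0 with p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group membership (factor or coercible); at least 2 groups
#'   with at least 2 observations each.
#' @return A one-row tibble: `ms_between`, `ms_within`, `f`, `p`,
#'   `significant`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups", class = "hsisort_error_stats")
  if (any(table(groups) < 2)) abort("each group needs n >= 2", class = "hsisort_error_stats")
  fit <- summary(aov(values ~ groups))[[1]]
  ms_b <- fit["groups", "Mean Sq"]
  ms_w <- fit["Residuals", "Mean Sq"]
  f <- fit["groups", "F value"]
  p <- fit["groups", "Pr(>F)"]
  if (ms_b < 1e-300) {                  # identical groups: no between variation
    f <- 0; p <- 1
  } else if (!is.finite(f)) {           # perfect separation with zero residual
    f <- Inf; p <- 0
  }
  tibble::tibble(ms_between = ms_b, ms_within = ms_w, f = f, p = p,
                 significant = p <= 0.05)
}

#' Germination-rate report per predicted group
#'
#' Computes the germination rate (percent of seeds that germinated) within
#' each predicted viability group, the style of table used to verify a
#' sorter: the predicted-viable stream should germinate at a much higher
#' rate than the rejected stream. Empty groups report `NA`, never 0.
#'
#' @param assay Tibble with one row per seed: `predicted` (0/1 predicted
#'   group) and `germination` (0/1 outcome).
#' @param given_rate Optional baseline germination rate (%) of the unsorted
#'   lot, echoed into the report for comparison.
#' @return A list: `rates` -- tibble per predicted group (`group`, `n`,
#'   `germinated`, `rate_pct`); `comparison` -- one-row tibble with the
#'   given and final (predicted-viable) rates; `confusion` -- prediction vs
#'   outcome metrics from [evaluate_classification()].
#' @export
germination_report <- function(assay, given_rate = NA_real_) {
  stopifnot(all(c("predicted", "germination") %in% names(assay)))
  rates <- assay %>%
    group_by(group = ifelse(.data$predicted == 1, "viable", "nonviable")) %>%
    summarise(n = dplyr::n(), germinated = sum(.data$germination),
              rate_pct = 100 * mean(.data$germination), .groups = "drop")
  for (g in c("viable", "nonviable")) {
    if (!g %in% rates$group) {
      rates <- dplyr::bind_rows(rates, tibble::tibble(
        group = g, n = 0L, germinated = NA_integer_, rate_pct = NA_real_))
    }
  }
  final <- rates$rate_pct[rates$group == "viable"]
  list(rates = rates %>% arrange(dplyr::desc(.data$group)),
       comparison = tibble::tibble(given_rate_pct = given_rate,
                                   final_rate_pct = final),
       confusion = evaluate_classification(assay$predicted, assay$germination))
}

#' Viable vs nonviable group difference for one analyte
#'
#' Per variety (when a `variety` column is present, else pooled): group
#' means, their difference, a one-way ANOVA, and mean +/- sd summaries for
#' error-bar plots.
#'
#' @param assay Assay tibble with a `class` column (1 viable / 0 nonviable)
#'   and the analyte column.
#' @param analyte Name of the analyte column (e.g.
#'   `"carbohydrate_area_pct"`, `"protein_area_pct"`, `"moisture_pct"`).
#' @return A tibble with one row per variety: group means and sds,
#'   `difference`, `ms_between`, `ms_within`, `f`, `p`, `significant`.
#' @export
group_difference_report <- function(assay, analyte) {
  if (!analyte %in% names(assay)) {
    abort(sprintf("no column '%s' in the assay table", analyte),
          class = "hsisort_error_stats")
  }
  if (!"variety" %in% names(assay)) assay$variety <- "all"
  assay %>%
    group_by(.data$variety) %>%
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$class)) < 2) {
        abort("both groups must be non-empty per variety",
              class = "hsisort_error_stats")
      }
      v <- d[[analyte]]
      an <- one_way_anova(v, d$class)
      tibble::tibble(
        analyte = analyte,
        mean_viable = mean(v[d$class == 1]), sd_viable = sd(v[d$class == 1]),
        mean_nonviable = mean(v[d$class == 0]), sd_nonviable = sd(v[d$class == 0]),
        difference = mean(v[d$class == 1]) - mean(v[d$class == 0])) %>%
        dplyr::bind_cols(an)
    }) %>% ungroup()
}
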