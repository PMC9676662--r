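#' Assign calibration/validation splits
#'
#' Stratified split of a labelled spectra table into calibration and
#' validation sets. Stratification is by class label within variety, at the
#' *seed* level: both sides of a seed always land in the same split. Per
#' stratum, `round(cal_fraction * n_seeds)` seeds go to calibration. With
#' `balanced = TRUE` the input must hold equal viable/nonviable seed counts
#' per variety (the convention used to avoid class bias when building the
#' classifier).
#'
#' The default fraction is 2/3: with double-sided spectra this reproduces
#' the canonical 612-sample = 408 calibration + 204 validation layout.
#'
#' @param table Spectra tibble with `seed_id`, `side`, `variety`, `label`
#'   (0/1) and `split` columns.
#' @param cal_fraction Fraction of seeds per stratum assigned to calibration.
#' @param balanced Require equal class counts per variety.
#' @param seed Integer random seed for the stratified draw.
#' @return The table with its `split` column filled with `"calibration"` /
#'   `"validation"` (rows with missing labels stay `"unassigned"`).
#' @export
split_calibration_validation <- function(table, cal_fraction = 2 / 3,
                                         balanced = TRUE, seed = 1L) {
  stopifnot(is.data.frame(table))
  if (cal_fraction < 0 || cal_fraction > 1) {
    abort("cal_fraction must be in [0, 1]", class = "hsisort_error_split")
  }
  labelled <- table %>% filter(!is.na(.data$label))
  seeds <- labelled %>% distinct(.data$seed_id, .data$variety, .data$label)
  if (any(duplicated(seeds$seed_id))) {
    abort("a seed_id appears with conflicting variety/label",
          class = "hsisort_error_split")
  }
  if (balanced) {
    counts <- seeds %>% count(.data$variety, .data$label)
    bad <- counts %>% group_by(.data$variety) %>%
      summarise(ok = dplyr::n_distinct(.data$n) == 1 && dplyr::n() == 2) %>%
      filter(!.data$ok)
    if (nrow(bad)) {
      abort(paste0("unbalanced classes in variety ",
                   paste(bad$variety, collapse = ", "),
                   "; downsample to equal viable/nonviable counts or use balanced = FALSE"),
            class = "hsisort_error_split")
    }
  }
  withr::local_seed(seed)
  cal_ids <- seeds %>%
    group_by(.data$variety, .data$label) %>%
    slice_sample(prop = 1) %>%        # shuffle within stratum
    filter(row_number() <= round(cal_fraction * n())) %>%
    ungroup() %>% pull("seed_id")
  table %>% mutate(split = dplyr::case_when(
    is.na(.data$label) ~ "unassigned",
    .data$seed_id %in% cal_ids ~ "calibration",
    TRUE ~ "validation"))
}
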