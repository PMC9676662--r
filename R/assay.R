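#' Emit linked wet-lab assay tables for a synthetic scene
#'
#' Simulates the destructive follow-up measurements for every seed in a scene
#' truth table: gravimetric wet/dry weights (moisture content on a wet-weight
#' basis is proportional to the latent moisture level, so a seed with zero
#' moisture has wet weight equal to dry weight) and chromatographic peak
#' areas (area %) for the carbohydrate and protein analytes, linear in the
#' latent chemistry levels with magnitudes in the range reported for
#' watermelon seed endosperm. Because the generator keeps class chemistry
#' levels disjoint, at `noise_scale = 0` every viable seed's moisture
#' fraction strictly exceeds every nonviable seed's.
#'
#' @param truth Scene truth tibble from [render_scene()] (one row per seed
#'   and side; side A rows are used so each seed appears once).
#' @param noise_scale Non-negative multiplier on all measurement noise sds.
#' @param params List of assay constants: `mc_per_level` (% moisture content
#'   per unit latent moisture), `dry_weight_g` (median dry weight),
#'   `dry_sdlog`, `mc_sd` (% MC measurement sd), `area_base`, `area_gain`
#'   (peak-area % intercept/slope per analyte) and `area_sd`.
#' @param seed Integer random seed.
#' @return A tibble with one row per seed: `seed_id`, `class`,
#'   `germination`, `wet_weight_g`, `dry_weight_g`, `moisture_pct`,
#'   `carbohydrate_area_pct`, `protein_area_pct`.
#' @export
emit_assay_tables <- function(truth, noise_scale = 1,
                              params = list(mc_per_level = 11,
                                            dry_weight_g = 0.055,
                                            dry_sdlog = 0.10,
                                            mc_sd = 0.35,
                                            area_base = c(carbohydrate = 12, protein = 10),
                                            area_gain = c(carbohydrate = 30, protein = 32),
                                            area_sd = 2.5),
                              seed = 1L) {
  if (noise_scale < 0) {
    abort("noise_scale must be >= 0", class = "hsisort_error_assay")
  }
  withr::local_seed(seed)
  one <- truth %>% filter(.data$side == .data$side[[1]])
  n <- nrow(one)
  mc <- params$mc_per_level * one$moisture +
    rnorm(n, 0, noise_scale * params$mc_sd)
  mc <- pmin(pmax(mc, 0), 60)
  dry <- params$dry_weight_g * exp(rnorm(n, 0, noise_scale * params$dry_sdlog))
  wet <- dry / (1 - mc / 100)
  carb <- pmax(params$area_base[["carbohydrate"]] +
                 params$area_gain[["carbohydrate"]] * one$carbohydrate +
                 rnorm(n, 0, noise_scale * params$area_sd), 0.1)
  prot <- pmax(params$area_base[["protein"]] +
                 params$area_gain[["protein"]] * one$protein +
                 rnorm(n, 0, noise_scale * params$area_sd), 0.1)
  tibble::tibble(
    seed_id = one$seed_id, class = one$class, germination = one$germination,
    wet_weight_g = wet, dry_weight_g = dry,
    moisture_pct = (wet - dry) * 100 / wet,
    carbohydrate_area_pct = carb, protein_area_pct = prot)
}
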