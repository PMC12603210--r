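#' Published European commodity shock table (worked-example fixture)
#'
#' The ten pollination-dependent commodity accounts cultivated in Europe,
#' with their Europe-aggregate mean dependence ratio, wild-pollinator
#' contribution share, trade indicators and the resulting productivity
#' shocks (mean and 95% confidence bounds, triangular distribution).
#' Commodities not grown in Europe (oil palm, coffee, cocoa) are excluded.
#'
#' Ratios are stored as fractions (`D_mean`, `phi`); the indicator and shock
#' columns are percentages as printed. For the eight commodities flagged
#' `single_crop_consistent` the mean shock equals `D_mean * phi` (to one
#' decimal, half-up); for the two multi-crop aggregates (Other Vegetables,
#' Other Fruits) the printed shock is a value-weighted aggregate of
#' region-specific shocks and is carried as data only. `fallback_ci` marks
#' the commodity (Other Cereals, whose only dependent crop is buckwheat)
#' whose bounds use the +/-50% proportional fallback instead of triangular
#' quantiles. `phi_imputed` marks commodities (Tomatoes, Soya) whose wild
#' contribution was imputed with the cross-crop average.
#'
#' @return A ten-row tibble; see Details for column semantics.
#' @export
table1_fixture <- function() {
  tibble(
    commodity = c("Other Cereals", "Pulses", "Rapeseed", "Sunflower", "Soya",
                  "Tomatoes", "Other Vegetables", "Apples", "Citrus Fruits",
                  "Other Fruits"),
    group = c("other_cereals_crops", "other_cereals_crops", "oilseeds",
              "oilseeds", "oilseeds", "vegetables_fruits", "vegetables_fruits",
              "vegetables_fruits", "vegetables_fruits", "vegetables_fruits"),
    europe_share_global_pct = c(13.7, 9.1, 32.6, 64.7, 5.0,
                                24.8, 7.5, 14.5, 6.1, 8.0),
    value_share_europe_pct = c(1.6, 2.2, 6.0, 5.9, 2.0,
                               16.0, 39.3, 5.3, 2.9, 18.8),
    self_sufficiency_pct = c(76.3, 103.4, 87.3, 104.6, 50.2,
                             99.0, 91.3, 93.7, 45.4, 57.7),
    export_intensity_pct = c(0.3, 13.1, 26.6, 11.1, 18.0,
                             7.8, 1.6, 8.3, 2.0, 9.1),
    import_penetration_pct = c(23.9, 10.2, 35.9, 7.0, 58.8,
                               8.7, 10.2, 14.1, 55.5, 47.5),
    D_mean = c(0.187, 0.092, 0.270, 0.540, 0.190,
               0.270, 0.381, 0.666, 0.513, 0.610),
    phi = c(0.230, 0.760, 0.596, 0.147, 0.504,
            0.504, 0.760, 0.429, 0.155, 0.481),
    shock_mean_pct = c(4.3, 7.0, 16.1, 7.9, 9.6, 13.6, 28.9, 28.6, 8.0, 29.4),
    shock_low_pct = c(2.2, 4.2, 4.1, 2.6, 2.1, 3.0, 25.3, 7.2, 6.1, 23.1),
    shock_high_pct = c(6.5, 9.1, 36.1, 12.3, 16.6, 23.3, 32.2, 37.1, 9.7, 33.3),
    fallback_ci = c(TRUE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE),
    phi_imputed = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                    TRUE, FALSE, FALSE, FALSE, FALSE),
    single_crop_consistent = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                               TRUE, FALSE, TRUE, TRUE, FALSE))
}
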