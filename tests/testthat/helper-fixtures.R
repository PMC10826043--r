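# fits used across tests: the published alpha-amylase single-agent parameters
acarbose_fit <- function() {
  median_effect_fit(dm = 0.061, m = 1.32, r = 1.00, dose_unit = "mM",
                    agent = "acarbose")
}
propolis_fit <- function() {
  median_effect_fit(dm = 1.07, m = 0.512, r = 1.00, dose_unit = "mg/mL",
                    agent = "propolis")
}
kaempferol_fit <- function() {
  median_effect_fit(dm = 4.84, m = 1.18, r = 1.00, dose_unit = "mM",
                    agent = "kaempferol")
}

# noiseless dose-effect table generated exactly from a medfit
exact_points <- function(fit, doses = fit$dm * 2^seq(-2, 2)) {
  data.frame(dose = doses, fa = effect_at_dose(fit, doses))
}

# decimals of the published table entries: 3 below 1, 2 below 10, 1 above
printed_decimals <- function(x) ifelse(abs(x) < 1, 3L, ifelse(abs(x) < 10, 2L, 1L))
printed_ulp <- function(x) 10^(-printed_decimals(x))
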