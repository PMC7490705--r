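# Small season specs reused across tests.

tiny_season <- function(rng_seed = 1L, mean_total_seeds = 500,
                        sampled_fraction = 0.16, dispersion = 1,
                        n_weeks = 8L) {
  season_spec(
    n_weeks = n_weeks,
    weekly_containers = 30L,
    taxa = list(taxon_spec(
      "T", mean_total_seeds = mean_total_seeds,
      peak_day = round(n_weeks * 7 / 2), peak_width_days = 10,
      dispersion = dispersion
    )),
    sampled_fraction = sampled_fraction,
    rng_seed = rng_seed
  )
}

# Season emulating the study scale: ~1,900 containers over 32 weeks,
# biweekly visits at 16% coverage, one Saccharum-like taxon.
study_scale_season <- function(rng_seed) {
  season_spec(
    taxa = list(taxon_spec(
      "Saccharum-like", mean_total_seeds = 10000,
      peak_day = 100, peak_width_days = 20, dispersion = 1,
      germination_true = 0.09, survival_true = 0.47
    )),
    rng_seed = rng_seed
  )
}
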