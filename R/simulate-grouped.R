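#' Simulate a clustered (culture / neuron) grouped sample
#'
#' Generates log-normal observations with the nesting structure of
#' super-resolution cluster metrics: values from neurons within cultures,
#' two conditions, unequal per-neuron counts. On the log scale the model is
#' `log v = culture effect + neuron effect + noise`, with a multiplicative
#' `effect` applied to the treated condition. Used to calibrate and power
#' the balanced Monte-Carlo Mann-Whitney procedure; `effect = 1` gives a
#' null dataset (both conditions from the same distribution).
#'
#' Defaults describe mild-but-present between-cell variability: 2 cultures,
#' 5 neurons per condition per culture, per-neuron counts Poisson(25)
#' clamped to at least 15, culture log-sd 0.3, neuron log-sd 0.1, within-
#' neuron log-sd 0.5.
#'
#' @param n_cultures number of cultures.
#' @param neurons_per_condition neurons per condition in each culture.
#' @param mean_obs_per_neuron Poisson mean of the per-neuron observation
#'   count.
#' @param min_obs_per_neuron lower clamp on the per-neuron count.
#' @param culture_sd,neuron_sd,within_sd log-scale standard deviations.
#' @param effect multiplicative shift of the treated condition (1 = null).
#' @param seed optional integer seed.
#' @return `data.frame` with columns `value`, `condition`, `culture`,
#'   `neuron` (neuron ids unique across cultures and conditions).
#' @export
simulate_grouped_sample <- function(n_cultures = 2L,
                                    neurons_per_condition = 5L,
                                    mean_obs_per_neuron = 25,
                                    min_obs_per_neuron = 15L,
                                    culture_sd = 0.3,
                                    neuron_sd = 0.1,
                                    within_sd = 0.5,
                                    effect = 1,
                                    seed = NULL) {
  stopifnot(effect > 0)
  .local_seed(seed)
  rows <- list()
  nid <- 0L
  for (cu in seq_len(n_cultures)) {
    cu_eff <- rnorm(1, 0, culture_sd)
    for (cond in c("control", "treated")) {
      for (ne in seq_len(neurons_per_condition)) {
        nid <- nid + 1L
        n_obs <- max(rpois(1, mean_obs_per_neuron), min_obs_per_neuron)
        lv <- cu_eff + rnorm(1, 0, neuron_sd) + rnorm(n_obs, 0, within_sd) +
          (cond == "treated") * log(effect)
        rows[[nid]] <- data.frame(
          value = exp(lv), condition = cond, culture = cu, neuron = nid
        )
      }
    }
  }
  do.call(rbind, rows)
}
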