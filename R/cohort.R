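#' Sample a cohort of participant traits
#'
#' Draws trait-like individual differences for `n` participants from a
#' documented multivariate distribution. Four latent standard-normal scores
#' (attentive speed, attentive dispersion, lapse propensity, homeostatic
#' gain) share a correlation structure in which the two speed traits and the
#' two vulnerability traits are cross-correlated at
#' `config$trait_correlation`; circadian amplitude/phase and the time-on-task
#' gain are drawn independently. Traits are constant across all sessions of a
#' participant.
#'
#' @param n number of participants (>= 2).
#' @param config a [pvt_protocol()] object.
#' @return A `data.frame` with one row per participant and columns
#'   `participant_id`, `base_speed` (mean log attentive RT, log-ms),
#'   `base_sd` (attentive RT dispersion, log-ms), `lapse_propensity`
#'   (baseline log-odds of a lapse-state trial), `homeo_gain` (initial
#'   increase in lapse log-odds per hour awake beyond 16 h), `circ_amp`,
#'   `circ_phase` (hours after wake of the circadian alertness minimum) and
#'   `tot_gain` (lapse log-odds per minute of time on task).
#' @examples
#' cohort <- sample_cohort(8, pvt_protocol(seed = 42))
#' @export
sample_cohort <- function(n, config = pvt_protocol()) {
  assert_that(is.numeric(n) && length(n) == 1 && n >= 2,
              "n must be a single number >= 2")
  n <- as.integer(n)
  tp <- config$traits
  rho <- config$trait_correlation

  # correlation of (speed, dispersion, propensity, gain)
  R <- matrix(rho, 4, 4)
  diag(R) <- 1
  R[1, 2] <- R[2, 1] <- tp$speed_sd_cor
  R[3, 4] <- R[4, 3] <- tp$propensity_gain_cor
  L <- tryCatch(chol(R), error = function(e) {
    stop("trait correlation settings do not form a positive-definite matrix")
  })

  with_seed(derive_seed(config$seed, 101L), {
    z <- matrix(stats::rnorm(n * 4), n, 4) %*% L
    extra <- matrix(stats::rnorm(n * 3), n, 3)
    data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      base_speed = tp$base_speed_mean + tp$base_speed_sd * z[, 1],
      base_sd = tp$base_sd_mean * exp(tp$base_sd_spread * z[, 2]),
      lapse_propensity = tp$lapse_propensity_mean +
        tp$lapse_propensity_sd * z[, 3],
      homeo_gain = tp$homeo_gain_mean + tp$homeo_gain_sd * z[, 4],
      circ_amp = abs(tp$circ_amp_mean + tp$circ_amp_sd * extra[, 1]),
      circ_phase = tp$circ_phase_mean + tp$circ_phase_sd * extra[, 2],
      tot_gain = tp$tot_gain_mean + tp$tot_gain_sd * extra[, 3],
      stringsAsFactors = FALSE
    )
  })
}

#' Representative trait profiles
#'
#' Returns the expected trait values of a participant at the centre of a
#' vulnerability group under the default trait distribution: the group mean
#' of a quartile of a standard normal sits at |z| = 1.27, so the
#' `"vulnerable"` (`"resilient"`) profile places lapse propensity and
#' homeostatic gain at +1.27 (-1.27) population SDs; `"intermediate"` uses
#' the population means.
#'
#' @param group one of `"resilient"`, `"intermediate"`, `"vulnerable"`.
#' @param config a [pvt_protocol()] object.
#' @return A one-row `data.frame` in the [sample_cohort()] layout.
#' @export
example_traits <- function(group = c("intermediate", "resilient", "vulnerable"),
                           config = pvt_protocol()) {
  group <- match.arg(group)
  tp <- config$traits
  # E[Z | Z in top quartile] for a standard normal
  zq <- stats::dnorm(stats::qnorm(0.75)) / 0.25
  z <- switch(group, resilient = -zq, intermediate = 0, vulnerable = zq)
  data.frame(
    participant_id = paste0("example_", group),
    base_speed = tp$base_speed_mean + tp$base_speed_sd * config$trait_correlation * z,
    base_sd = tp$base_sd_mean,
    lapse_propensity = tp$lapse_propensity_mean + tp$lapse_propensity_sd * z,
    homeo_gain = tp$homeo_gain_mean + tp$homeo_gain_sd * z,
    circ_amp = tp$circ_amp_mean,
    circ_phase = tp$circ_phase_mean,
    tot_gain = tp$tot_gain_mean,
    stringsAsFactors = FALSE
  )
}
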