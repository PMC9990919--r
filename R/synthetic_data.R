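#' Configuration for the synthetic behavioral-data generator
#'
#' The generator uses a latent-trait (item-response-style) model of a 2AFC
#' task. Each participant p has a general ability a_p ~ N(0, ability_sd),
#' each question q an easiness e_q ~ N(0, easiness_sd), and each cell a
#' question-specific knowledge term k_pq ~ N(0, item_knowledge_sd). The
#' latent evidence s_pq = a_p + e_q + k_pq drives both the response,
#'
#'   correct_pq ~ Bernoulli(plogis(s_pq)),
#'
#' and the confidence rating,
#'
#'   confidence_pq = 100 * plogis(calib_intercept + calib_slope * s_pq + eps_pq),
#'   eps_pq ~ N(0, confidence_noise_sd).
#'
#' Because k_pq informs accuracy only on question q, confidence is more
#' predictive of accuracy within a question than between questions; the
#' between-question association is carried by ability alone. Setting
#' `calib_slope <= 0` produces an uncalibrated ("wicked") environment in
#' which confidence does not track accuracy.
#'
#' Defaults mirror the shape of a ~150-participant, 70-question population
#' inference task; see [task_shapes()] for the companion 149 x 25 shape.
#'
#' @param n_participants,n_questions design size (both >= 2).
#' @param ability_sd SD of participant general ability (>= 0).
#' @param easiness_sd SD of question easiness (>= 0).
#' @param item_knowledge_sd SD of participant-by-question knowledge (>= 0).
#' @param calib_intercept confidence calibration intercept (logit scale).
#' @param calib_slope confidence-evidence coupling; 0 decouples confidence
#'   from accuracy, negative values yield anti-calibration.
#' @param confidence_noise_sd SD of confidence noise on the logit scale (>= 0).
#' @param seed integer seed; identical configs give bit-identical datasets.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 150,
                             n_questions = 70,
                             ability_sd = 0.3,
                             easiness_sd = 0.7,
                             item_knowledge_sd = 1.0,
                             calib_intercept = 0,
                             calib_slope = 1,
                             confidence_noise_sd = 0.5,
                             seed = 1) {
  n_participants <- check_count(n_participants, "n_participants", lower = 2L)
  n_questions <- check_count(n_questions, "n_questions", lower = 2L)
  check_scalar_number(ability_sd, "ability_sd", lower = 0)
  check_scalar_number(easiness_sd, "easiness_sd", lower = 0)
  check_scalar_number(item_knowledge_sd, "item_knowledge_sd", lower = 0)
  check_scalar_number(calib_intercept, "calib_intercept")
  check_scalar_number(calib_slope, "calib_slope")
  check_scalar_number(confidence_noise_sd, "confidence_noise_sd", lower = 0)
  check_scalar_number(seed, "seed")
  structure(list(n_participants = n_participants,
                 n_questions = n_questions,
                 ability_sd = ability_sd,
                 easiness_sd = easiness_sd,
                 item_knowledge_sd = item_knowledge_sd,
                 calib_intercept = calib_intercept,
                 calib_slope = calib_slope,
                 confidence_noise_sd = confidence_noise_sd,
                 seed = seed),
            class = "generator_config")
}

#' Canonical task shapes
#'
#' The two study designs emulated by the generator: a 150-participant,
#' 70-question "population inference" task and a 149-participant,
#' 25-question "relationships comparison" task.
#'
#' @return named list of (n_participants, n_questions) pairs.
#' @export
task_shapes <- function() {
  list(population_inference = c(n_participants = 150, n_questions = 70),
       relationships_comparison = c(n_participants = 149, n_questions = 25))
}

#' Generate a synthetic behavioral dataset
#'
#' Draws a complete participants x questions table from the latent-trait
#' model described in [generator_config()]. Randomness is organised in
#' deterministic substreams: abilities use one substream, and each
#' question's easiness, knowledge, response and confidence draws use a
#' substream keyed by the question index, so adding questions never
#' perturbs the draws of earlier questions.
#'
#' @param config a [generator_config()].
#' @param task_name label stored on the dataset.
#' @param keep_latent attach the latent evidence matrix s_pq (participants
#'   x questions) as attribute `latent_evidence`; `plogis(s_pq)` is the
#'   true per-cell probability of a correct response.
#' @return a [behavioral_dataset()].
#' @export
#' @examples
#' d <- generate_dataset(generator_config(n_participants = 20, n_questions = 5))
#' mean(d$correct)
generate_dataset <- function(config, task_name = "synthetic",
                             keep_latent = FALSE) {
  if (!inherits(config, "generator_config")) {
    stopf("`config` must be a generator_config.")
  }
  np <- config$n_participants
  nq <- config$n_questions
  pid <- sprintf("P%03d", seq_len(np))
  qid <- sprintf("Q%03d", seq_len(nq))

  ability <- with_seed(substream_seed(config$seed, 0),
                       stats::rnorm(np, 0, config$ability_sd))

  correct <- matrix(NA_real_, np, nq)
  confid <- matrix(NA_real_, np, nq)
  latent <- if (keep_latent) matrix(NA_real_, np, nq,
                                    dimnames = list(pid, qid))
  for (q in seq_len(nq)) {
    draws <- with_seed(substream_seed(config$seed, q), {
      easiness <- stats::rnorm(1, 0, config$easiness_sd)
      knowledge <- stats::rnorm(np, 0, config$item_knowledge_sd)
      u <- stats::runif(np)
      eps <- stats::rnorm(np, 0, config$confidence_noise_sd)
      list(easiness = easiness, knowledge = knowledge, u = u, eps = eps)
    })
    s <- ability + draws$easiness + draws$knowledge
    if (keep_latent) latent[, q] <- s
    correct[, q] <- as.numeric(draws$u < stats::plogis(s))
    confid[, q] <- 100 * stats::plogis(config$calib_intercept +
                                         config$calib_slope * s + draws$eps)
  }

  data <- behavioral_dataset(
    tibble::tibble(participant_id = rep(pid, times = nq),
                   question_id = rep(qid, each = np),
                   correct = as.vector(correct),
                   confidence = as.vector(confid)),
    task_name = task_name)
  if (keep_latent) attr(data, "latent_evidence") <- latent
  data
}
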