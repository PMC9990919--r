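#' Logistic regression of accuracy on confidence
#'
#' Fits P(correct = 1) = plogis(alpha + beta * confidence) by maximum
#' likelihood and reports the confidence slope `beta` (log-odds change in
#' the probability of a correct response per unit of 0-100 confidence)
#' with a 95% Wald interval.
#'
#' The fit is flagged `converged = FALSE` rather than erroring when the
#' likelihood is degenerate or (quasi-)separated: all responses identical,
#' IRLS non-convergence, a non-finite standard error, near-zero residual
#' deviance (perfect separation), or |beta| above `beta_cap`. Downstream
#' summaries drop non-converged fits, mirroring the exclusion of
#' non-converged estimates in MCMC-based analyses.
#'
#' @param confidence numeric vector of confidence ratings.
#' @param correct 0/1 vector of the same length (>= 2).
#' @param level interval coverage, default 0.95.
#' @param beta_cap absolute slope above which the fit is treated as
#'   separated; 50 per unit confidence is far outside any plausible
#'   calibration slope.
#' @return one-row tibble: `independent_question`, `dependent_question`
#'   (both `NA` here; filled by the dataset-level analyses), `beta`,
#'   `ci_low`, `ci_high`, `converged`.
#' @export
fit_confidence_logistic <- function(confidence, correct, level = 0.95,
                                    beta_cap = 50) {
  if (length(confidence) != length(correct)) {
    stopf("`confidence` and `correct` must have the same length.")
  }
  if (length(correct) < 2L) stopf("need at least 2 observations.")
  if (!all(correct %in% c(0, 1))) stopf("`correct` must be 0/1.")

  est <- tibble::tibble(independent_question = NA_character_,
                        dependent_question = NA_character_,
                        beta = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, converged = FALSE)

  if (length(unique(correct)) < 2L || stats::var(confidence) == 0) {
    return(est)  # degenerate likelihood: slope unidentified
  }

  fit <- suppressWarnings(
    stats::glm(correct ~ confidence, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- unname(stats::coef(fit)["confidence"])
  se <- sqrt(diag(stats::vcov(fit)))["confidence"]
  separated <- fit$deviance < 1e-7
  ok <- fit$converged && is.finite(beta) && is.finite(se) &&
    abs(beta) <= beta_cap && !separated

  if (ok) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    est$beta <- beta
    est$ci_low <- beta - z * se
    est$ci_high <- beta + z * se
    est$converged <- TRUE
  }
  est
}

#' Within-question prediction of accuracy from confidence
#'
#' For each question, regresses the participants' correctness on their
#' confidence in that same question. One estimate per question, in the
#' dataset's question order.
#'
#' @param data a [behavioral_dataset()].
#' @inheritParams fit_confidence_logistic
#' @return tibble of coefficient estimates, one row per question, with
#'   `independent_question == dependent_question`.
#' @export
within_question_analysis <- function(data, level = 0.95, beta_cap = 50) {
  conf <- response_matrix(data, "confidence")
  corr <- response_matrix(data, "correct")
  qs <- questions(data)
  out <- lapply(seq_along(qs), function(q) {
    est <- fit_confidence_logistic(conf[, q], corr[, q],
                                   level = level, beta_cap = beta_cap)
    est$independent_question <- qs[q]
    est$dependent_question <- qs[q]
    est
  })
  do.call(rbind, out)
}

#' Ordered question pairs of a dataset
#'
#' All ordered pairs (i, j), i != j, of the dataset's questions: the pair
#' lattice over which the between-question analysis runs, n*(n-1) rows.
#'
#' @param question_ids character vector of question ids.
#' @return tibble with columns `independent_question`, `dependent_question`.
#' @export
question_pairs <- function(question_ids) {
  grid <- expand.grid(dependent_question = question_ids,
                      independent_question = question_ids,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$independent_question != grid$dependent_question,
               c("independent_question", "dependent_question")]
  # order by independent question first, then dependent
  grid <- grid[order(match(grid$independent_question, question_ids),
                     match(grid$dependent_question, question_ids)), ]
  tibble::as_tibble(grid)
}

#' Between-question prediction of accuracy from confidence
#'
#' For every ordered pair of distinct questions (i, j), regresses each
#' participant's correctness on question j on their confidence in
#' question i. A 70-question task yields 4,830 fits; a 25-question task
#' yields 600.
#'
#' @inheritParams within_question_analysis
#' @return tibble of coefficient estimates, one row per ordered pair.
#' @export
between_question_analysis <- function(data, level = 0.95, beta_cap = 50) {
  conf <- response_matrix(data, "confidence")
  corr <- response_matrix(data, "correct")
  qs <- questions(data)
  pairs <- question_pairs(qs)
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$independent_question[r]
    j <- pairs$dependent_question[r]
    est <- fit_confidence_logistic(conf[, i], corr[, j],
                                   level = level, beta_cap = beta_cap)
    est$independent_question <- i
    est$dependent_question <- j
    out[[r]] <- est
  }
  do.call(rbind, out)
}

#' Exclude questions, pairs and non-converged fits
#'
#' Removes every estimate whose independent or dependent question is
#' excluded, every estimate matching an excluded ordered (independent,
#' dependent) pair, and every non-converged estimate.
#'
#' @param estimates tibble of coefficient estimates.
#' @param excluded_questions character vector of question ids.
#' @param excluded_pairs data frame with columns `independent_question`
#'   and `dependent_question`, or a list of length-2 vectors
#'   `c(independent, dependent)`.
#' @return the filtered estimates tibble.
#' @export
apply_exclusions <- function(estimates,
                             excluded_questions = character(),
                             excluded_pairs = NULL) {
  keep <- estimates$converged &
    !(estimates$independent_question %in% excluded_questions) &
    !(estimates$dependent_question %in% excluded_questions)
  if (!is.null(excluded_pairs)) {
    if (is.list(excluded_pairs) && !is.data.frame(excluded_pairs)) {
      excluded_pairs <- do.call(rbind, lapply(excluded_pairs, function(p) {
        data.frame(independent_question = p[[1]], dependent_question = p[[2]])
      }))
    }
    key <- paste(estimates$independent_question,
                 estimates$dependent_question, sep = "\r")
    ex_key <- paste(excluded_pairs$independent_question,
                    excluded_pairs$dependent_question, sep = "\r")
    keep <- keep & !(key %in% ex_key)
  }
  estimates[keep, ]
}

#' Summarize a set of confidence-slope estimates
#'
#' Mean and SD of the slopes, and the proportion of estimates whose 95%
#' interval excludes zero (the cases where confidence reliably predicts
#' accuracy). Non-converged estimates are dropped first.
#'
#' @param estimates tibble of coefficient estimates.
#' @return one-row tibble: `n_estimates`, `mean_beta`, `sd_beta`,
#'   `prop_ci_excluding_zero`.
#' @export
summarize_coefficients <- function(estimates) {
  estimates <- estimates[estimates$converged, ]
  if (nrow(estimates) == 0L) {
    stopf("no converged estimates to summarize.")
  }
  excl0 <- estimates$ci_low > 0 | estimates$ci_high < 0
  tibble::tibble(n_estimates = nrow(estimates),
                 mean_beta = mean(estimates$beta),
                 sd_beta = stats::sd(estimates$beta),
                 prop_ci_excluding_zero = mean(excl0))
}
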