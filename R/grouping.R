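#' Rank participants by mean confidence on training questions
#'
#' Participants are sorted in descending order of their mean confidence
#' over the given training questions. Exact ties (rare with a continuous
#' 0-100 scale) are broken uniformly at random under `tie_seed`, so the
#' ranking is reproducible without biasing either tied participant.
#'
#' @param data a [behavioral_dataset()].
#' @param training_questions non-empty vector of question ids in `data`.
#' @param tie_seed integer seed for tie-breaking.
#' @return tibble of class `confidence_ranking` with columns
#'   `participant_id` and `mean_confidence`, best-ranked first.
#' @export
rank_by_confidence <- function(data, training_questions, tie_seed = 1) {
  if (length(training_questions) == 0L) {
    stopf("`training_questions` must be non-empty.")
  }
  unknown <- setdiff(training_questions, questions(data))
  if (length(unknown) > 0) {
    stopf("unknown question id(s): %s", paste(unknown, collapse = ", "))
  }
  conf <- response_matrix(data, "confidence")
  mc <- rowMeans(conf[, training_questions, drop = FALSE])
  jitter_rank <- with_seed(tie_seed, sample.int(length(mc)))
  ord <- order(-mc, jitter_rank)
  structure(tibble::tibble(participant_id = names(mc)[ord],
                           mean_confidence = unname(mc[ord])),
            tie_seed = tie_seed,
            class = c("confidence_ranking", class(tibble::tibble())))
}

#' Member-selection scheme
#'
#' Describes how a group is drawn from a confidence ranking. `category`
#' fixes the eligible pool: `highest` = the top `group_size` ranks,
#' `higher` = the above-median ranks 1..ceiling(N/2), `mixed` = all ranks.
#' `mode` fixes how members are taken from the pool: `stride` picks
#' deterministic, evenly spaced rank positions spanning the pool;
#' `random` samples uniformly without replacement (for `highest` the two
#' modes coincide: ranks 1..group_size).
#'
#' @param category one of `"highest"`, `"higher"`, `"mixed"`.
#' @param mode `"stride"` or `"random"`.
#' @param group_size number of members to select.
#' @return list of class `selection_scheme`.
#' @export
selection_scheme <- function(category = c("highest", "higher", "mixed"),
                             mode = c("stride", "random"),
                             group_size = 15) {
  category <- match.arg(category)
  mode <- match.arg(mode)
  group_size <- check_count(group_size, "group_size", lower = 1L)
  structure(list(category = category, mode = mode, group_size = group_size),
            class = "selection_scheme")
}

# Deterministic stride positions: g evenly spaced ranks over a pool of
# size `pool`, starting at rank 1 with step pool/g. With 150 participants
# and g = 15 this gives 1,6,...,71 (higher, pool 75) and 1,11,...,141
# (mixed, pool 150); for pool == g it degenerates to ranks 1..g.
stride_positions <- function(pool, group_size) {
  1 + round((seq_len(group_size) - 1) * pool / group_size)
}

#' Select group members from a confidence ranking
#'
#' @param ranking a [rank_by_confidence()] result.
#' @param scheme a [selection_scheme()].
#' @param rng_seed integer seed used by `mode = "random"`.
#' @return character vector of `group_size` participant ids.
#' @export
select_members <- function(ranking, scheme, rng_seed = 1) {
  if (!inherits(scheme, "selection_scheme")) {
    stopf("`scheme` must be a selection_scheme.")
  }
  n <- nrow(ranking)
  g <- scheme$group_size
  pool <- switch(scheme$category,
                 highest = g,
                 higher = ceiling(n / 2),
                 mixed = n)
  if (g > pool || pool > n) {
    stopf("group_size %d exceeds the eligible pool (%d of %d participants).",
          g, min(pool, n), n)
  }
  ranks <- if (scheme$mode == "stride" || scheme$category == "highest") {
    stride_positions(pool, g)
  } else {
    with_seed(rng_seed, sample.int(pool, g))
  }
  ranking$participant_id[ranks]
}

#' Majority vote over a binary choice
#'
#' Returns the alternative chosen by a strict majority. On an exact tie
#' the vote is decided uniformly at random under `tie_seed`; without a
#' tie seed a tie is an error.
#'
#' @param choices non-empty vector over two alternatives (e.g. "A"/"B" or 0/1).
#' @param tie_seed optional integer seed for tie-breaking.
#' @return the winning alternative.
#' @export
majority_vote <- function(choices, tie_seed = NULL) {
  if (length(choices) == 0L) stopf("`choices` must be non-empty.")
  tab <- table(choices)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) {
    winner <- top
  } else if (!is.null(tie_seed)) {
    winner <- with_seed(tie_seed, sample(top, 1L))
  } else {
    stopf("majority vote is tied and no `tie_seed` was given.")
  }
  if (is.numeric(choices)) as.numeric(winner) else winner
}

#' Confidence-weighted vote
#'
#' Each alternative scores the sum of the confidence ratings of the
#' members who chose it; the alternative with the larger sum wins. For
#' example, three members choosing A with confidences 20, 30, 40 lose to
#' two members choosing B with confidences 80 and 90 (sums 90 vs 170),
#' even though A holds the majority.
#'
#' @param choices vector over two alternatives.
#' @param confidences non-negative numeric vector, same length.
#' @return list with `choice` (the winner) and `winning_sum`.
#' @export
weighted_confidence_vote <- function(choices, confidences) {
  if (length(choices) != length(confidences)) {
    stopf("`choices` and `confidences` must have the same length.")
  }
  if (length(choices) == 0L) stopf("`choices` must be non-empty.")
  if (any(confidences < 0)) stopf("`confidences` must be >= 0.")
  sums <- tapply(confidences, as.character(choices), sum)
  if (length(sums) > 1L && length(unique(sums)) == 1L) {
    stopf("weighted vote is tied (equal confidence sums).")
  }
  winner <- names(sums)[which.max(sums)]
  if (is.numeric(choices)) {
    list(choice = as.numeric(winner), winning_sum = unname(max(sums)))
  } else {
    list(choice = winner, winning_sum = unname(max(sums)))
  }
}

#' Transmission-chain aggregation
#'
#' Members are polled sequentially. The first member's choice is adopted
#' unconditionally; each later member overwrites the running collective
#' solution if and only if their confidence is at least `threshold`. The
#' final solution is the group judgment.
#'
#' @param choices ordered vector over two alternatives.
#' @param confidences ordered numeric vector, same length; the first
#'   entry is never consulted.
#' @param threshold confidence needed to overwrite the running solution.
#' @return the final collective choice.
#' @export
transmission_chain <- function(choices, confidences, threshold = 50) {
  if (length(choices) == 0L) stopf("`choices` must be non-empty.")
  if (length(choices) != length(confidences)) {
    stopf("`choices` and `confidences` must have the same length.")
  }
  current <- choices[1]
  for (i in seq_along(choices)[-1]) {
    if (!is.na(confidences[i]) && confidences[i] >= threshold) {
      current <- choices[i]
    }
  }
  current
}

#' Accordance rate between two response vectors
#'
#' The fraction of positions at which two responders gave the same
#' answer: 1 minus the normalized Hamming distance. Two responders
#' answering "1 0 0 0 1 1 1 0 1" and "1 1 0 1 1 0 1 0 0" accord on 5 of
#' 9 questions, rate 5/9.
#'
#' @param responses_x,responses_y equal-length non-empty vectors.
#' @return accordance rate in [0, 1].
#' @export
accordance_rate <- function(responses_x, responses_y) {
  if (length(responses_x) != length(responses_y)) {
    stopf("response vectors must have the same length.")
  }
  if (length(responses_x) == 0L) stopf("response vectors must be non-empty.")
  mean(responses_x == responses_y)
}

#' Group accuracy under an aggregation rule
#'
#' For each question, aggregates the members' choices by the given rule
#' and scores 1 if the group judgment equals the true alternative;
#' returns the mean over questions. Choices enter as the correctness
#' indicator, so "the group is correct" means the rule selects the true
#' alternative.
#'
#' @param data a [behavioral_dataset()].
#' @param members participant ids forming the group.
#' @param question_ids questions the group judges.
#' @param rule `"majority"`, `"weighted"` or `"chain"`.
#' @param tie_seed integer seed for majority ties (even group sizes);
#'   `NULL` turns a tie into an error.
#' @param chain_threshold confidence threshold for `rule = "chain"`.
#' @return proportion of questions judged correctly, in [0, 1].
#' @export
group_accuracy <- function(data, members, question_ids,
                           rule = c("majority", "weighted", "chain"),
                           tie_seed = NULL, chain_threshold = 50) {
  rule <- match.arg(rule)
  if (length(setdiff(members, participants(data))) > 0) {
    stopf("unknown participant id(s) in `members`.")
  }
  if (length(setdiff(question_ids, questions(data))) > 0) {
    stopf("unknown question id(s).")
  }
  corr <- response_matrix(data, "correct")[members, question_ids, drop = FALSE]
  conf <- response_matrix(data, "confidence")[members, question_ids, drop = FALSE]
  m <- length(members)
  ok <- vapply(seq_along(question_ids), function(q) {
    switch(rule,
      majority = {
        votes_true <- sum(corr[, q])
        if (votes_true * 2 == m) {
          if (is.null(tie_seed)) stopf("majority vote is tied and no `tie_seed` was given.")
          with_seed(substream_seed(tie_seed, q), stats::runif(1) < 0.5)
        } else {
          votes_true * 2 > m
        }
      },
      weighted = {
        v <- weighted_confidence_vote(corr[, q], conf[, q])
        v$choice == 1
      },
      chain = transmission_chain(corr[, q], conf[, q], chain_threshold) == 1
    )
  }, logical(1))
  mean(ok)
}

# Fast majority-rule group accuracy on a 0/1 members x questions matrix.
# Even-size ties are broken by iid fair coin flips drawn from the current
# RNG stream. Used by the simulation drivers.
majority_accuracy_matrix <- function(corr) {
  m <- nrow(corr)
  votes_true <- colSums(corr)
  ok <- votes_true * 2 > m
  tie <- votes_true * 2 == m
  if (any(tie)) ok[tie] <- stats::runif(sum(tie)) < 0.5
  mean(ok)
}
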