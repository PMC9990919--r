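#' Train/test split of a dataset's questions
#'
#' Draws `n_train` training questions and `n_test` disjoint test
#' questions without replacement from the current RNG stream.
#'
#' @param question_ids character vector of available question ids.
#' @param n_train,n_test sizes of the two disjoint sets.
#' @return list of class `split_design` with `training_questions` and
#'   `test_questions`.
#' @export
split_questions <- function(question_ids, n_train, n_test) {
  n_train <- check_count(n_train, "n_train")
  n_test <- check_count(n_test, "n_test")
  if (n_train + n_test > length(question_ids)) {
    stopf("n_train + n_test (%d) exceeds the %d available questions.",
          n_train + n_test, length(question_ids))
  }
  picked <- sample(question_ids, n_train + n_test)
  structure(list(training_questions = picked[seq_len(n_train)],
                 test_questions = picked[n_train + seq_len(n_test)]),
            class = "split_design")
}

# Mean pairwise accordance over all unordered pairs of rows of a 0/1
# matrix, computed from per-question vote counts: a question with c ones
# among m rows contributes choose(c,2) + choose(m-c,2) agreeing pairs.
pairwise_accordance <- function(mat) {
  m <- nrow(mat)
  cts <- colSums(mat)
  agree <- choose(cts, 2) + choose(m - cts, 2)
  sum(agree) / (choose(m, 2) * ncol(mat))
}

#' Simulation 1: pairwise accordance rates by confidence category
#'
#' Each iteration draws `n_sample_questions` questions, uses the first as
#' the single training question and the rest as test questions, ranks all
#' participants by their confidence on the training question, and forms a
#' panel of `panel_size` members for each category by deterministic
#' stride positions (highest = ranks 1..15; higher = evenly spaced over
#' the top half, e.g. 1,6,...,71 of 150; mixed = evenly spaced over all,
#' e.g. 1,11,...,141). The iteration's statistic per category is the mean
#' accordance rate over all panel pairs (105 pairs for a 15-member panel)
#' on the test questions. Results are averaged over iterations with a
#' t-based 95% CI of the mean.
#'
#' @param data a [behavioral_dataset()].
#' @param n_iterations number of resampling iterations (5,000 in the full
#'   design; smaller values for quick runs).
#' @param n_sample_questions questions drawn per iteration (1 training +
#'   the rest test).
#' @param panel_size members per category panel.
#' @param seed integer seed; same seed, same result.
#' @param level CI coverage for the mean accordance rate.
#' @return tibble of class `accordance_result`: one row per category with
#'   `mean_rate`, `ci_low`, `ci_high`, `n_iterations`, plus a matrix of
#'   per-iteration rates in attribute `rates`.
#' @export
run_accordance_simulation <- function(data, n_iterations = 5000,
                                      n_sample_questions = 10,
                                      panel_size = 15, seed = 1,
                                      level = 0.95) {
  n_iterations <- check_count(n_iterations, "n_iterations")
  n_sample_questions <- check_count(n_sample_questions, "n_sample_questions", 2L)
  panel_size <- check_count(panel_size, "panel_size", 2L)
  qs <- questions(data)
  np <- length(participants(data))
  if (length(qs) < n_sample_questions) {
    stopf("dataset has %d questions; %d needed.", length(qs), n_sample_questions)
  }
  if (np < 2 * panel_size) {
    stopf("stride selection needs at least 2 * panel_size = %d participants, have %d.",
          2 * panel_size, np)
  }
  conf <- response_matrix(data, "confidence")
  corr <- response_matrix(data, "correct")
  categories <- c("highest", "higher", "mixed")
  pools <- c(highest = panel_size, higher = ceiling(np / 2), mixed = np)

  rates <- matrix(NA_real_, n_iterations, 3, dimnames = list(NULL, categories))
  for (it in seq_len(n_iterations)) {
    with_seed(substream_seed(seed, it), {
      qdraw <- sample(qs, n_sample_questions)
      train_q <- qdraw[1]
      test_q <- qdraw[-1]
      ord <- order(-conf[, train_q], sample.int(np))
      for (cat in categories) {
        members <- ord[stride_positions(pools[[cat]], panel_size)]
        rates[it, cat] <- pairwise_accordance(corr[members, test_q, drop = FALSE])
      }
    })
  }

  res <- do.call(rbind, lapply(categories, function(cat) {
    ci <- mean_ci(rates[, cat], level = level)
    tibble::tibble(category = cat, mean_rate = ci$mean,
                   ci_low = ci$ci_low, ci_high = ci$ci_high,
                   n_iterations = n_iterations)
  }))
  structure(res, rates = rates,
            class = c("accordance_result", class(tibble::tibble())))
}

#' Simulation 2: group accuracy on training vs. test questions
#'
#' Each iteration splits the questions into `n_train` training and
#' `n_test` test questions, ranks participants by mean training
#' confidence, forms one group of `group_size` members for the requested
#' category (highest = the top ranks, deterministic; higher = sampled
#' uniformly from the above-median ranks; mixed = sampled uniformly from
#' all ranks), and records the group's majority-rule accuracy separately
#' on the training and the test questions.
#'
#' @param data a [behavioral_dataset()].
#' @param n_train number of training questions (1, 5 or 10 in the full
#'   design).
#' @param group_size members per group (3 or 15 in the full design).
#' @param category `"highest"`, `"higher"` or `"mixed"`.
#' @param n_test number of test questions (25 or 15 in the full design).
#' @param n_iterations resampling iterations.
#' @param seed integer seed.
#' @return list of class `group_sim_result` with `condition` (n_train,
#'   group_size, category), `train_accuracies`, `test_accuracies` (both
#'   length `n_iterations`) and `splits` (list of the per-iteration
#'   question splits).
#' @export
run_group_simulation <- function(data, n_train, group_size,
                                 category = c("highest", "higher", "mixed"),
                                 n_test, n_iterations = 5000, seed = 1) {
  category <- match.arg(category)
  n_iterations <- check_count(n_iterations, "n_iterations")
  group_size <- check_count(group_size, "group_size")
  qs <- questions(data)
  np <- length(participants(data))
  if (group_size > np) stopf("group_size exceeds the number of participants.")
  conf <- response_matrix(data, "confidence")
  corr <- response_matrix(data, "correct")
  pool <- switch(category, highest = group_size,
                 higher = ceiling(np / 2), mixed = np)
  if (group_size > pool) {
    stopf("group_size %d exceeds the '%s' pool of %d.", group_size, category, pool)
  }

  train_acc <- numeric(n_iterations)
  test_acc <- numeric(n_iterations)
  splits <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    with_seed(substream_seed(seed, it), {
      sp <- split_questions(qs, n_train, n_test)
      splits[[it]] <- sp
      mc <- rowMeans(conf[, sp$training_questions, drop = FALSE])
      ord <- order(-mc, sample.int(np))
      members <- if (category == "highest") {
        ord[seq_len(group_size)]
      } else {
        ord[sample.int(pool, group_size)]
      }
      train_acc[it] <- majority_accuracy_matrix(
        corr[members, sp$training_questions, drop = FALSE])
      test_acc[it] <- majority_accuracy_matrix(
        corr[members, sp$test_questions, drop = FALSE])
    })
  }
  structure(list(condition = list(n_train = n_train, group_size = group_size,
                                  category = category),
                 train_accuracies = train_acc,
                 test_accuracies = test_acc,
                 splits = splits),
            class = "group_sim_result")
}

#' @export
print.group_sim_result <- function(x, ...) {
  cat(sprintf(
    "<group_sim_result> n_train=%d, group_size=%d, category=%s, %d iterations\n",
    x$condition$n_train, x$condition$group_size, x$condition$category,
    length(x$train_accuracies)))
  cat(sprintf("  mean train accuracy %.4f, mean test accuracy %.4f\n",
              mean(x$train_accuracies), mean(x$test_accuracies)))
  invisible(x)
}

#' Test-worse decomposition of a group simulation
#'
#' A simulated group is "test worse" when its test accuracy falls below
#' its training accuracy (test - train < 0). Reports the proportion of
#' test-worse iterations and the mean of the (negative) differences over
#' those iterations; when no iteration is test-worse the mean is reported
#' as 0 with `no_test_worse = TRUE`.
#'
#' @param result a [run_group_simulation()] result.
#' @return one-row tibble: condition columns, `test_worse_proportion`,
#'   `mean_diff_in_test_worse`, `no_test_worse`.
#' @export
summarize_test_worse <- function(result) {
  if (!inherits(result, "group_sim_result")) {
    stopf("`result` must be a group_sim_result.")
  }
  d <- result$test_accuracies - result$train_accuracies
  if (length(d) == 0L) stopf("empty simulation result.")
  worse <- d < 0
  tibble::tibble(n_train = result$condition$n_train,
                 group_size = result$condition$group_size,
                 category = result$condition$category,
                 test_worse_proportion = mean(worse),
                 mean_diff_in_test_worse = if (any(worse)) mean(d[worse]) else 0,
                 no_test_worse = !any(worse))
}

#' Effect size between two simulated conditions
#'
#' Cliff's delta of condition A's per-iteration accuracies versus
#' condition B's, on the test or the training questions.
#'
#' @param result_a,result_b [run_group_simulation()] results.
#' @param on `"test"` or `"train"`.
#' @return an effect-size object from [cliffs_delta()].
#' @export
compare_conditions <- function(result_a, result_b, on = c("test", "train")) {
  on <- match.arg(on)
  field <- if (on == "test") "test_accuracies" else "train_accuracies"
  cliffs_delta(result_a[[field]], result_b[[field]])
}
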