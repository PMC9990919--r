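# Independent oracles and fixture builders shared across test files.
# Each oracle deliberately avoids the code path it is used to check.

# Direct maximization of the Bernoulli log-likelihood over (intercept,
# slope) with optim/BFGS; independent of glm's IRLS.
logistic_slope_oracle <- function(confidence, correct) {
  nll <- function(par) {
    eta <- par[1] + par[2] * confidence
    -sum(correct * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15,
                                     parscale = c(1, 1 / diff(range(confidence)))))
  fit$par[2]
}

# Brute-force Cliff's delta: full enumeration of all n_a x n_b pairs.
cliffs_delta_oracle <- function(a, b) {
  mean(sign(outer(a, b, "-")))
}

# Mean pairwise accordance of rows of a 0/1 matrix by explicit
# enumeration of every unordered pair. Also returns the pair count.
pairwise_accordance_oracle <- function(mat) {
  m <- nrow(mat)
  pairs <- 0L
  total <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      total <- total + mean(mat[i, ] == mat[j, ])
      pairs <- pairs + 1L
    }
  }
  list(rate = total / pairs, n_pairs = pairs)
}

# Condorcet (binomial) group accuracy: m independent voters of accuracy p
# under strict majority (odd m).
condorcet_oracle <- function(m, p) {
  stopifnot(m %% 2 == 1)
  k <- ((m + 1) / 2):m
  sum(stats::dbinom(k, m, p))
}

# Complete 2AFC dataset from a participants x questions correctness
# matrix (and optional confidence matrix; constant 50 otherwise).
dataset_from_matrices <- function(corr, conf = NULL, task = "fixture") {
  np <- nrow(corr)
  nq <- ncol(corr)
  pid <- sprintf("P%03d", seq_len(np))
  qid <- sprintf("Q%03d", seq_len(nq))
  if (is.null(conf)) conf <- matrix(50, np, nq)
  behavioral_dataset(
    data.frame(participant_id = rep(pid, times = nq),
               question_id = rep(qid, each = np),
               correct = as.vector(corr),
               confidence = as.vector(conf)),
    task_name = task)
}

# iid Bernoulli(p) responders with uniform confidences.
iid_dataset <- function(n_participants, n_questions, p, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  corr <- matrix(rbinom(n_participants * n_questions, 1, p), n_participants)
  conf <- matrix(runif(n_participants * n_questions, 0, 100), n_participants)
  dataset_from_matrices(corr, conf, task = "iid")
}
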