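# Independent brute-force ROC oracle: naive per-cutoff confusion-table
# counting, rank-formula AUC (Mann-Whitney with midranks), and an explicit
# loop implementing the cut-point selection rule.
oracle_roc <- function(score, state, floor = 0.70) {
  state <- as.logical(state)
  n1 <- sum(state); n0 <- sum(!state)
  u <- sort(unique(score))
  gap <- if (length(u) > 1) min(diff(u)) else 1
  cutoffs <- c(u[1] - gap / 2,
               if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
               u[length(u)] + gap / 2)
  k <- length(cutoffs)
  sens <- spec <- numeric(k)
  for (j in seq_len(k)) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(score)) {
      predicted <- score[i] >= cutoffs[j]
      if (predicted && state[i]) tp <- tp + 1
      if (predicted && !state[i]) fp <- fp + 1
      if (!predicted && !state[i]) tn <- tn + 1
      if (!predicted && state[i]) fn <- fn + 1
    }
    sens[j] <- tp / (tp + fn)
    spec[j] <- tn / (tn + fp)
  }
  r <- rank(score)  # midranks handle ties: AUC by the Mann-Whitney identity
  auc <- (sum(r[state]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  qual <- which(sens >= floor & spec >= floor)
  if (length(qual)) {
    best <- qual[sens[qual] == max(sens[qual])]
    y <- sens[best] + spec[best] - 1
    best <- best[y == max(y)]
    sel <- best[which.min(cutoffs[best])]
  } else {
    y <- sens + spec - 1
    best <- which(y == max(y))
    if (any(sens[best] >= spec[best])) best <- best[sens[best] >= spec[best]]
    sel <- best[which.min(cutoffs[best])]
  }
  list(auc = auc, cutoff = cutoffs[sel],
       satisfied = length(qual) > 0)
}

# random small ROC instance with ties and both classes guaranteed
random_roc_instance <- function(n_max = 50) {
  n <- sample(8:n_max, 1)
  score <- if (runif(1) < 0.5) round(rnorm(n), 1) else rnorm(n)
  repeat {
    state <- runif(n) < runif(1, 0.2, 0.8)
    if (any(state) && any(!state)) break
  }
  shift <- runif(1, 0, 1.5)
  score[state] <- score[state] + shift
  list(score = score, state = state)
}
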