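# Independent brute-force oracles, written straight from the definitions
# with explicit loops; they share no code with the package internals.

# Concordance by exhaustive pair enumeration. A pair is skipped when both
# members have events at the same time, when both are censored, or when
# the shorter observed time is censored; otherwise the patient with the
# (determinably) shorter survival should carry the higher risk score.
# Tied scores stay in the denominator and add nothing to the numerator.
naive_cindex <- function(pred, time, event) {
  n <- length(pred)
  num <- 0; den <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      early <- NA
      if (time[i] == time[j]) {
        if (event[i] == 1 && event[j] == 0) early <- i
        if (event[j] == 1 && event[i] == 0) early <- j
      } else if (time[i] < time[j]) {
        if (event[i] == 1) early <- i
      } else {
        if (event[j] == 1) early <- j
      }
      if (is.na(early)) next
      late <- if (early == i) j else i
      den <- den + 1
      if (pred[early] > pred[late]) num <- num + 1
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Breslow partial log-likelihood by direct summation over events.
naive_pll <- function(X, time, event, beta) {
  eta <- as.numeric(X %*% beta)
  total <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    total <- total + eta[i] - log(sum(exp(eta[risk])))
  }
  total
}

# Random small survival fixture with tied times, tied predictions and
# mixed censoring.
random_surv_fixture <- function(n, seed) {
  set.seed(seed)
  time <- sample(1:8, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[1] <- 1
  pred <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)
  list(time = time, event = event, pred = pred)
}

# Small simulated dataset shared by several tests.
small_sim <- function(seed = 11, n = 80, p = 40, s = 3, effect = 1.5) {
  simulate_dataset(sim_config(n = n, p = p, s = s, effect_size = effect,
                              seed = seed))
}
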