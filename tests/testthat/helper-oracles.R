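# Independent oracle implementations used across the suite. These stay
# deliberately naive (loops, enumeration) so they share no code path with
# the package.

# count lattice points whose centre falls in the half-open annulus
bruteAnnulusCount <- function(gridSize, innerRadius, outerRadius) {
  ctr <- (gridSize + 1) / 2
  n <- 0L
  for (i in seq_len(gridSize)) for (j in seq_len(gridSize)) {
    r <- sqrt((i - ctr)^2 + (j - ctr)^2)
    if (r >= innerRadius && r < outerRadius) n <- n + 1L
  }
  n
}

# entropy by exhaustive per-pixel bin assignment (<= a dozen pixels)
bruteEntropyBits <- function(values, nBins) {
  lo <- min(values); hi <- max(values)
  counts <- integer(nBins)
  for (v in values) {
    if (hi == lo) b <- 1L
    else {
      b <- nBins            # right-most bin closed
      for (k in seq_len(nBins)) {
        up <- lo + k * (hi - lo) / nBins
        if (v < up) { b <- k; break }
      }
    }
    counts[b] <- counts[b] + 1L
  }
  p <- counts / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# C-index by explicit pair enumeration
bruteCindex <- function(times, events, risk) {
  conc <- usable <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (times[i] < times[j] && events[i] == 1) {
      usable <- usable + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / usable
}

# Cox partial log-likelihood for untied data, single covariate
brutePartialLoglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# log-rank O-E and hypergeometric variance tabulated per event time
bruteLogrank <- function(timesA, eventsA, timesB, eventsB) {
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  arm <- rep(1:2, c(length(timesA), length(timesB)))
  oMinusE <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n1 <- sum(atRisk & arm == 1); n <- sum(atRisk)
    d <- sum(event == 1 & time == t)
    o1 <- sum(event == 1 & time == t & arm == 1)
    oMinusE <- oMinusE + o1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oMinusE^2 / v
}

# simple null cohort plus an independent noise covariate
nullCohortWithNoise <- function(n, seed) {
  co <- generateCohort(cohortSpec(nSubjects = n, logHrPerUnitEntropy = 0,
                                  seed = seed))
  set.seed(seed + 1L)
  co$noise <- rnorm(n)
  co
}
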