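# Independent brute-force re-implementations used as oracles.
# These deliberately share no code with the package: plain loops,
# recomputed from the procedure's definition.

# response calling on one raw trace: baseline mean of first nb frames,
# dff, SD over baseline, loop-computed centered running mean with
# symmetrically shrinking edges, max over the inclusive rounded frame
# window, strict > k * SD
brute_force_detect <- function(f, onset_s, rate, nb = 28, k = 2.33,
                               win = c(0, 4.5), window = 5) {
  f0 <- sum(f[1:nb]) / nb
  dff <- (f - f0) / f0
  mu_b <- sum(dff[1:nb]) / nb
  bsd <- sqrt(sum((dff[1:nb] - mu_b)^2) / (nb - 1))
  n <- length(dff)
  half <- (window - 1) %/% 2
  sm <- numeric(n)
  for (i in 1:n) {
    h <- min(half, i - 1, n - i)
    acc <- 0
    for (j in (i - h):(i + h)) acc <- acc + dff[j]
    sm[i] <- acc / (2 * h + 1)
  }
  lo <- round((onset_s + win[1]) * rate)   # 0-based
  hi <- round((onset_s + win[2]) * rate)
  peak <- -Inf
  for (j in lo:hi) peak <- max(peak, sm[j + 1])
  list(peak = peak, threshold = k * bsd, responded = peak > k * bsd)
}

# expected final performance index of the binomial T-maze model
expected_final_peri <- function(memory, bias) {
  p_a <- 0.5 + memory / 2 + bias / 2
  p_b <- 0.5 + memory / 2 - bias / 2
  ((2 * p_a - 1) * 100 + (2 * p_b - 1) * 100) / 2
}

# build a minimal imaging_session from a cell x frame matrix (one sweep)
session_from_matrix <- function(m, rate = 7, odor = "OCT", onset = 5) {
  structure(list(
    animal_id = "fixture", training_condition = NA_character_,
    traces = array(m, dim = c(nrow(m), ncol(m), 1)),
    sweeps = data.frame(odor = odor, presentation = 1L, onset_s = onset,
                        stringsAsFactors = FALSE),
    frame_rate_hz = rate,
    truth = NULL, config = NULL
  ), class = "imaging_session")
}
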