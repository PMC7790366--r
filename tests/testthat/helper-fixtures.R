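# Shared fixtures: small deterministic datasets built in code.

# A fixed dataset where item 1 is always chosen, on a tiny 3-item design.
fixed_winner_data <- function() {
  d <- data.frame(participant = "p1",
                  trial = 1:3, block = 1L,
                  left = c(1L, 2L, 1L),
                  right = c(2L, 3L, 3L),
                  chosen = c(1L, 2L, 1L),
                  rt = NA_real_)
  attr(d, "n_items") <- 3L
  class(d) <- c("cbl_data", "data.frame")
  d
}

# Standard 15-item session used across tests.
std_schedule <- function(seed = 1) build_schedule(15, 21, seed = seed)

# Independent scalar replay of a CBL-family likelihood, written with
# plain arithmetic (no package step functions), as an oracle.
oracle_loglik_cbl <- function(a_c, a_r, beta, data, n_items) {
  V <- rep(0.5, n_items)
  ll <- 0
  for (t in seq_len(nrow(data))) {
    ch <- data$chosen[t]
    ot <- if (ch == data$left[t]) data$right[t] else data$left[t]
    p <- 1 / (1 + exp(-beta * (V[ch] - V[ot])))
    ll <- ll + log(p)
    V[ch] <- V[ch] + a_c * (1 - V[ch])
    V[ot] <- V[ot] + a_r * (0 - V[ot])
  }
  ll
}
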