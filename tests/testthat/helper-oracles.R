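# Independent brute-force Victor-Purpura oracle: enumerate every monotone
# matching between the two (sorted) trains explicitly. Unmatched spikes cost
# 1 each, matched pairs cost q * |dt|. Exponential in train size; fine for
# n <= 6.
bf_victor_purpura <- function(t1, t2, q) {
  n1 <- length(t1)
  n2 <- length(t2)
  best <- n1 + n2                       # match nothing
  for (k in seq_len(min(n1, n2))) {
    s1 <- utils::combn(seq_len(n1), k, simplify = FALSE)
    s2 <- utils::combn(seq_len(n2), k, simplify = FALSE)
    for (a in s1) {
      for (b in s2) {
        cost <- (n1 - k) + (n2 - k) + q * sum(abs(t1[a] - t2[b]))
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# random sorted spike train on [0, 1]
random_train <- function(n_max = 5) {
  sort(stats::runif(sample(0:n_max, 1)))
}

# uncoupled single-ORN low-concentration drives used by calibration checks
calibration_drives <- function(p = orn_params(), s = sensillum_params()) {
  pulse <- make_pulse_protocol("A", 0.5, "low")
  conc_pulse <- valve_to_concentration(pulse$channels$A,
                                       s$conc_peaks[["low"]],
                                       s$tau_rise, s$tau_fall,
                                       s$drive_rate, t0 = pulse$t_origin)
  const_seq <- valve_sequence(0.5, duration = 3.5, channel = "A")
  conc_const <- valve_to_concentration(const_seq, s$conc_peaks[["low"]],
                                       s$tau_rise, s$tau_fall,
                                       s$drive_rate, t0 = 0.5)
  list(pulse = transduce(conc_pulse, p),
       constant = transduce(conc_const, p))
}
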