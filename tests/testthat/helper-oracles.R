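# Independent oracles and small shared helpers for the suite.

# brute-force O(L^2) DFT of a mean-centered, zero-padded series
naiveDftAmplitudes <- function(x, L) {
  x <- x - mean(x)
  x <- c(x, rep(0, L - length(x)))
  vapply(seq_len(L %/% 2), function(n)
    Mod(sum(x * exp(-2i * pi * n * (seq_len(L) - 1) / L))), numeric(1))
}

# direct time-domain Morlet convolution at one scale:
# W(b) = s^(-1/2) * sum_m x[m] * Conj(psi0((m - b)/s)),
# psi0(t) = pi^(-1/4) exp(i*omega0*t - t^2/2)
naiveMorletRow <- function(x, s, omega0 = 6) {
  n <- length(x)
  m <- seq_len(n)
  vapply(seq_len(n), function(b) {
    t <- (m - b) / s
    psi <- pi^(-0.25) * exp(1i * omega0 * t - t^2 / 2)
    Mod(sum(x * Conj(psi)) / sqrt(s))
  }, numeric(1))
}

jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}

noRisks <- stats::setNames(rep("none", 4),
                           c("irritation", "mutagenic", "reproductive",
                             "tumorigenic"))

# sequence from pure values, bypassing encoders
rawSeq <- function(values, id = "raw", kind = "protein")
  new("EncodedSequence", id = id, kind = kind,
      values = values, tokens = rep("*", length(values)))
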