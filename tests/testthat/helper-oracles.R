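# Independent oracles used to check the implementation.

# Brute-force DFT projection: computes each retained Fourier coefficient
# by direct summation and resynthesizes by direct summation (no FFT).
# Same conventions as the implementation under test: demean, append
# zeros, keep |f| in [f_low, f_high), drop DC, return first n samples.
dft_bandpass_oracle <- function(x, fs, f_low, f_high, pad_to = 256) {
  n <- length(x)
  xp <- c(x - mean(x), numeric(pad_to - n))
  k <- 0:(pad_to - 1)
  freq <- ifelse(k <= pad_to / 2, k, k - pad_to) * fs / pad_to
  retained <- which(abs(freq) >= f_low & abs(freq) < f_high & k != 0) - 1
  nn <- 0:(pad_to - 1)
  acc <- rep(0 + 0i, pad_to)
  for (kk in retained) {
    Xk <- sum(xp * exp(-2i * pi * kk * nn / pad_to))
    acc <- acc + Xk * exp(2i * pi * kk * nn / pad_to)
  }
  Re(acc / pad_to)[seq_len(n)]
}

# Sum of retained squared spectral magnitudes for the Parseval check.
dft_retained_power <- function(x, fs, f_low, f_high, pad_to = 256) {
  n <- length(x)
  xp <- c(x - mean(x), numeric(pad_to - n))
  k <- 0:(pad_to - 1)
  freq <- ifelse(k <= pad_to / 2, k, k - pad_to) * fs / pad_to
  retained <- which(abs(freq) >= f_low & abs(freq) < f_high & k != 0) - 1
  nn <- 0:(pad_to - 1)
  sum(vapply(retained, function(kk)
    Mod(sum(xp * exp(-2i * pi * kk * nn / pad_to)))^2, numeric(1)))
}
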