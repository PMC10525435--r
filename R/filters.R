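# Butterworth band-pass in cascaded second-order sections.
#
# The respiratory band (0.1-0.6 Hz at fs = 125 Hz) sits at ~0.2-1% of
# Nyquist; a transfer-function (b, a) realisation of the 4th-order band-pass
# is numerically unusable there (coefficient conditioning blows up), so the
# design is kept in zero-pole form and realised as biquads: analog
# Butterworth prototype -> lowpass-to-bandpass transform -> bilinear
# transform -> conjugate-pair sections, each with one zero at z = +1 and one
# at z = -1 and an even share of the overall gain.

butter_bandpass_sos <- function(order, f_lo, f_hi, fs) {
  if (f_lo <= 0 || f_hi <= f_lo || f_hi >= fs / 2)
    transrr_error("transrr_parameter_error",
                  "band [%g, %g] Hz must satisfy 0 < lo < hi < fs/2 = %g",
                  f_lo, f_hi, fs / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP prototype poles
  wl <- 2 * fs * tan(pi * f_lo / fs)                          # prewarped edges
  wh <- 2 * fs * tan(pi * f_hi / fs)
  bw <- wh - wl
  w0 <- sqrt(wl * wh)
  poles <- unlist(lapply(proto, function(p) {
    disc <- sqrt((p * bw / 2)^2 - w0^2 + 0i)
    c(p * bw / 2 + disc, p * bw / 2 - disc)
  }))
  zeros <- rep(0 + 0i, order)
  gain <- bw^order
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  kd <- Re(gain * prod(fs2 - zeros) / prod(fs2 - poles))
  # pair poles with their conjugates into biquads
  used <- rep(FALSE, length(pd))
  sections <- list()
  for (i in seq_along(pd)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & abs(pd - Conj(pd[i])) < 1e-8)[1]
    if (is.na(j)) transrr_error("transrr_internal_error", "unpaired filter pole")
    used[j] <- TRUE
    sections[[length(sections) + 1]] <- c(pd[i], pd[j])
  }
  g <- abs(kd)^(1 / length(sections))
  sos <- t(vapply(seq_along(sections), function(s) {
    pp <- sections[[s]]
    gg <- g * if (s == 1) sign(kd) else 1
    c(gg, 0, -gg, 1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2]))
  }, numeric(6)))
  sos
}

# One cascaded pass; each biquad is initialised at its steady state for the
# first input value so that constant inputs map to (exactly) their
# steady-state output, which for a band-pass is 0.
sosfilt <- function(sos, x) {
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    y0 <- x[1] * sum(b) / sum(a)
    x <- as.numeric(signal::filter(b, a, x, init.x = c(x[1], x[1]),
                                   init.y = c(y0, y0)))
  }
  x
}

# Zero-phase (forward-backward) cascaded filtering with odd-reflection
# padding sized to the filter's slowest time constant.
sosfiltfilt <- function(sos, x, f_lo, fs) {
  n <- length(x)
  npad <- min(n - 1L, ceiling(3 * fs / f_lo))
  xp <- if (npad > 0)
    c(2 * x[1] - x[seq(npad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - npad)])
  else x
  y <- sosfilt(sos, xp)
  y <- rev(sosfilt(sos, rev(y)))
  y[(npad + 1):(npad + n)]
}
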