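# Monte-Carlo oracle for the shot-noise ratio: Poisson phase-stepping
# simulation -> sinusoid extraction of (T, nu) -> log standard deviations.
# Independent of the closed-form model it is used to check.
#
# The error-propagation model treats the fringe mean and the fringe
# amplitude as independent estimates; the oracle realizes that assumption
# by drawing the mean and the modulation from independent stepping passes
# (split = TRUE). With split = FALSE both come from the same pass, which
# adds the mean-amplitude covariance of single-scan processing that the
# model neglects (a ~V^2/2 relative reduction of the visibility variance).
mcNoiseRatio <- function(T, D, vRef = 0.365, flux = 1e6, nStep = 8L,
                         reps = 2e4, seed = 1, split = TRUE) {
  ph <- seq(0, 2 * pi, length.out = nStep + 1)[-(nStep + 1)]
  set.seed(seed)
  stepScan <- function(total, V) {
    means <- total / nStep * (1 + V * cos(ph))
    counts <- matrix(rpois(reps * nStep, rep(means, each = reps)),
                     reps, nStep)
    a <- rowMeans(counts)
    c1 <- (counts %*% cos(ph)) * 2 / nStep
    s1 <- (counts %*% sin(ph)) * 2 / nStep
    list(a = a, amp = sqrt(c1^2 + s1^2))
  }
  visScan <- function(total, V) {
    p1 <- stepScan(total, V)
    if (!split) return(list(a = p1$a, v = p1$amp / p1$a))
    p2 <- stepScan(total, V)
    list(a = p1$a, v = p2$amp / p1$a)
  }
  ref <- visScan(flux, vRef)
  smp <- visScan(flux * T, vRef * D)
  lnT <- log(smp$a / ref$a)
  lnD <- log(smp$v / ref$v)
  sd(lnD) / sd(lnT)
}
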