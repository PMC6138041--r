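# Independent oracles and small fixtures, built in code.

# Brute-force ICC(3,1) through R's ANOVA machinery: an implementation
# path completely independent of icc31()'s closed-form mean squares.
bruteIcc31 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  subj = factor(rep(seq_len(n), k)),
                  sess = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::aov(y ~ subj + sess, data = d))
  bms <- a["subj", "Mean Sq"]
  ems <- a["Residuals", "Mean Sq"]
  (bms - ems) / (bms + (k - 1) * ems)
}

# Analytic sampling interval for the ICC(3,1) estimate at true value rho:
# BMS/EMS is distributed as F_true * F(n-1, (n-1)(k-1)), and the estimate
# is the monotone map (F - 1) / (F + k - 1) of that ratio.
iccSamplingInterval <- function(rho, n, k = 2, level = 0.95) {
  fTrue <- 1 + k * rho / (1 - rho)
  q <- stats::qf(c((1 - level) / 2, 1 - (1 - level) / 2),
                 n - 1, (n - 1) * (k - 1))
  fq <- fTrue * q
  (fq - 1) / (fq + k - 1)
}

# Small acquisition + matching topology for fast simulation tests.
tinyAcq <- function(gridShape = c(10L, 10L, 8L), nVolumes = 155L) {
  acquisitionSpec(nVolumes = nVolumes, gridShape = gridShape)
}

tinyTopology <- function(acq, radius = 4, mu = 1) {
  spheres <- data.frame(
    region = c("A", "V", "M", "C"),
    condition = c("auditory", "visual", "motor", "cognitive"),
    x = c(-7, 7, -7, 7), y = c(-7, -7, 7, 7), z = 0,
    radius = radius, mu = mu)
  activationTopology(spheres, acq)
}

withr_like_tempdir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}

# Single-trial table for regressor shape tests.
singleTrial <- function(condition = "auditory", onset = 0, duration = 3) {
  data.frame(onset = onset, duration = duration, condition = condition,
             stringsAsFactors = FALSE)
}
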