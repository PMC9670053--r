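# Brute-force maximizer of the gamma log-link likelihood for a
# one-covariate model, by iteratively refined grid search. The gamma score
# equations for the mean parameters do not involve the shape, so the kernel
# sum(-y/mu - log(mu)) suffices.
grid_glm_oracle <- function(x1, y, center = c(0, 0), width = c(8, 8),
                            levels = 6, points = 81) {
  best <- center
  for (l in seq_len(levels)) {
    b0s <- seq(best[1] - width[1], best[1] + width[1], length.out = points)
    b1s <- seq(best[2] - width[2], best[2] + width[2], length.out = points)
    ll <- matrix(NA_real_, points, points)
    for (i in seq_len(points)) {
      eta <- b0s[i] + x1 %o% b1s       # n x points, fixed b0
      ll[i, ] <- colSums(-y * exp(-eta) - eta)
    }
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0s[idx[1]], b1s[idx[2]])
    width <- width * 2 / (points - 1) * 2  # shrink around the argmax
  }
  best
}

# sort-based median oracle, independent of stats::median
sort_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
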