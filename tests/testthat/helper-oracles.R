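# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive results by brute force / closed form and
# must stay independent of the package implementations they check.

# Brute-force sliding extreme over |mz_j - mz_i| <= half (O(n^2)).
oracle_roll_extreme <- function(mz, x, half, maximum) {
  vapply(seq_along(mz), function(i) {
    w <- x[abs(mz - mz[i]) <= half]
    if (maximum) max(w) else min(w)
  }, numeric(1))
}

# Brute-force top-hat: erosion then dilation, subtracted.
oracle_tophat <- function(mz, x, window) {
  half <- window / 2
  ero <- oracle_roll_extreme(mz, x, half, FALSE)
  open <- oracle_roll_extreme(mz, ero, half, TRUE)
  x - open
}

# Brute-force strict local-maximum scan (no plateaus in the inputs used).
oracle_local_maxima <- function(x, y, threshold) {
  idx <- which(diff(sign(diff(y))) == -2) + 1L
  idx[y[idx] >= threshold]
}

# Closed-form least-squares line fit y ~ x (slope, intercept).
oracle_lsq_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# All-pairs Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Pearson chi-square by the definitional sum over expected counts.
oracle_chisq <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  sum((o - e)^2 / e)
}

# A noiseless Gaussian-mixture spectrum on a uniform grid.
make_gaussian_spectrum <- function(centers, heights, fwhm = 2.5,
                                   grid = 0.1, range = c(2300, 3600),
                                   baseline = function(x) 0) {
  x <- seq(range[1], range[2], by = grid)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- baseline(x)
  for (j in seq_along(centers))
    y <- y + heights[j] * exp(-(x - centers[j])^2 / (2 * sigma^2))
  glycomig:::new_spectrum(x, y)
}

# Random simplex profile over the default 22-name vocabulary (IgG1 only).
random_profile <- function(seed = 1) {
  gf <- default_glycoforms()
  w <- glycomig:::with_seed(seed, runif(length(gf), 0.2, 1))
  glycomig:::new_glyco_profile(rep("IgG1", length(gf)), gf, w / sum(w))
}

write_spectrum_file <- function(spectrum, path) {
  writeLines(sprintf("%.5f %.6f", spectrum$mz, spectrum$intensity), path)
  path
}
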