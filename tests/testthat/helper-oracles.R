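# Independent brute-force oracles, written from the defining formulas
# with explicit loops; they share no code with the package internals.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# linear-interpolation percentile (type-7 order statistics, by hand)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# element-wise Fisher's Ratio matrix from a patients x features matrix
oracle_fisher <- function(x, labels, location = "median") {
  loc_fun <- if (location == "median") oracle_median else mean
  out <- matrix(NA_real_, 4, ncol(x),
                dimnames = list(c("mu_r", "mu_n", "sigma_r", "sigma_n"),
                                colnames(x)))
  fr <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    vr <- x[labels == "R", j]
    vn <- x[labels == "N", j]
    out["mu_r", j] <- loc_fun(vr)
    out["mu_n", j] <- loc_fun(vn)
    out["sigma_r", j] <- oracle_sd(vr)
    out["sigma_n", j] <- oracle_sd(vn)
    fr[j] <- (out["mu_r", j] - out["mu_n", j])^2 /
      (out["sigma_r", j]^2 + out["sigma_n", j]^2)
  }
  list(stats = out, fr = fr)
}

# confusion-matrix metrics plus pairwise-comparison AUC
oracle_metrics <- function(truth, pred, scores) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "R" && pred[i] == "R") tp <- tp + 1
    if (truth[i] == "N" && pred[i] == "N") tn <- tn + 1
    if (truth[i] == "N" && pred[i] == "R") fp <- fp + 1
    if (truth[i] == "R" && pred[i] == "N") fn <- fn + 1
  }
  num <- 0
  for (i in which(truth == "R")) for (j in which(truth == "N")) {
    num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       auc = num / (sum(truth == "R") * sum(truth == "N")))
}

# Pearson r and its t-test p-value from first principles
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# two-sample Welch t statistic from first principles
oracle_welch_t <- function(a, b) {
  va <- oracle_sd(a)^2 / length(a)
  vb <- oracle_sd(b)^2 / length(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}
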