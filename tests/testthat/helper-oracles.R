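# Independent brute-force oracles, kept deliberately naive: explicit loops
# and textbook formulas, no shared code with the package internals.

# Wilks' lambda by direct determinant evaluation of the scatter matrices.
brute_wilks <- function(X, y) {
  X <- as.matrix(X)
  Tm <- matrix(0, ncol(X), ncol(X))
  xbar <- colMeans(X)
  for (i in seq_len(nrow(X))) {
    d <- X[i, ] - xbar
    Tm <- Tm + outer(d, d)
  }
  W <- matrix(0, ncol(X), ncol(X))
  for (g in unique(y)) {
    Xg <- X[y == g, , drop = FALSE]
    mg <- colMeans(Xg)
    for (i in seq_len(nrow(Xg))) {
      d <- Xg[i, ] - mg
      W <- W + outer(d, d)
    }
  }
  det(W) / det(Tm)
}

# One-way ANOVA F from group sums of squares.
brute_anova_f <- function(x, y) {
  groups <- split(x, y)
  grand <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups)
  n <- length(x)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Direct two-class LDA: pooled covariance, linear scores, equal priors.
brute_lda_predict <- function(Xtr, ytr, Xte, priors = c(0.5, 0.5)) {
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  mu0 <- colMeans(Xtr[ytr == 0, , drop = FALSE])
  mu1 <- colMeans(Xtr[ytr == 1, , drop = FALSE])
  n <- nrow(Xtr)
  S <- matrix(0, ncol(Xtr), ncol(Xtr))
  for (g in c(0, 1)) {
    Xg <- Xtr[ytr == g, , drop = FALSE]
    mg <- colMeans(Xg)
    for (i in seq_len(nrow(Xg))) {
      d <- Xg[i, ] - mg
      S <- S + outer(d, d)
    }
  }
  S <- S / (n - 2)
  Sinv <- solve(S)
  d0 <- Xte %*% (Sinv %*% mu0) - 0.5 * drop(t(mu0) %*% Sinv %*% mu0) + log(priors[1])
  d1 <- Xte %*% (Sinv %*% mu1) - 0.5 * drop(t(mu1) %*% Sinv %*% mu1) + log(priors[2])
  list(class = as.integer(d1 > d0),
       p_positive = drop(1 / (1 + exp(d0 - d1))))
}

# Exhaustive scan over every midpoint threshold; returns the maximal Gini
# decrease and its threshold.
brute_gini_scan <- function(values, y, min_leaf = 1) {
  gini <- function(lbl) {
    if (!length(lbl)) return(0)
    p <- mean(lbl == 1)
    1 - p^2 - (1 - p)^2
  }
  n <- length(values)
  parent <- gini(y)
  uv <- sort(unique(values))
  if (length(uv) < 2 || parent == 0) return(NULL)
  best <- NULL
  for (i in seq_len(length(uv) - 1)) {
    thr <- (uv[i] + uv[i + 1]) / 2
    left <- values < thr
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    dec <- parent - (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / n
    if (is.null(best) || dec > best$gini_decrease + 1e-12) {
      best <- list(threshold = thr, gini_decrease = dec)
    }
  }
  if (!is.null(best) && best$gini_decrease <= 0) return(NULL)
  best
}

# Shared fixture: a small spectra dataset with planted carbon signal.
make_planted_spectra <- function(seed = 1, n = 300) {
  windows <- list(
    list(nucleus = "C13", lo = 48, hi = 50, rate_pos = 2.0, rate_neg = 0.1),
    list(nucleus = "C13", lo = 96, hi = 98, rate_pos = 2.0, rate_neg = 0.1),
    list(nucleus = "C13", lo = 144, hi = 146, rate_pos = 2.0, rate_neg = 0.1),
    list(nucleus = "C13", lo = 198, hi = 200, rate_pos = 2.0, rate_neg = 0.1),
    list(nucleus = "N15", lo = 230, hi = 240, rate_pos = 2.0, rate_neg = 0.1))
  generate_spectra_dataset(spectra_sim_config(
    n_compounds = n, planted_windows = windows, seed = seed))
}

planted_bin_labels <- c("C2 (48–50)", "C2 (96–98)", "C2 (144–146)",
                        "C2 (198–200)", "N10 (230–240)")
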