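# Independent brute-force reference implementations. These deliberately use
# naive scalar loops and textbook formulas, sharing no code with the package
# internals they check.

# -- B-spline mutual information ---------------------------------------------

# Cox-de Boor recursion for a single scalar, one basis function at a time.
oracle_basis <- function(i, ord, t, knots) {
  if (ord == 1) {
    tmax <- knots[length(knots)]
    if (knots[i] <= t && t < knots[i + 1]) return(1)
    # the domain maximum belongs to the last interval of positive width
    if (t == tmax && knots[i] < knots[i + 1] && knots[i + 1] == tmax) {
      return(1)
    }
    return(0)
  }
  d1 <- knots[i + ord - 1] - knots[i]
  d2 <- knots[i + ord] - knots[i + 1]
  a <- if (d1 > 0) (t - knots[i]) / d1 * oracle_basis(i, ord - 1, t, knots) else 0
  b <- if (d2 > 0) (knots[i + ord] - t) / d2 * oracle_basis(i + 1, ord - 1, t, knots) else 0
  a + b
}

oracle_weights <- function(x, bins, ord) {
  tmax <- bins - ord + 1
  z <- (x - min(x)) / (max(x) - min(x)) * tmax
  knots <- c(rep(0, ord), seq_len(bins - ord), rep(tmax, ord))
  w <- matrix(0, length(x), bins)
  for (s in seq_along(z)) {
    for (a in seq_len(bins)) {
      w[s, a] <- oracle_basis(a, ord, z[s], knots)
    }
  }
  w
}

oracle_mi <- function(x, y, bins, ord) {
  wx <- oracle_weights(x, bins, ord)
  wy <- oracle_weights(y, bins, ord)
  n <- length(x)
  px <- numeric(bins)
  py <- numeric(bins)
  pxy <- matrix(0, bins, bins)
  for (s in seq_len(n)) {
    px <- px + wx[s, ] / n
    py <- py + wy[s, ] / n
    for (a in seq_len(bins)) {
      for (b in seq_len(bins)) {
        pxy[a, b] <- pxy[a, b] + wx[s, a] * wy[s, b] / n
      }
    }
  }
  total <- 0
  for (a in seq_len(bins)) {
    for (b in seq_len(bins)) {
      if (pxy[a, b] > 0) {
        total <- total + pxy[a, b] * log2(pxy[a, b] / (px[a] * py[b]))
      }
    }
  }
  total
}

# -- CLR background correction -----------------------------------------------

oracle_clr <- function(mi) {
  g <- nrow(mi)
  mu <- sig <- numeric(g)
  for (i in seq_len(g)) {
    vals <- mi[i, -i]
    mu[i] <- mean(vals)
    sig[i] <- sqrt(mean((vals - mu[i])^2))
  }
  out <- matrix(0, g, g, dimnames = dimnames(mi))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i == j) next
      zi <- if (sig[i] > 0) max(0, (mi[i, j] - mu[i]) / sig[i]) else 0
      zj <- if (sig[j] > 0) max(0, (mi[j, i] - mu[j]) / sig[j]) else 0
      out[i, j] <- sqrt(zi^2 + zj^2)
    }
  }
  out
}

# -- network similarity ------------------------------------------------------

oracle_mae <- function(a, b) {
  g <- nrow(a)
  total <- 0
  count <- 0
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      total <- total + abs(a[i, j] - b[i, j])
      count <- count + 1
    }
  }
  total / count
}

# -- precision-recall by exhaustive threshold enumeration --------------------

oracle_pr <- function(score, label) {
  thresholds <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(label == 1)
  prec <- rec <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    called <- score >= thresholds[k]
    tp <- sum(label == 1 & called)
    prec[k] <- tp / sum(called)
    rec[k] <- tp / n_pos
  }
  data.frame(threshold = thresholds, precision = prec, recall = rec)
}

oracle_aupr <- function(score, label) {
  curve <- oracle_pr(score, label)
  area <- 0
  prev_rec <- 0
  for (k in seq_len(nrow(curve))) {
    area <- area + (curve$recall[k] - prev_rec) * curve$precision[k]
    prev_rec <- curve$recall[k]
  }
  area
}

# -- functional edge overlap -------------------------------------------------

oracle_feo <- function(edges, ann) {
  num <- den <- 0
  for (e in seq_len(nrow(edges))) {
    ca <- ann[[edges[e, 1]]]
    cb <- ann[[edges[e, 2]]]
    if (is.null(ca) || length(ca) == 0 || is.null(cb) || length(cb) == 0) next
    den <- den + 1
    if (any(ca %in% cb)) num <- num + 1
  }
  if (den == 0) NA_real_ else num / den
}

# -- Welch's t-test from the defining formulas -------------------------------

oracle_welch <- function(xs, ys) {
  nx <- length(xs); ny <- length(ys)
  vx <- sum((xs - mean(xs))^2) / (nx - 1)
  vy <- sum((ys - mean(ys))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(xs) - mean(ys)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  p <- 2 * stats::integrate(dens, lower = abs(t_stat), upper = Inf,
                            rel.tol = 1e-10)$value
  list(statistic = t_stat, df = df, p_value = min(p, 1))
}
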