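# Independent oracles, deliberately implemented with different machinery
# than the package paths they check.

# Brute-force queue flood fill over a binary matrix (2D) or array (3D).
oracle_component_count <- function(bin, connectivity, min_size = 1) {
  d <- dim(bin)
  ndim <- length(d)
  offs <- if (ndim == 2) {
    o <- as.matrix(expand.grid(-1:1, -1:1))
    o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
    if (connectivity == 4) o[rowSums(abs(o)) == 1, , drop = FALSE] else o
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
    if (connectivity == 6) o[rowSums(abs(o)) == 1, , drop = FALSE] else o
  }
  seen <- array(FALSE, d)
  count <- 0L
  todo <- which(bin & !seen)
  for (start in todo) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      cc <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- cc + offs[k, , drop = FALSE]
        if (any(nb < 1) || any(nb > d)) next
        lin <- if (ndim == 2) nb[1] + (nb[2] - 1) * d[1] else
          nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (bin[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    if (size >= min_size) count <- count + 1L
  }
  count
}

# Hand-coded two-sample t p-values.
oracle_student_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), n1 + n2 - 2)
}

oracle_welch_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  q1 <- var(a) / n1; q2 <- var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(q1 + q2)
  df <- (q1 + q2)^2 / (q1^2 / (n1 - 1) + q2^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

# Mann-Whitney normal approximation with tie and continuity correction.
oracle_mw_approx_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- W - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# Exact Mann-Whitney by full enumeration of group assignments (no ties).
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  Ws <- apply(sets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- if (W_obs > mu) 2 * mean(Ws >= W_obs) else 2 * mean(Ws <= W_obs)
  min(1, p)
}

# Kruskal-Wallis H with tie correction, from the rank formula.
oracle_kw <- function(groups) {
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(vals)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(H = H, p = pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Simple-regression slope/intercept/R^2 straight from the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Sort-based median, independent of stats::median.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Standard noisy-fixture counting settings used across tests: light plane-wise
# smoothing and a threshold halfway into the rendered amplitude.
count_noisy_3d <- function(stack) {
  sm <- smooth_stack(stack, sigma = 0.8)
  count_puncta_3d(binarize_stack(sm, policy = "fixed", value = 400)$binary,
                  min_size_vox = 3)
}
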