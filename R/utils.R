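# Internal helpers shared across modules.

.assert <- function(ok, msg, class = "wolbtiter_error") {
  if (!ok) stop(rlang::error_cnd(class = c(class, "rlang_error"), message = msg))
  invisible(TRUE)
}

.check_numeric <- function(x, name) {
  .assert(is.numeric(x) && length(x) > 0 && all(is.finite(x)),
          paste0("`", name, "` must be a non-empty finite numeric vector"))
  as.numeric(x)
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Closed-form two-sample t statistics. Used by the randomization test and the
# vectorized power loop; t.test() remains the user-facing path.
.welch_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

.student_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# Column-wise Welch / Student p-values on subsample matrices (groups in
# columns-aligned matrices A, B; one test per column).
.t_p_cols <- function(A, B, var_equal = FALSE) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- (colSums(A * A) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(B * B) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * pt(-abs(t), df)
  p[!is.finite(t)] <- NA_real_  # degenerate subsample: zero variance in both
  p
}

# Mann-Whitney p, mirroring the scalar rule: exact (pwilcox) when the combined
# sample is <= 20 with no ties, else normal approximation with tie and
# continuity correction, as in wilcox.test(correct = TRUE).
.mw_p_cols <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B); N <- n1 + n2
  comb <- rbind(A, B)
  stat <- apply(comb, 2, function(col) {
    r <- rank(col)
    lens <- rle(sort(col))$lengths
    c(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2, sum(lens^3 - lens))
  })
  W <- stat[1L, ]; tiesum <- stat[2L, ]
  p <- rep(NA_real_, length(W))
  exact <- (N <= 20) & (tiesum == 0)
  if (any(exact)) {
    w <- W[exact]
    p[exact] <- pmin(1, ifelse(w > n1 * n2 / 2,
                               2 * pwilcox(w - 1, n1, n2, lower.tail = FALSE),
                               2 * pwilcox(w, n1, n2)))
  }
  if (any(!exact)) {
    w <- W[!exact]; ts <- tiesum[!exact]
    sig2 <- n1 * n2 / 12 * ((N + 1) - ts / (N * (N - 1)))
    z <- w - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    pn <- pmin(1, 2 * pnorm(-abs(z)))
    pn[sig2 == 0] <- NA_real_  # every value tied: no ordering information
    p[!exact] <- pn
  }
  p
}

# Two-group Levene p-value (one-way ANOVA on absolute deviations), closed form.
# Equals car::leveneTest for two groups; used where building an lm per
# iteration would dominate runtime.
.levene_p2 <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  f <- if (center == "mean") mean else median
  da <- abs(a - f(a)); db <- abs(b - f(b))
  st <- .student_stat(da, db)
  if (!is.finite(st$statistic)) return(NA_real_)
  st$p
}
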