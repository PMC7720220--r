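# Independent oracle implementations used to cross-check the package.
# Each is deliberately written with a different algorithm/decomposition than
# the implementation it checks.

# --- normal-equations OLS oracle (explicit solve, no qr/chol shortcuts) ----
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  XtX_inv <- solve(XtX)
  beta <- drop(XtX_inv %*% (t(X) %*% y))
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(coef = beta, se = sqrt(diag(XtX_inv) * sigma2),
       sigma = sqrt(sigma2), XtX_inv = XtX_inv)
}

# --- Newton-Raphson logistic MLE oracle -----------------------------------
irls_oracle <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- t(X) %*% (y - p)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  info <- t(X) %*% (X * (1 / (1 + exp(-drop(X %*% beta)))) *
                      (1 - 1 / (1 + exp(-drop(X %*% beta)))))
  list(coef = beta, se = sqrt(diag(solve(info))))
}

# --- sort-based median oracle ---------------------------------------------
sort_median_oracle <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# --- loop-and-accumulate rmse oracle --------------------------------------
rmse_loop_oracle <- function(v, r) {
  acc <- 0
  for (i in seq_along(v)) acc <- acc + (v[i] - r[i])^2
  sqrt(acc / length(v))
}

# --- compound 3RS3R running-median smoother reference ----------------------
# Written from the smoother's definition: repeated medians of 3 with the
# Tukey end rule, one pass splitting extremal 2-flats (with one-sided rules
# at the boundary pairs), then repeated medians again; the split pass is
# kept only when its final store flag reports a change.
med3_ref <- function(a, b, c) median(c(a, b, c))

ref_sm3 <- function(x) {
  n <- length(x); y <- x
  if (n < 3) return(x)
  for (i in 2:(n - 1)) y[i] <- med3_ref(x[i - 1], x[i], x[i + 1])
  y[1] <- med3_ref(3 * y[2] - 2 * y[3], x[1], y[2])
  y[n] <- med3_ref(y[n - 1], x[n], 3 * y[n - 1] - 2 * y[n - 2])
  y
}

ref_sm3R <- function(x) {
  repeat { y <- ref_sm3(x); if (identical(y, x)) return(y); x <- y }
}

ref_split_store <- function(u, v, w) {
  # med3(u, v, w) where v is the current value: selecting v leaves the
  # series and the change flag untouched
  if ((u <= v && v <= w) || (u >= v && v >= w)) return(NULL)
  z <- if ((v <= u && u <= w) || (v >= u && u >= w)) u else w
  list(z = z, chg = z != v)
}

ref_split <- function(x) {
  n <- length(x); y <- x; chg <- FALSE
  if (n <= 4) return(list(y = y, chg = FALSE))
  sptest <- function(i)
    x[i] == x[i + 1] &&
      ((x[i - 1] < x[i] && x[i + 2] < x[i + 1]) ||
       (x[i - 1] > x[i] && x[i + 2] > x[i + 1]))
  if (sptest(2)) {
    y[2] <- x[1]
    y[3] <- med3_ref(x[4], x[3], 3 * x[4] - 2 * x[5])
    chg <- TRUE
  }
  if (n >= 6) for (i in 3:(n - 3)) {
    if (sptest(i)) {
      s <- ref_split_store(x[i - 1], x[i], 3 * x[i - 1] - 2 * x[i - 2])
      if (!is.null(s)) { y[i] <- s$z; chg <- s$chg }
      s <- ref_split_store(x[i + 2], x[i + 1], 3 * x[i + 2] - 2 * x[i + 3])
      if (!is.null(s)) { y[i + 1] <- s$z; chg <- s$chg }
    }
  }
  if (sptest(n - 2)) {
    y[n - 1] <- x[n]
    y[n - 2] <- med3_ref(x[n - 3], x[n - 2], 3 * x[n - 3] - 2 * x[n - 4])
    chg <- TRUE
  }
  list(y = y, chg = chg)
}

ref_3rs3r <- function(x) {
  if (length(x) < 3) return(x)
  y <- ref_sm3R(x)
  sp <- ref_split(y)
  if (sp$chg) ref_sm3R(sp$y) else y
}

# --- step-by-step transcription of the bootstrap procedure -----------------
# Mirrors the documented RNG order (row resample, then outcome draw) but
# fits every draw with the independent oracle fitters above.
boot_oracle <- function(validation, rel, spec, B, seed) {
  set.seed(seed)
  X <- model.matrix(spec$rhs, validation$covariates)
  n <- nrow(X)
  continuous <- inherits(rel, "continuous_relationship")
  est <- matrix(NA_real_, B, ncol(X))
  ses <- matrix(NA_real_, B, ncol(X))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (continuous) {
      yp <- as.numeric(validation$predicted)[idx]
      ytil <- rnorm(n, rel$gamma0 + rel$gamma1 * yp, rel$sigma_r)
      fit <- ols_oracle(X[idx, , drop = FALSE], ytil)
    } else {
      pr <- validation$probabilities[idx, rel$positive_class]
      p1 <- plogis(rel$model$gamma0 + rel$model$gamma1 * pr)
      ytil <- rbinom(n, 1L, p1)
      fit <- irls_oracle(X[idx, , drop = FALSE], ytil)
    }
    est[b, ] <- fit$coef
    ses[b, ] <- fit$se
  }
  list(estimates = est, ses = ses)
}
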