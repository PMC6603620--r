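# Shared fixtures and independent oracles. Oracles are deliberately naive
# (direct enumeration, closed forms) and never call the code paths they check.

# A short acquisition design for fast end-to-end tests: full ambient-run
# structure, reduced duration. Generator defaults themselves are untouched.
short_design <- function(duration_s = 60, runs = NULL) {
  if (is.null(runs)) {
    protocol_design(duration_s = duration_s)
  } else {
    protocol_design(runs = runs, duration_s = duration_s)
  }
}

neutral_panel <- function() {
  panel <- beverage_panel()
  panel$voc_multiplier <- 1
  panel
}

# Direct-enumeration oracle for the outlier-gated trailing moving average.
gated_ma_oracle <- function(x, window, gate_k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - window + 1):i]
    mu <- mean(w)
    sigma <- sqrt(mean((w - mu)^2))
    keep <- abs(w - mu) <= gate_k * sigma
    out[i] <- if (sigma == 0 || !any(keep)) mu else mean(w[keep])
  }
  out
}

# Plain trailing simple moving average (cumulative-sum closed form).
plain_tma <- function(x, window) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  s <- pmax(0, i - window)
  (cs - c(0, cs)[s + 1]) / (i - s)
}

# Exhaustive-split CART regression oracle matching the forest engine's
# conventions: candidate thresholds are midpoints of consecutive sorted
# unique values, assignment is x <= threshold, a node is split only when its
# size is at least min_split and some split strictly reduces the total sum
# of squares; leaves predict their mean.
cart_oracle_predict <- function(X, y, min_split = 5) {
  X <- as.matrix(X)
  pred <- numeric(nrow(X))
  grow <- function(idx) {
    ys <- y[idx]
    if (length(idx) < min_split || stats::var(ys) == 0) {
      pred[idx] <<- mean(ys)
      return(invisible())
    }
    best <- list(sse = sum((ys - mean(ys))^2), var = NA, thr = NA)
    improved <- FALSE
    for (j in seq_len(ncol(X))) {
      u <- sort(unique(X[idx, j]))
      if (length(u) < 2) next
      for (thr in (u[-1] + u[-length(u)]) / 2) {
        left <- X[idx, j] <= thr
        yl <- ys[left]; yr <- ys[!left]
        sse <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
        if (sse < best$sse - 1e-12) {
          best <- list(sse = sse, var = j, thr = thr)
          improved <- TRUE
        }
      }
    }
    if (!improved) {
      pred[idx] <<- mean(ys)
      return(invisible())
    }
    left <- X[idx, best$var] <= best$thr
    grow(idx[left])
    grow(idx[!left])
  }
  grow(seq_len(nrow(X)))
  pred
}

# 12-row regression table with three well-separated response plateaus and
# tie-free predictors; the best splits are unambiguous.
cart_fixture <- function() {
  list(X = data.frame(x1 = 1:12,
                      x2 = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 12, 10, 11) + 0.1),
       y = c(1, 1, 1, 1, 5, 5, 5, 5, 9, 9, 9, 9) +
         c(.01, -.02, .03, .01, -.01, .02, 0, .01, -.03, .02, .01, 0))
}

# Random feature matrix with an affine response, for exact-recovery checks.
affine_problem <- function(n = 40, p = 4, seed = 1, noise_sd = 0) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(runif(n * p), n, p))
    names(X) <- paste0("s", seq_len(p))
    beta <- seq_len(p)
    y <- 0.7 + as.matrix(X) %*% beta + rnorm(n, 0, noise_sd)
    list(X = X, y = as.numeric(y), beta = beta, intercept = 0.7)
  })
}
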