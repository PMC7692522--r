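# Independent line-by-line transcriptions of the four consumption-rate
# recursions, kept deliberately naive (max-form stock update, explicit
# loops) and separate from the package engine so they can serve as oracles.

oracle_ideal_W <- function(P, W_init, t0 = 5) {
  T_len <- length(P)
  W <- numeric(T_len + 1L)
  W[t0] <- W_init
  for (t in t0:T_len) {
    future <- if (t < T_len) sum(P[(t + 1):T_len]) else 0
    r <- if (future == 0) 1 else min(W[t] / future, 1)
    W[t + 1L] <- max(W[t] - floor(r * P[t]), 0)
  }
  W[t0:(T_len + 1L)]
}

oracle_main_W <- function(P, Phat, W_init, t0 = 5) {
  # Phat: plain matrix, rownames = fit weeks, Phat[t, s] = forecast of week s
  T_len <- length(P)
  W <- numeric(T_len + 1L)
  W[t0] <- W_init
  for (t in t0:T_len) {
    future <- if (t < T_len) sum(Phat[as.character(t), (t + 1):T_len]) else 0
    r <- if (future == 0) 1 else min(W[t] / future, 1)
    W[t + 1L] <- max(W[t] - floor(r * P[t]), 0)
  }
  W[t0:(T_len + 1L)]
}

oracle_s1_W <- function(P, W_init, t0 = 5) {
  T_len <- length(P)
  W <- numeric(T_len + 1L)
  W[t0] <- W_init
  for (t in t0:T_len) {
    W[t + 1L] <- W[t] - min(floor(W[t] / 2), P[t])
  }
  W[t0:(T_len + 1L)]
}

oracle_s2_W <- function(P, W_init, t0 = 5) {
  T_len <- length(P)
  W <- numeric(T_len + 1L)
  W[t0] <- W_init
  for (t in t0:T_len) {
    use <- if (t < T_len) min(floor(W[t] / (T_len - t)), P[t]) else {
      min(W[t], P[t])
    }
    W[t + 1L] <- W[t] - use
  }
  W[t0:(T_len + 1L)]
}

# Random small rationing instance (uses the current RNG; seed in the test).
rand_instance <- function(T_max = 12, W_max = 50, count_max = 20) {
  T_len <- sample(7:T_max, 1L)
  list(
    series = weekly_series("rnd", "s",
                           sample(0:count_max, T_len, replace = TRUE)),
    W_init = sample(1:W_max, 1L)
  )
}

# Wrap a plain matrix (rows named by fit week) as a forecast_matrix.
as_forecast_matrix <- function(mat, T_len, first_fit_week = 5) {
  structure(mat, class = c("forecast_matrix", "matrix"), T = T_len,
            first_fit_week = first_fit_week, sse = NULL)
}

# Forecast matrix whose entries are the true future counts.
oracle_forecasts <- function(series, t0 = 5) {
  T_len <- series$T
  fit_weeks <- t0:(T_len - 1L)
  mat <- matrix(NA_real_, nrow = length(fit_weeks), ncol = T_len,
                dimnames = list(fit_week = fit_weeks, week = 1:T_len))
  for (t in fit_weeks) {
    mat[as.character(t), (t + 1L):T_len] <- series$counts[(t + 1L):T_len]
  }
  as_forecast_matrix(mat, T_len, t0)
}
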