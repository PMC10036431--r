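# Internal helpers shared across modules.

stop_pgs <- function(message, class) {
  abort(message, class = c(class, "pgsrisk_error"))
}

# Kaplan-Meier complement (event probability) at a fixed horizon.
# Uses the last available estimate when the curve stops short of `horizon`.
km_event_prob <- function(time, event, horizon) {
  fit <- survival::survfit(Surv(time, event) ~ 1)
  idx <- findInterval(horizon, fit$time)
  if (idx == 0L) return(0)
  1 - fit$surv[idx]
}

# KM event probability with a confidence interval at `horizon`.
km_event_prob_ci <- function(time, event, horizon, conf_level = 0.95) {
  fit <- survival::survfit(Surv(time, event) ~ 1, conf.int = conf_level)
  idx <- findInterval(horizon, fit$time)
  if (idx == 0L) return(c(est = 0, lo = 0, hi = 0))
  c(est = 1 - fit$surv[idx],
    lo = 1 - fit$upper[idx],
    hi = 1 - fit$lower[idx])
}

# Deterministic sub-seed derivation; keeps results in [0, 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop_pgs(sprintf("`%s` must be a positive integer (got %s).", name,
                     paste(format(x), collapse = ", ")),
             "pgsrisk_invalid_config")
  }
  invisible(as.integer(x))
}
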