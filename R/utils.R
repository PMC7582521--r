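# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL uses the current stream
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

# ordinary least-squares slope/intercept without lm() overhead
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(intercept = my, slope = NA_real_, r2 = NA_real_))
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  res <- y - (a + b * x)
  sst <- sum((y - my)^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(res^2) / sst
  list(intercept = a, slope = b, r2 = r2)
}
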