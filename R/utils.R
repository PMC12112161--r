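# internal validators and small helpers

stop_invalid <- function(...) {
  stop(structure(class = c("slmeco_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (x < lower || (strict_lower && x <= lower))
    stop_invalid(name, " must be ", if (strict_lower) "> " else ">= ", lower)
  if (x > upper || (strict_upper && x >= upper))
    stop_invalid(name, " must be ", if (strict_upper) "< " else "<= ", upper)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower)
    stop_invalid(name, " must be an integer >= ", lower)
  invisible(as.integer(x))
}

# set.seed when a seed is supplied, without touching the caller's RNG stream
# when it is not
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_count(seed, "seed", lower = 0L)
    set.seed(seed)
  }
  expr
}

# derive a per-iteration sub-seed from a base seed, kept below 2^31
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483629)
}
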