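## Internal helpers: argument checking and hierarchical seeding.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tf <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tailflip_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lower || x > upper) {
    stop_tf("tailflip_parameter_error",
            "`%s` must be a single %s number in [%g, %g], got %s",
            name, if (finite) "finite" else "", lower, upper,
            paste(format(x), collapse = ","))
  }
  invisible(x)
}

## Derive a child RNG seed from a parent seed and an index so that per-fish
## streams are stable when the design around them changes. Kept inside
## 32-bit signed integer range.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 69621 + as.double(index) * 30011 + as.double(salt) * 104729)
  as.integer(x %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

## lognormal parameterised by mean and coefficient of variation;
## cv may be a vector (recycled against n)
rlnorm_cv <- function(n, mean, cv) {
  cv <- rep_len(cv, n)
  if (all(cv <= 0)) return(rep_len(mean, n))
  sdlog <- sqrt(log(1 + pmax(cv, 0)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
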