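# Internal helpers shared across the package.

# Byte-stable character sort (C locale), independent of the session locale.
csort <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

# Domain error with a named violated clause, caught by the CLI (exit 1).
stop_screp <- function(clause, message, ...) {
  stop(structure(
    class = c("screp_error", "error", "condition"),
    list(message = sprintf("[%s] %s", clause, sprintf(message, ...)),
         clause = clause, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

# All nonempty subsets of a character vector, as a list (2^n - 1 entries).
nonempty_subsets <- function(x) {
  n <- length(x)
  if (n == 0L) return(list())
  out <- vector("list", 2L^n - 1L)
  for (m in seq_len(2L^n - 1L)) {
    out[[m]] <- x[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  }
  out
}
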