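# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
tc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tunnelcall_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

tc_input_error <- function(msg, ...) tc_stop("tunnelcall_input_error", msg, ...)
tc_format_error <- function(msg, ...) tc_stop("tunnelcall_format_error", msg, ...)
tc_fit_error <- function(msg, ...) tc_stop("tunnelcall_fit_error", msg, ...)
tc_insufficient <- function(msg, ...) tc_stop("tunnelcall_insufficient_data", msg, ...)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All public stochastic entry points funnel through this.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    tc_input_error("`seed` must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

split_letters <- function(s) {
  if (length(s) == 1L && is.character(s)) strsplit(s, "", fixed = TRUE)[[1L]] else as.character(s)
}

join_letters <- function(x) paste(x, collapse = "")

check_sequence <- function(sequence, alphabet) {
  letters <- split_letters(sequence)
  if (length(letters) == 0L) tc_input_error("sequence must be non-empty")
  bad <- setdiff(unique(letters), alphabet)
  if (length(bad) > 0L) {
    tc_input_error("sequence contains symbols outside the alphabet {%s}: %s",
                   paste(alphabet, collapse = ", "), paste(bad, collapse = ", "))
  }
  letters
}

# Sample standard deviations of the columns of a matrix (n-1 denominator).
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}
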