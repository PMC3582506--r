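#' @keywords internal
"_PACKAGE"

# Internal parameter checks -------------------------------------------------

stop_domain <- function(...) {
  stop(structure(
    class = c("ddrdyn_domain_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_domain(name, " must be > ", lower)
  }
  if (!strict_lower && x < lower) {
    stop_domain(name, " must be >= ", lower)
  }
  if (strict_upper && x >= upper) {
    stop_domain(name, " must be < ", upper)
  }
  if (!strict_upper && x > upper) {
    stop_domain(name, " must be <= ", upper)
  }
  invisible(x)
}

check_times <- function(t, name = "t", positive = FALSE) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t))) {
    stop_domain(name, " must be finite numeric")
  }
  if (positive && any(t <= 0)) {
    stop_domain(name, " must be strictly positive")
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop_domain(name, " must be strictly increasing")
  }
  invisible(t)
}

# Display helper matching the two-significant-figure table convention.
signif2 <- function(x) signif(x, 2)
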