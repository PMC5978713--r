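# Classed error helper so callers can distinguish degenerate plans,
# empty cohorts, etc. from programming errors.
stop_jawsearch <- function(message, class, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "jawsearch_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

# Full-precision numeric formatting for text artifacts; "%.17g" round-trips
# IEEE doubles exactly through as.numeric().
fmt_num <- function(x) sprintf("%.17g", x)
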