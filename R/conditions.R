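# Classed error helper: every user-facing failure mode gets a condition
# class so callers (and the CLI) can distinguish input errors, domain
# violations and fit failures.

tv_stop <- function(message, class) {
  stop(structure(
    class = c(class, "tv_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}
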