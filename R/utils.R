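## internal condition helpers: errors carry a class so callers/tests can
## distinguish placement failures from plain misuse

nsError <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "numerosenseError", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## draw one multiplicity value from a probability vector over 1, 2, ...
sampleMultiplicity <- function(prob) {
  if (length(prob) == 1L) return(1L)
  sample.int(length(prob), 1L, prob = prob)
}
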