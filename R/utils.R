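#' @keywords internal
"_PACKAGE"

## Derive a reproducible sub-stream seed from a master seed and a tag.
## Keeps results per component (schedule / feedback / agent / noise)
## independently reproducible while staying below .Machine$integer.max.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer(((abs(seed) %% 1000003) * 7919 + h * 104729) %% 2147483629) + 1L
}

otherMapping <- function(mapping) {
  ifelse(mapping == "A", "B", "A")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

isWhole <- function(x, tol = 1e-9) abs(x - round(x)) < tol
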