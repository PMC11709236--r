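## Internal helpers shared across modules.

## Round half-up to `digits` decimals; base round() is half-to-even, which
## does not reproduce printed percentage tables.
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

## Evaluate `expr` under a deterministic RNG state derived from `seed`,
## restoring any pre-existing state afterwards. All simulator sub-streams
## flow through this.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647L), kind = "Mersenne-Twister")
    expr
}

## Derive a bounded sub-stream seed from a master seed and a stage offset.
subSeed <- function(seed, offset) {
    (as.double(seed) * 131L + offset) %% 2147483647
}

stopIfNot01 <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value < 0 || value > 1)
        stop(sprintf("parameter '%s' must be a single value in [0, 1]", field),
             call. = FALSE)
    invisible(value)
}
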