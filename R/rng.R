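## Reproducible sub-streams: one master seed is split into independent
## L'Ecuyer-CMRG streams, one per sampled record field, so changing how one
## field is drawn never perturbs the draws of another.

fieldStreams <- function() {
    c(genotype = 1L, mi = 2L, irt1 = 3L, irt2 = 4L, sweat = 5L,
      uptake = 6L, contact = 7L)
}

#' Evaluate an expression under a dedicated RNG sub-stream
#'
#' Sets the RNG to L'Ecuyer-CMRG seeded with `seed`, advances `index`
#' independent streams, evaluates `expr`, and restores the caller's RNG
#' state. Stream indices are fixed per sampled field, so the draws of one
#' field are unchanged when another field's sampler changes.
#'
#' @param seed master integer seed.
#' @param index non-negative stream index.
#' @param expr expression to evaluate under the sub-stream.
#' @return The value of `expr`.
#' @keywords internal
withSubstream <- function(seed, index, expr) {
    stopifnot(length(seed) == 1L, is.finite(seed),
              length(index) == 1L, index >= 0L)
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
    s <- get(".Random.seed", envir = genv, inherits = FALSE)
    for (i in seq_len(index)) s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, envir = genv)
    expr
}
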