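## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded package internals
#' never perturb the caller's RNG stream. All stochastic operations in the
#' package thread seeds explicitly through this helper; there is no hidden
#' global state.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single non-missing number")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    expr
}

## Derive a per-mutant sub-seed from a base seed; kept below 2^31.
subSeed <- function(seed, index) {
    as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %%
                   2147483647)
}

## 0-based half-open interval [a, b) -> IRanges (1-based closed).
## A zero-length junction point at p is represented as width-1 at p+1 so
## that it intersects [a, b) iff a <= p < b under findOverlaps().
asIRanges0 <- function(start0, end0 = start0) {
    point <- end0 <= start0
    IRanges::IRanges(start = start0 + 1L,
                     end = ifelse(point, start0 + 1L, end0))
}

## single-linkage 1D clustering: positions within 'gap' of the previous
## member (after sorting) share a cluster id. Returns cluster ids in the
## original order of 'pos'.
chain1d <- function(pos, gap) {
    if (length(pos) == 0L) return(integer(0))
    o <- order(pos)
    p <- pos[o]
    brk <- c(FALSE, diff(p) > gap)
    id <- cumsum(brk) + 1L
    out <- integer(length(pos))
    out[o] <- id
    out
}

## Weighted reservoir-free sampling of one index per row given a matrix-free
## setting; plain helper to draw event classes.
drawClasses <- function(n, classes, probs) {
    sample(classes, size = n, replace = TRUE, prob = probs)
}

stopIfNot0 <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
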