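#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; reported ratios here follow the
#' half-up convention of the source tables (82.05 -> 82.1 at one decimal).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Gap in nt between 0-based half-open intervals [a1,a2) and [b1,b2);
# 0 when they overlap or touch is not possible (touching intervals have gap 0
# only if they share a position; adjacency [0,5) vs [5,9) has gap 0 here by
# the max() arithmetic: 5 - 5 = 0).
intervalGap <- function(a1, a2, b1, b2) {
    pmax(0, pmax(b1 - a2, a1 - b2))
}

# Full containment of [a1,a2) within [b1,b2)
intervalWithin <- function(a1, a2, b1, b2) {
    a1 >= b1 & a2 <= b2
}

# Derive a per-stage RNG seed from a master seed; stays below 2^31.
stageSeed <- function(seed, stage) {
    offsets <- c(simulate = 11L, genome = 101L, promoter = 211L,
                 network = 307L, associate = 401L, discover = 503L)
    off <- if (stage %in% names(offsets)) offsets[[stage]] else
        sum(utf8ToInt(stage))
    as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# md5 of an R object via its serialization (version 3, no header variance).
objectHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    con <- file(f, "wb")
    serialize(x, con, version = 3L, xdr = TRUE)
    close(con)
    unname(tools::md5sum(f))
}

stopIfMissingCols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    invisible(df)
}
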