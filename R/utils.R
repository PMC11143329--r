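`%||%` <- function(a, b) if (is.null(a)) b else a

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.isNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a named sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline (fold shuffling, permutation,
#' jitter, optimizer seeding) draws its own seed deterministically from one
#' master seed and a stage name, so stages are independently reproducible.
#' Uses an FNV-1a hash of the name folded into the seed, reduced modulo
#' 2^31 - 1 to stay within R's integer range.
#'
#' @param seed Integer master seed.
#' @param name Character stage name.
#' @return A single integer in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, name) {
    stopifnot(.isNumber(seed), is.character(name), length(name) == 1L)
    h <- 2166136261
    for (b in utf8ToInt(name)) {
        h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
        h <- (h * 16777619) %% (2^31 - 1)
    }
    as.integer((abs(seed) + h) %% (2^31 - 1))
}

# Deterministic FNV-1a hash of a character scalar, as 8 hex digits.
.hashString <- function(x) {
    h <- 2166136261
    for (b in utf8ToInt(x)) {
        h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
        h <- (h * 16777619) %% (2^31 - 1)
    }
    sprintf("%08x", as.integer(h))
}

# Stable hash of an R object via its canonical JSON form.
.hashObject <- function(x) {
    .hashString(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                              digits = 10, force = TRUE)))
}

# Arc-length resampling of a polyline at a fixed step (mm). Returns a matrix
# with >= 2 rows; consecutive duplicated input points are collapsed first.
.resamplePolyline <- function(points, step) {
    keep <- c(TRUE, rowSums(abs(diff(points))) > 1e-12)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 2L) return(points[c(1L, 1L), , drop = FALSE])
    seg <- sqrt(rowSums(diff(points)^2))
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    t <- unique(c(seq(0, total, by = step), total))
    cbind(approx(s, points[, 1], xout = t)$y,
          approx(s, points[, 2], xout = t)$y,
          approx(s, points[, 3], xout = t)$y)
}

# Stack resampled streamlines into one point matrix plus 0-based offsets for
# the C++ kernels. Cached on the tractogram via an attribute-free helper.
.stackStreamlines <- function(streamlines, step) {
    pts <- lapply(streamlines, .resamplePolyline, step = step)
    n <- vapply(pts, nrow, integer(1))
    list(pts = do.call(rbind, pts),
         offsets = as.integer(c(0L, cumsum(n))))
}
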