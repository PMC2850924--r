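# Shared constants: residue alphabet, background frequencies, hydropathy
# scale, structural element vocabulary.

#' The 20 canonical amino acids
#'
#' Single-letter codes of the 20 canonical amino acids, in the fixed order
#' used for every emission matrix and count table in the package.  `X`
#' (unknown residue) is additionally accepted in sequences and scores as
#' background (zero log-odds contribution); it is never a profile symbol.
#'
#' @return Character vector of length 20.
#' @examples
#' aminoAcids()
#' @export
aminoAcids <- function() .AA20

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.AA_ALPHABET <- c(.AA20, "X")

#' Background amino-acid frequencies
#'
#' Residue frequencies used as the null model for profile log-odds scores,
#' pseudocounts, E-value calibration and the synthetic generator.  The
#' default table is a fixed Swiss-Prot-like composition shipped with the
#' package so that no download is required; a uniform background (1/20) is
#' available for controlled tests.
#'
#' @param type `"swissprot"` (default) or `"uniform"`.
#' @return Named numeric vector of length 20 summing to 1, in
#'   [aminoAcids()] order.
#' @examples
#' backgroundFrequencies()["W"]
#' @export
backgroundFrequencies <- function(type = c("swissprot", "uniform")) {
    type <- match.arg(type)
    if (type == "uniform") {
        f <- rep(1 / 20, 20)
        names(f) <- .AA20
        return(f)
    }
    .BG_SWISSPROT
}

# Swiss-Prot-like residue composition (fractions), normalised at load time.
.BG_SWISSPROT <- local({
    f <- c(A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
           G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
           M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
           S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)
    f / sum(f)
})

# Kyte-Doolittle hydropathy indices.
.KYTE_DOOLITTLE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                     G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                     M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                     S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Structural elements of the Alpha Crystallin Domain
#'
#' Ordered vocabulary of the beta-strand and loop labels used to annotate
#' seed-alignment columns, from strand beta2 to strand beta9.  The three
#' analysis zones are derived from it: the beta2-beta5 zone (`b2` through
#' `b5`), the L57 loop, and the beta7-beta9 zone (`b7` through `b9`).
#'
#' @return Character vector of the 13 element labels in structural order.
#' @examples
#' acdElements()
#' @export
acdElements <- function() .ACD_ELEMENTS

.ACD_ELEMENTS <- c("b2", "L23", "b3", "L34", "b4", "L45", "b5",
                   "L57", "b7", "L78", "b8", "L89", "b9")

.ACD_ZONES <- c(b2 = "b2b5", L23 = "b2b5", b3 = "b2b5", L34 = "b2b5",
                b4 = "b2b5", L45 = "b2b5", b5 = "b2b5",
                L57 = "L57",
                b7 = "b7b9", L78 = "b7b9", b8 = "b7b9", L89 = "b7b9",
                b9 = "b7b9")

# Single-character codes used on the "#=GC ACD_elements" Stockholm line.
.ELEMENT_CODES <- c("2" = "b2", "a" = "L23", "3" = "b3", "b" = "L34",
                    "4" = "b4", "c" = "L45", "5" = "b5", "L" = "L57",
                    "7" = "b7", "d" = "L78", "8" = "b8", "e" = "L89",
                    "9" = "b9")

#' Zone of a structural element
#'
#' @param element Character vector of element labels (see [acdElements()]).
#' @return Character vector with values `"b2b5"`, `"L57"` or `"b7b9"`.
#' @examples
#' zoneOfElement(c("b3", "L57", "b9"))
#' @export
zoneOfElement <- function(element) {
    bad <- !element %in% .ACD_ELEMENTS
    if (any(bad))
        stop("unknown ACD element label(s): ",
             paste(unique(element[bad]), collapse = ", "))
    unname(.ACD_ZONES[element])
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic operations in the
# package funnel through this so that results are reproducible without
# clobbering the user's RNG.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Deterministic sub-seed derivation; stays well inside 32-bit range.
deriveSeed <- function(master, index) {
    as.integer((as.numeric(master) %% 1000003) * 1009 + index) %% 2147483587L
}

# Cheap deterministic checksum of a numeric object (used in iteration
# traces).  Hashes the rounded decimal rendering so that equal profiles give
# equal checksums across runs.
numericChecksum <- function(x) {
    s <- paste(sprintf("%.10g", as.numeric(x)), collapse = ",")
    r <- as.integer(charToRaw(s))
    h <- 5381
    for (v in r) h <- (h * 33 + v) %% 4294967291
    sprintf("%08x", as.integer(h %% 2147483647))
}
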