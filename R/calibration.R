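# Gumbel (extreme-value) calibration of profile scores and E-values.

.EULER_GAMMA <- 0.577215664901532860606512

#' Fit a Gumbel distribution to a sample of scores
#'
#' Method-of-moments initialisation (`lambda = pi / (sd * sqrt(6))`,
#' `mu = mean - gamma / lambda`) followed by maximum-likelihood refinement
#' of the Gumbel location/scale.
#'
#' @param scores Numeric vector of at least 100 finite scores with
#'   non-degenerate variance.
#' @param nSamples,sampleLength,seed Bookkeeping recorded on the returned
#'   object (default: taken from `scores` / `NA`).
#' @return A [GumbelFit-class].
#' @examples
#' set.seed(1)
#' x <- 10 - log(-log(runif(5000))) / 0.7   # Gumbel(mu = 10, lambda = 0.7)
#' fitGumbel(x)
#' @export
fitGumbel <- function(scores, nSamples = length(scores),
                      sampleLength = NA_integer_, seed = NA_integer_) {
    scores <- as.numeric(scores)
    if (length(scores) < 100)
        stop("Gumbel fitting needs at least 100 scores (got ",
             length(scores), ")")
    if (any(!is.finite(scores)))
        stop("non-finite scores in calibration sample")
    s <- stats::sd(scores)
    if (!is.finite(s) || s < 1e-12)
        stop("degenerate score variance; cannot calibrate")
    lambda0 <- pi / (s * sqrt(6))
    mu0 <- mean(scores) - .EULER_GAMMA / lambda0
    nll <- function(par) {
        mu <- par[1]; lambda <- exp(par[2])
        z <- lambda * (scores - mu)
        sum(z + exp(-z)) - length(scores) * log(lambda)
    }
    opt <- stats::optim(c(mu0, log(lambda0)), nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    new("GumbelFit", mu = opt$par[1], lambda = exp(opt$par[2]),
        nSamples = as.integer(nSamples),
        sampleLength = as.integer(sampleLength),
        seed = as.integer(seed))
}

#' Sample random background sequences
#'
#' @param n Number of sequences.
#' @param length Residues per sequence.
#' @param background Frequencies to draw from.
#' @return Character vector of residue strings (uses the current RNG
#'   state; wrap in a seed yourself or use [calibrateProfile()]).
#' @export
randomSequences <- function(n, length, background = backgroundFrequencies()) {
    bg <- background / sum(background)
    vapply(seq_len(n), function(i)
        paste(sample(.AA20, length, replace = TRUE, prob = bg),
              collapse = ""),
        character(1))
}

#' Calibrate a profile: fit the Gumbel law of random-sequence scores
#'
#' Scores `n` i.i.d. background sequences of the given length with the
#' glocal Viterbi scorer and fits a [GumbelFit-class] to the resulting bit
#' scores.  Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param p A [ProfileHMM-class].
#' @param n Number of random sequences (>= 100); default 200.
#' @param length Random-sequence length; default 150.
#' @param seed Integer seed.
#' @return The profile with its `calibration` slot set.
#' @export
calibrateProfile <- function(p, n = 200L, length = 150L, seed = 1L) {
    stopifnot(is(p, "ProfileHMM"))
    if (n < 100) stop("calibration needs n >= 100 (got ", n, ")")
    seqs <- withSeed(seed, randomSequences(n, length, p@background))
    scores <- vapply(seqs, function(s) viterbiScore(p, s)$score,
                     numeric(1), USE.NAMES = FALSE)
    fit <- fitGumbel(scores, nSamples = n, sampleLength = length,
                     seed = seed)
    calibration(p) <- fit
    p
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `E = dbSize * (1 - exp(-exp(-lambda * (score - mu))))`: the expected
#' number of sequences in a databank of `dbSize` reaching `score` by
#' chance.  Monotonically decreasing in the score.
#'
#' @param score Bit score(s).
#' @param fit A [GumbelFit-class].
#' @param dbSize Number of sequences scanned.
#' @return Numeric E-value(s).
#' @examples
#' fit <- new("GumbelFit", mu = 10, lambda = 0.7, nSamples = 1000L,
#'            sampleLength = 150L, seed = 1L)
#' eValue(10, fit, dbSize = 1000)   # 1000 * (1 - exp(-1))
#' @export
eValue <- function(score, fit, dbSize) {
    stopifnot(is(fit, "GumbelFit"), dbSize >= 0)
    dbSize * (1 - exp(-exp(-fit@lambda * (score - fit@mu))))
}
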