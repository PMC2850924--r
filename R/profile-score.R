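# Scoring sequences against a profile: glocal Viterbi (with traceback for
# the column map) and forward.

#' @useDynLib acdscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.encodeSeq <- function(residues) {
    ch <- strsplit(toupper(residues), "")[[1]]
    bad <- setdiff(unique(ch), .AA_ALPHABET)
    if (length(bad))
        stop("illegal residue character(s): ", paste(bad, collapse = ", "))
    out <- match(ch, .AA20) - 1L
    out[is.na(out)] <- -1L          # X: background, zero log-odds
    out
}

.safeLog2 <- function(x) ifelse(x > 0, log2(x), -1e300)

.profileScoringParts <- function(p) {
    bg <- p@background
    list(lm = log2(sweep(p@matchEmit, 2, bg, "/")),
         li = log2(sweep(p@insertEmit, 2, bg, "/")),
         ltMM = .safeLog2(p@tMM), ltMI = .safeLog2(p@tMI),
         ltMD = .safeLog2(p@tMD), ltIM = .safeLog2(p@tIM),
         ltII = .safeLog2(p@tII), ltDM = .safeLog2(p@tDM),
         ltDD = .safeLog2(p@tDD))
}

#' Glocal Viterbi score and alignment of one sequence
#'
#' Aligns the *entire* profile (all columns, deletions allowed) to one
#' contiguous subsequence of the target and returns the best-path bit
#' score, `log2(P(path) / P_background(aligned subsequence))`, together
#' with the alignment.  Ties are broken toward match over delete over
#' insert, so the traceback is deterministic.
#'
#' @param p A [ProfileHMM-class].
#' @param residues Non-empty residue string (20 canonical amino acids plus
#'   `X`; `X` scores as background).
#' @return A list: `score` (bits), `map` (integer length M: target
#'   position of each profile column, `NA` for a deleted column),
#'   `inserts` (integer length M + 1: inserted residues after each
#'   position, index 1 = before column 1), `envStart`, `envEnd` (1-based
#'   inclusive envelope on the target).
#' @examples
#' # single-path toy: M = 1, delta emission on A, uniform background
#' p <- toyProfile(matrix(c(1, rep(0, 19)), 1, byrow = TRUE))
#' viterbiScore(p, "A")$score  # log2(20)
#' @export
viterbiScore <- function(p, residues) {
    stopifnot(is(p, "ProfileHMM"), nchar(residues) > 0)
    parts <- .profileScoringParts(p)
    r <- viterbi_glocal(parts$lm, parts$li, parts$ltMM, parts$ltMI,
                        parts$ltMD, parts$ltIM, parts$ltII, parts$ltDM,
                        parts$ltDD, .encodeSeq(residues))
    map <- r$map
    map[map == 0L] <- NA_integer_
    list(score = r$score, map = map, inserts = r$inserts,
         envStart = r$envStart, envEnd = r$envEnd)
}

#' Glocal forward score of one sequence
#'
#' As [viterbiScore()] but summing probability over all glocal paths;
#' always greater than or equal to the Viterbi score.
#'
#' @inheritParams viterbiScore
#' @return Bit score (numeric scalar).
#' @export
forwardScore <- function(p, residues) {
    stopifnot(is(p, "ProfileHMM"), nchar(residues) > 0)
    parts <- .profileScoringParts(p)
    forward_glocal(parts$lm, parts$li, parts$ltMM, parts$ltMI,
                   parts$ltMD, parts$ltIM, parts$ltII, parts$ltDM,
                   parts$ltDD, .encodeSeq(residues))
}

#' Construct a small profile directly from probability tables
#'
#' Test/exploration helper building a [ProfileHMM-class] from explicit
#' emission and transition tables, bypassing alignment compilation.
#' Defaults give an indel-free profile (`M -> M` probability 1) with a
#' uniform background and all columns labelled `b2`.
#'
#' @param matchEmit `M x 20` matrix of match emission probabilities.
#' @param tMM,tMI,tMD,tIM,tII,tDM,tDD Optional transition vectors, length
#'   `M + 1` (see [ProfileHMM-class]); sensible deterministic defaults.
#' @param background 20 frequencies; default uniform.
#' @param landmarks Character length `M`; default all `"b2"`.
#' @param insertEmit Optional `(M + 1) x 20`; default background rows.
#' @return A [ProfileHMM-class].
#' @export
toyProfile <- function(matchEmit, tMM = NULL, tMI = NULL, tMD = NULL,
                       tIM = NULL, tII = NULL, tDM = NULL, tDD = NULL,
                       background = backgroundFrequencies("uniform"),
                       landmarks = NULL, insertEmit = NULL) {
    M <- nrow(matchEmit)
    colnames(matchEmit) <- .AA20
    if (is.null(tMM)) tMM <- rep(1, M + 1)
    if (is.null(tMI)) tMI <- rep(0, M + 1)
    if (is.null(tMD)) tMD <- rep(0, M + 1)
    if (is.null(tIM)) tIM <- rep(1, M + 1)
    if (is.null(tII)) tII <- rep(0, M + 1)
    if (is.null(tDM)) tDM <- rep(1, M + 1)
    if (is.null(tDD)) tDD <- rep(0, M + 1)
    if (is.null(landmarks)) landmarks <- rep("b2", M)
    if (is.null(insertEmit))
        insertEmit <- matrix(background / sum(background), M + 1, 20,
                             byrow = TRUE, dimnames = list(NULL, .AA20))
    new("ProfileHMM", matchEmit = matchEmit, insertEmit = insertEmit,
        tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
        tDM = tDM, tDD = tDD,
        background = stats::setNames(background / sum(background), .AA20),
        landmarks = landmarks, calibration = NULL)
}
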