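#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings AAStringSet
NULL

#' SequenceBank: a protein databank with curation metadata
#'
#' Container for the target databank: amino-acid sequences (20 canonical
#' residues plus `X`) together with the per-record curation metadata used
#' by the pipeline (taxonomic lineage, fragment flag, protein-existence
#' level 1-5 where 5 means unknown).
#'
#' @slot seqs An [Biostrings::AAStringSet] holding the residues; names are
#'   the accessions.
#' @slot meta A [S4Vectors::DataFrame] with one row per sequence and
#'   columns `description` (character), `lineage` (list of character
#'   vectors, possibly empty), `isFragment` (logical) and
#'   `existenceLevel` (integer in 1..5).
#'
#' @seealso [readFastaBank()], [readMetadata()]
#' @export
setClass("SequenceBank",
         representation(seqs = "AAStringSet", meta = "DataFrame"))

setValidity("SequenceBank", function(object) {
    n <- length(object@seqs)
    msg <- character()
    if (nrow(object@meta) != n)
        msg <- c(msg, "metadata row count must match number of sequences")
    need <- c("description", "lineage", "isFragment", "existenceLevel")
    if (!all(need %in% colnames(object@meta)))
        msg <- c(msg, paste("metadata must have columns:",
                            paste(need, collapse = ", ")))
    if (n > 0) {
        if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
            msg <- c(msg, "sequences must have unique accession names")
        w <- Biostrings::width(object@seqs)
        if (any(w == 0))
            msg <- c(msg, "residue strings must be non-empty")
        letters <- unique(unlist(strsplit(as.character(object@seqs), "")))
        bad <- setdiff(letters, .AA_ALPHABET)
        if (length(bad))
            msg <- c(msg, paste0("illegal residue character(s): ",
                                 paste(bad, collapse = ", ")))
        el <- object@meta$existenceLevel
        if (!all(el %in% 1:5))
            msg <- c(msg, "existenceLevel must be an integer in 1..5")
    }
    if (length(msg)) msg else TRUE
})

#' AcdAlignment: a gapped multiple alignment
#'
#' Minimal alignment container used for both the seed alignment and
#' profile-realigned hit sets.  Rows are gapped strings of equal width;
#' `-` marks a gap in a match-type column while insert-type columns (as
#' produced by [hitsToAlignment()]) carry lowercase residues and are padded
#' with `.`.
#'
#' @slot sequences Named character vector of gapped rows (names are
#'   accessions).
#'
#' @export
setClass("AcdAlignment", representation(sequences = "character"))

setValidity("AcdAlignment", function(object) {
    s <- object@sequences
    msg <- character()
    if (length(s) < 2)
        msg <- c(msg, "an alignment needs at least 2 rows")
    if (length(s) && length(unique(nchar(s))) != 1)
        msg <- c(msg, "all gapped rows must have equal length (ragged rows)")
    if (length(s) && nchar(s[1]) == 0)
        msg <- c(msg, "alignment must have at least one column")
    if (is.null(names(s)) || any(names(s) == ""))
        msg <- c(msg, "alignment rows must be named by accession")
    letters <- unique(unlist(strsplit(s, "")))
    bad <- setdiff(letters, c(.AA_ALPHABET, tolower(.AA_ALPHABET), "-", "."))
    if (length(bad))
        msg <- c(msg, paste0("illegal alignment character(s): ",
                             paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' AcdAlignment constructor
#'
#' @param sequences Named character vector of equal-length gapped rows.
#' @return An [AcdAlignment-class] object.
#' @examples
#' AcdAlignment(c(A = "AC-E", B = "ACDE"))
#' @export
AcdAlignment <- function(sequences) {
    new("AcdAlignment", sequences = sequences)
}

#' SeedAnnotation: structural landmarks on alignment columns
#'
#' Maps alignment (or profile) columns to the structural elements of the
#' Alpha Crystallin Domain, `b2` through `b9` (see [acdElements()]).
#' Columns outside the labelled beta2..beta9 range are `NA`.  Validity
#' enforces the structural order of elements, contiguity of each element,
#' and full coverage of the labelled range, so the three zones
#' (beta2-beta5, L57, beta7-beta9) always partition it.
#'
#' @slot elements Character vector, one label (or `NA`) per column.
#'
#' @export
setClass("SeedAnnotation", representation(elements = "character"))

setValidity("SeedAnnotation", function(object) {
    e <- object@elements
    msg <- character()
    lab <- which(!is.na(e))
    if (!length(lab))
        return("annotation labels no column")
    bad <- setdiff(e[lab], .ACD_ELEMENTS)
    if (length(bad))
        return(paste0("unknown element label(s): ", paste(bad, collapse = ", ")))
    if (any(is.na(e[min(lab):max(lab)])))
        msg <- c(msg, "every column between the first and last labelled column must be labelled")
    idx <- match(e[lab], .ACD_ELEMENTS)
    if (any(diff(idx) < 0))
        msg <- c(msg, "element labels must appear in structural order (b2..b9)")
    r <- rle(e[lab])
    if (anyDuplicated(r$values))
        msg <- c(msg, "each element must occupy one contiguous block of columns")
    if (length(msg)) msg else TRUE
})

#' SeedAnnotation constructor
#'
#' @param elements Character vector of element labels (or `NA`) per column.
#' @return A [SeedAnnotation-class] object.
#' @examples
#' SeedAnnotation(c("b2", "b2", "L23", "b3"))
#' @export
SeedAnnotation <- function(elements) {
    new("SeedAnnotation", elements = as.character(elements))
}

#' GumbelFit: extreme-value calibration of profile scores
#'
#' Location/scale parameters of the Gumbel (type-I extreme value)
#' distribution fitted to glocal bit scores of random background sequences;
#' behind every E-value reported by the package.
#'
#' @slot mu Location, in bits.
#' @slot lambda Scale (1/bits), strictly positive.
#' @slot nSamples Number of random sequences scored (>= 100).
#' @slot sampleLength Length of each random sequence.
#' @slot seed Integer seed the calibration was run with.
#'
#' @seealso [calibrateProfile()], [fitGumbel()], [eValue()]
#' @export
setClass("GumbelFit",
         representation(mu = "numeric", lambda = "numeric",
                        nSamples = "integer", sampleLength = "integer",
                        seed = "integer"))

setValidity("GumbelFit", function(object) {
    msg <- character()
    if (length(object@lambda) != 1 || !is.finite(object@lambda) ||
        object@lambda <= 0)
        msg <- c(msg, "lambda must be a single positive number")
    if (length(object@mu) != 1 || !is.finite(object@mu))
        msg <- c(msg, "mu must be a single finite number")
    if (object@nSamples < 100L)
        msg <- c(msg, "nSamples must be >= 100")
    if (length(msg)) msg else TRUE
})

setClassUnion("GumbelFitOrNULL", c("GumbelFit", "NULL"))

#' ProfileHMM: a glocal profile hidden Markov model of the ACD
#'
#' Match/insert/delete profile with background log-odds scoring.  The
#' architecture is the classic profile HMM: match states `M_1..M_M`,
#' insert states `I_0..I_M` and delete states `D_1..D_M`, with entry
#' `B -> {M_1, I_0, D_1}` and exit from `M_M`, `I_M` or `D_M`.  Scoring is
#' glocal: every profile column must be visited (as match or delete) while
#' the alignment is local in the target sequence, so partial domains never
#' match.
#'
#' Transition vectors have length `M + 1`; index `k` holds the transitions
#' *from position* `k - 1` (position 0 is entry `B`, position `M` leads to
#' exit `E`).  `tDM[1]`/`tDD[1]` are structural placeholders (`1`/`0`)
#' since `D_0` does not exist, and `tMD[M + 1]` is 0 since there is no
#' `D_{M+1}`.
#'
#' @slot matchEmit `M x 20` matrix of match emission probabilities (rows
#'   sum to 1), columns in [aminoAcids()] order.
#' @slot insertEmit `(M + 1) x 20` matrix of insert emission probabilities
#'   for `I_0..I_M`.
#' @slot tMM,tMI,tMD Numeric, length `M + 1`: from-match transitions.
#' @slot tIM,tII Numeric, length `M + 1`: from-insert transitions.
#' @slot tDM,tDD Numeric, length `M + 1`: from-delete transitions.
#' @slot background Named numeric vector of length 20 (null model).
#' @slot landmarks Character vector, length `M`: structural element of each
#'   profile column (see [acdElements()]).
#' @slot calibration A [GumbelFit-class] or `NULL` if the profile has not
#'   been calibrated yet.
#'
#' @seealso [buildProfile()], [viterbiScore()], [scanBank()]
#' @export
setClass("ProfileHMM",
         representation(matchEmit = "matrix", insertEmit = "matrix",
                        tMM = "numeric", tMI = "numeric", tMD = "numeric",
                        tIM = "numeric", tII = "numeric",
                        tDM = "numeric", tDD = "numeric",
                        background = "numeric", landmarks = "character",
                        calibration = "GumbelFitOrNULL"))

setValidity("ProfileHMM", function(object) {
    M <- nrow(object@matchEmit)
    msg <- character()
    tol <- 1e-9
    if (M < 1) return("profile must have at least one match state")
    if (ncol(object@matchEmit) != 20 || ncol(object@insertEmit) != 20)
        msg <- c(msg, "emission matrices must have 20 columns")
    if (nrow(object@insertEmit) != M + 1)
        msg <- c(msg, "insertEmit must have M + 1 rows (I_0..I_M)")
    if (any(abs(rowSums(object@matchEmit) - 1) > tol) ||
        any(abs(rowSums(object@insertEmit) - 1) > tol))
        msg <- c(msg, "every emission row must sum to 1 (tol 1e-9)")
    for (v in c("tMM", "tMI", "tMD", "tIM", "tII", "tDM", "tDD"))
        if (length(slot(object, v)) != M + 1)
            msg <- c(msg, paste0(v, " must have length M + 1"))
    if (!length(msg)) {
        sM <- object@tMM + object@tMI + object@tMD
        if (any(abs(sM - 1) > tol))
            msg <- c(msg, "match transition groups must sum to 1")
        if (abs(object@tMD[M + 1]) > tol)
            msg <- c(msg, "M_M -> D transition must be 0 (no D_{M+1})")
        sI <- object@tIM + object@tII
        if (any(abs(sI - 1) > tol))
            msg <- c(msg, "insert transition groups must sum to 1")
        sD <- (object@tDM + object@tDD)[-1]
        if (any(abs(sD - 1) > tol))
            msg <- c(msg, "delete transition groups must sum to 1")
        if (M >= 1 && abs(object@tDD[M + 1]) > tol)
            msg <- c(msg, "D_M -> D transition must be 0")
    }
    if (length(object@background) != 20 ||
        abs(sum(object@background) - 1) > 1e-6 || any(object@background <= 0))
        msg <- c(msg, "background must be 20 positive frequencies summing to 1")
    if (length(object@landmarks) != M)
        msg <- c(msg, "landmark map must cover columns 1..M")
    else if (any(is.na(object@landmarks)) ||
             !all(object@landmarks %in% .ACD_ELEMENTS))
        msg <- c(msg, "landmarks must be valid ACD element labels")
    if (length(msg)) msg else TRUE
})

#' LogoMatrix: gap-aware sequence-logo counts and information content
#'
#' Per-profile-column counts over 21 symbols (20 amino acids plus the gap
#' symbol `-`).  Gaps enter the information-content computation as an
#' explicit 21st symbol but are not drawn: letter heights are
#' `freq(aa) * I(c)` for the 20 amino acids only.
#'
#' @slot counts `M x 21` matrix of non-negative counts (columns:
#'   [aminoAcids()] then `-`).
#' @slot info Numeric length `M`: information content in bits,
#'   `I(c) = log2(21) - H(c)` (`NA` for columns with zero observations).
#' @slot heights `M x 20` matrix of drawn letter heights.
#'
#' @seealso [logoCounts()]
#' @export
setClass("LogoMatrix",
         representation(counts = "matrix", info = "numeric",
                        heights = "matrix"))

setValidity("LogoMatrix", function(object) {
    msg <- character()
    if (ncol(object@counts) != 21)
        msg <- c(msg, "counts must have 21 columns (20 aa + gap)")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(object@info) != nrow(object@counts))
        msg <- c(msg, "info must have one entry per column")
    ok <- !is.na(object@info)
    if (any(object@info[ok] < -1e-9 | object@info[ok] > log2(21) + 1e-9))
        msg <- c(msg, "information content must lie in [0, log2(21)]")
    if (ncol(object@heights) != 20 ||
        nrow(object@heights) != nrow(object@counts))
        msg <- c(msg, "heights must be an M x 20 matrix")
    if (length(msg)) msg else TRUE
})
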