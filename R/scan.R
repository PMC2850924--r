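# Databank scanning: one best glocal hit per sequence, E-value thresholded.

#' @importFrom IRanges IntegerList
NULL

.emptyHits <- function() {
    DataFrame(accession = character(0), acdStart = integer(0),
              acdEnd = integer(0), bitScore = numeric(0),
              eValue = numeric(0), multiAcd = logical(0),
              columnMap = IRanges::IntegerList(),
              insertCounts = IRanges::IntegerList())
}

#' Scan a databank for complete-ACD hits
#'
#' Scores every sequence with the glocal Viterbi scorer, converts bit
#' scores to E-values with the profile's Gumbel calibration (the databank
#' size is the number of sequences scanned) and keeps, per sequence, the
#' single best-scoring envelope with `E <= eThreshold`.  Because scoring
#' is glocal, partial ACDs never qualify.  With `flagMultiAcd = TRUE`,
#' each hit's envelope is masked to `X` and the sequence rescanned; a
#' second non-overlapping qualifying envelope sets `multiAcd` (such
#' proteins are excluded by [curateHits()]).
#'
#' @param p A calibrated [ProfileHMM-class] (see [calibrateProfile()]).
#' @param bank A [SequenceBank-class].
#' @param eThreshold E-value acceptance threshold.
#' @param flagMultiAcd Rescan hits for additional envelopes (default
#'   `FALSE`; enabled by the final curation pass of [iterateProfile()]).
#' @return A [S4Vectors::DataFrame] with columns `accession`, `acdStart`,
#'   `acdEnd` (1-based inclusive envelope), `bitScore`, `eValue`,
#'   `multiAcd`, and list columns `columnMap` (target position per profile
#'   column, `NA` = deletion) and `insertCounts` (inserted residues after
#'   each of positions 0..M).
#' @export
scanBank <- function(p, bank, eThreshold, flagMultiAcd = FALSE) {
    stopifnot(is(p, "ProfileHMM"), is(bank, "SequenceBank"))
    if (is.null(p@calibration))
        stop("profile is not calibrated; run calibrateProfile() first")
    n <- length(bank)
    if (n == 0 || eThreshold <= 0) return(.emptyHits())
    seqs <- as.character(bank@seqs)
    acc <- names(bank@seqs)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        v <- viterbiScore(p, seqs[i])
        if (!is.finite(v$score)) next
        e <- eValue(v$score, p@calibration, n)
        if (e > eThreshold) next
        multi <- FALSE
        if (flagMultiAcd) {
            masked <- seqs[i]
            substr(masked, v$envStart, v$envEnd) <-
                strrep("X", v$envEnd - v$envStart + 1)
            v2 <- viterbiScore(p, masked)
            if (is.finite(v2$score) &&
                eValue(v2$score, p@calibration, n) <= eThreshold &&
                (v2$envEnd < v$envStart || v2$envStart > v$envEnd))
                multi <- TRUE
        }
        rows[[i]] <- list(acc = acc[i], s = v$envStart, e = v$envEnd,
                          b = v$score, ev = e, multi = multi,
                          map = v$map, ins = v$inserts)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(.emptyHits())
    DataFrame(accession = vapply(rows, `[[`, character(1), "acc"),
              acdStart = vapply(rows, `[[`, integer(1), "s"),
              acdEnd = vapply(rows, `[[`, integer(1), "e"),
              bitScore = vapply(rows, `[[`, numeric(1), "b"),
              eValue = vapply(rows, `[[`, numeric(1), "ev"),
              multiAcd = vapply(rows, `[[`, logical(1), "multi"),
              columnMap = IRanges::IntegerList(lapply(rows, `[[`, "map")),
              insertCounts = IRanges::IntegerList(lapply(rows, `[[`,
                                                         "ins")))
}
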