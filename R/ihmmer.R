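# The iterative enrichment loop: build -> scan -> filter -> realign ->
# rebuild -> recalibrate, relaxing the E-value threshold one order of
# magnitude per iteration, then a final curation pass.

#' Iteration configuration
#'
#' Thresholds run from `10^startExponent` up to `10^endExponent`, one
#' order of magnitude per iteration; a final pass keeps envelopes with
#' `E <= 10^finalExponent`.  The exponent defaults are configuration (the
#' conventional, documented choices of this package), while the 10
#' iteration cap and the 100-residue ACD filter are fixed by the method.
#'
#' @param startExponent First threshold exponent (default -10).
#' @param endExponent Last iteration exponent (default -5).
#' @param finalExponent Final selection exponent (default -5).
#' @param maxAcdLength Maximum accepted ACD envelope length in residues
#'   (default 100).
#' @param maxIterations Cap on enrichment iterations (default 10).
#' @return A validated list of class `IterationConfig`.
#' @export
iterationConfig <- function(startExponent = -10L, endExponent = -5L,
                            finalExponent = -5L, maxAcdLength = 100L,
                            maxIterations = 10L) {
    if (startExponent > endExponent)
        stop("startExponent must be <= endExponent")
    if (maxAcdLength <= 0) stop("maxAcdLength must be positive")
    if (maxIterations < 1) stop("maxIterations must be >= 1")
    structure(list(startExponent = as.integer(startExponent),
                   endExponent = as.integer(endExponent),
                   finalExponent = as.integer(finalExponent),
                   maxAcdLength = as.integer(maxAcdLength),
                   maxIterations = as.integer(maxIterations)),
              class = "IterationConfig")
}

#' Filter hits by ACD envelope length
#'
#' Keeps hits whose envelope spans at most `maxLen` residues (the method
#' rejects ACDs longer than 100 residues by default).
#'
#' @param hits Hit table from [scanBank()].
#' @param maxLen Maximum `acdEnd - acdStart + 1`.
#' @return The filtered hit table; warns if every hit is dropped.
#' @export
filterHits <- function(hits, maxLen = 100L) {
    stopifnot(maxLen > 0)
    if (!nrow(hits)) return(hits)
    keep <- (hits$acdEnd - hits$acdStart + 1) <= maxLen
    if (!any(keep) && nrow(hits))
        warning("all ", nrow(hits), " hits exceed the ACD length cap (",
                maxLen, " residues)")
    hits[keep, , drop = FALSE]
}

#' Re-express hit envelopes as an alignment on profile columns
#'
#' Each hit becomes one row over the profile's match columns: the matched
#' residue per column, `-` for a deleted column.  Inserted residues are
#' placed in dedicated insert columns between match columns (lowercase,
#' padded with `.`); the widest insert across rows sets the insert-column
#' count at each position.  The result feeds [buildProfile()] for the next
#' iteration; the returned annotation labels insert columns with the
#' preceding match column's element so zone landmarks propagate.
#'
#' @param p The [ProfileHMM-class] the hits were found with.
#' @param hits Hit table from [scanBank()] (at least one row).
#' @param bank The scanned [SequenceBank-class].
#' @param keepInserts Keep insert-state residues as insert columns
#'   (default `TRUE`); `FALSE` discards them.
#' @return list(alignment = [AcdAlignment-class],
#'   annotation = [SeedAnnotation-class]).
#' @export
hitsToAlignment <- function(p, hits, bank, keepInserts = TRUE) {
    stopifnot(is(p, "ProfileHMM"), is(bank, "SequenceBank"))
    if (!nrow(hits)) stop("no hits to align")
    M <- profileLength(p)
    unknown <- setdiff(hits$accession, accessions(bank))
    if (length(unknown))
        stop("hit references unknown accession(s): ",
             paste(unknown, collapse = ", "))
    seqs <- bankResidues(bank, hits$accession)
    maps <- as.list(hits$columnMap)
    insL <- as.list(hits$insertCounts)
    width <- if (keepInserts)
        apply(do.call(rbind, insL), 2, max) else integer(M + 1)

    rows <- character(nrow(hits))
    for (r in seq_len(nrow(hits))) {
        ch <- strsplit(seqs[r], "")[[1]]
        map <- maps[[r]]
        ins <- insL[[r]]
        pieces <- character(0)
        cursor <- hits$acdStart[r]
        for (j in 0:M) {
            if (j > 0) {
                if (is.na(map[j])) {
                    pieces <- c(pieces, "-")
                } else {
                    pieces <- c(pieces, ch[map[j]])
                    cursor <- map[j] + 1L
                }
            }
            if (width[j + 1] > 0) {
                k <- ins[j + 1]
                insRes <- if (k > 0)
                    tolower(paste(ch[cursor:(cursor + k - 1)],
                                  collapse = "")) else ""
                cursor <- cursor + k
                pieces <- c(pieces,
                            paste0(insRes,
                                   strrep(".", width[j + 1] - k)))
            } else {
                cursor <- cursor + ins[j + 1]
            }
        }
        rows[r] <- paste(pieces, collapse = "")
    }
    names(rows) <- make.unique(hits$accession)
    aln <- AcdAlignment(rows)
    elems <- character(0)
    for (j in 0:M) {
        if (j > 0) elems <- c(elems, p@landmarks[j])
        lab <- p@landmarks[max(j, 1)]
        if (width[j + 1] > 0)
            elems <- c(elems, rep(lab, width[j + 1]))
    }
    list(alignment = aln, annotation = SeedAnnotation(elems))
}

#' Run the iterative profile enrichment
#'
#' Builds the initial profile from the structure-annotated seed alignment,
#' calibrates it, then alternates scanning, length filtering, profile-
#' column realignment, rebuilding and recalibration while the E-value
#' threshold relaxes one order of magnitude per iteration.  Sequences
#' accepted earlier are re-evaluated against each new profile (no
#' grandfathering).  A final pass at the configured final threshold flags
#' multi-ACD sequences for curation.  Fully deterministic given `seed`:
#' each calibration uses a sub-seed derived from (seed, iteration).
#'
#' @param seedAln Seed [AcdAlignment-class].
#' @param annotation Its [SeedAnnotation-class].
#' @param bank Target [SequenceBank-class].
#' @param config An [iterationConfig()].
#' @param seed Master integer seed.
#' @param pseudocountWeight,transitionPseudocount,gapThreshold,background
#'   Passed to [buildProfile()].
#' @param calibrationN,calibrationLength Passed to [calibrateProfile()].
#' @return list(profile, hits, trace, finalPass): `trace` is a data.frame
#'   with one row per enrichment iteration (threshold, hit counts, profile
#'   checksum); `hits` come from the final selection pass, whose threshold
#'   and hit count are in `finalPass`.
#' @export
iterateProfile <- function(seedAln, annotation, bank,
                           config = iterationConfig(), seed = 42L,
                           pseudocountWeight = 20,
                           transitionPseudocount = 1,
                           gapThreshold = 0.5,
                           background = backgroundFrequencies(),
                           calibrationN = 200L, calibrationLength = 150L) {
    stopifnot(inherits(config, "IterationConfig"))
    p <- buildProfile(seedAln, annotation,
                      pseudocountWeight = pseudocountWeight,
                      transitionPseudocount = transitionPseudocount,
                      gapThreshold = gapThreshold, background = background)
    p <- calibrateProfile(p, n = calibrationN, length = calibrationLength,
                          seed = deriveSeed(seed, 0L))
    exponents <- seq(config$startExponent, config$endExponent)
    if (length(exponents) > config$maxIterations)
        exponents <- exponents[seq_len(config$maxIterations)]
    trace <- data.frame(iteration = integer(0), exponent = integer(0),
                        threshold = numeric(0), nHits = integer(0),
                        nNew = integer(0), checksum = character(0),
                        stringsAsFactors = FALSE)
    seen <- character(0)
    for (it in seq_along(exponents)) {
        thr <- 10^exponents[it]
        hits <- scanBank(p, bank, thr)
        if (it == 1 && !nrow(hits))
            stop("no hits at the first iteration (threshold 1e",
                 exponents[1], "): seed profile and databank are ",
                 "incompatible or the threshold is too strict")
        hits <- filterHits(hits, config$maxAcdLength)
        nNew <- length(setdiff(hits$accession, seen))
        if (nrow(hits) >= 2) {
            realn <- hitsToAlignment(p, hits, bank)
            p <- buildProfile(realn$alignment, realn$annotation,
                              pseudocountWeight = pseudocountWeight,
                              transitionPseudocount = transitionPseudocount,
                              gapThreshold = gapThreshold,
                              background = background)
        } else {
            warning("iteration ", it, ": fewer than 2 hits; ",
                    "profile kept unchanged")
        }
        p <- calibrateProfile(p, n = calibrationN,
                              length = calibrationLength,
                              seed = deriveSeed(seed, it))
        if (nrow(hits) < length(seen))
            warning("iteration ", it, ": hit set shrank from ",
                    length(seen), " to ", nrow(hits),
                    " despite a relaxed threshold (profile drift)")
        seen <- hits$accession
        trace <- rbind(trace, data.frame(
            iteration = it, exponent = exponents[it], threshold = thr,
            nHits = nrow(hits), nNew = nNew,
            checksum = numericChecksum(p@matchEmit),
            stringsAsFactors = FALSE))
    }
    finalThr <- 10^config$finalExponent
    hits <- scanBank(p, bank, finalThr, flagMultiAcd = TRUE)
    hits <- filterHits(hits, config$maxAcdLength)
    list(profile = p, hits = hits, trace = trace,
         finalPass = list(threshold = finalThr, nHits = nrow(hits)))
}

#' Curate the final hit set
#'
#' Applies the annotation-based selection: keeps records that are not
#' fragments, have protein-existence level at most 3, and carry exactly
#' one qualifying ACD envelope (hits flagged `multiAcd` are excluded).
#'
#' @param hits Final hit table (from the curation pass of
#'   [iterateProfile()] or [scanBank()] with `flagMultiAcd = TRUE`).
#' @param bank The [SequenceBank-class] with metadata loaded.
#' @return The curated subset of `hits`.
#' @export
curateHits <- function(hits, bank) {
    stopifnot(is(bank, "SequenceBank"))
    if (!nrow(hits)) return(hits)
    i <- match(hits$accession, accessions(bank))
    if (anyNA(i))
        stop("hit references unknown accession(s): ",
             paste(hits$accession[is.na(i)], collapse = ", "))
    keep <- !isFragment(bank)[i] & existenceLevel(bank)[i] <= 3L &
        !hits$multiAcd
    hits[keep, , drop = FALSE]
}
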