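# Profile construction from a (seed or re-aligned) multiple alignment.

.isGapChar <- function(ch) ch == "-" | ch == "."

.alnMatrix <- function(aln) {
    do.call(rbind, strsplit(toupper(aln@sequences), ""))
}

#' Decide which alignment columns become match states
#'
#' A column is promoted to a match state when its gap fraction is strictly
#' below `gapThreshold`; the remaining columns are treated as insert
#' columns.
#'
#' @param aln An [AcdAlignment-class].
#' @param gapThreshold Fraction in (0, 1]; default 0.5.
#' @return Logical mask over columns (`TRUE` = match).
#' @examples
#' aln <- AcdAlignment(c(a = "AC-", b = "A-G", c = "ACG"))
#' determineMatchColumns(aln)
#' @export
determineMatchColumns <- function(aln, gapThreshold = 0.5) {
    stopifnot(is(aln, "AcdAlignment"),
              gapThreshold > 0, gapThreshold <= 1)
    m <- .alnMatrix(aln)
    gapFrac <- colMeans(.isGapChar(m))
    mask <- gapFrac < gapThreshold
    if (!any(mask))
        stop("no column has gap fraction below the threshold (",
             gapThreshold, "); cannot build a profile")
    mask
}

# Henikoff & Henikoff position-based sequence weights (optional).
.henikoffWeights <- function(m) {
    n <- nrow(m)
    w <- numeric(n)
    for (c in seq_len(ncol(m))) {
        col <- m[, c]
        res <- !.isGapChar(col)
        if (!any(res)) next
        tab <- table(col[res])
        r <- length(tab)
        w[res] <- w[res] + 1 / (r * as.numeric(tab[col[res]]))
    }
    if (all(w == 0)) w <- rep(1, n)
    w * n / sum(w)
}

#' Build a glocal profile HMM from an annotated alignment
#'
#' Compiles an alignment into a [ProfileHMM-class].  Match columns are
#' chosen by [determineMatchColumns()]; match emissions are observed
#' residue counts plus background-proportional pseudocounts of total
#' weight `pseudocountWeight`, insert emissions are the background;
#' transitions are counted from each row's match/insert/delete path and
#' smoothed by adding `transitionPseudocount` to every structurally
#' allowed transition.  Structural landmarks of the annotation are
#' propagated through the match-column mask; insert columns that the mask
#' promotes to match states inherit the label of the nearest preceding
#' labelled column.
#'
#' @param aln An [AcdAlignment-class].
#' @param annotation A [SeedAnnotation-class] whose labels cover the match
#'   columns (per column of `aln`).
#' @param pseudocountWeight Total emission pseudocount mass per column
#'   (> 0); default 20.
#' @param transitionPseudocount Added to each allowed transition count;
#'   default 1 (Laplace).  May be 0 for a pure maximum-likelihood profile.
#' @param gapThreshold Match-column rule, see [determineMatchColumns()].
#' @param background Null-model frequencies ([backgroundFrequencies()]).
#' @param weighting `"none"` (default) or `"henikoff"` position-based
#'   sequence weighting.
#' @return An uncalibrated [ProfileHMM-class].
#' @examples
#' aln <- AcdAlignment(c(a = "AA", b = "AA"))
#' ann <- SeedAnnotation(c("b2", "b2"))
#' p <- buildProfile(aln, ann, pseudocountWeight = 20,
#'                   background = backgroundFrequencies("uniform"))
#' matchEmissions(p)[1, "A"]  # (2 + 20 * 0.05) / (2 + 20) = 3/22
#' @export
buildProfile <- function(aln, annotation,
                         pseudocountWeight = 20,
                         transitionPseudocount = 1,
                         gapThreshold = 0.5,
                         background = backgroundFrequencies(),
                         weighting = c("none", "henikoff")) {
    stopifnot(is(aln, "AcdAlignment"), is(annotation, "SeedAnnotation"),
              pseudocountWeight > 0, transitionPseudocount >= 0)
    weighting <- match.arg(weighting)
    if (length(annotation@elements) != nColumns(aln))
        stop("annotation covers ", length(annotation@elements),
             " columns but the alignment has ", nColumns(aln))
    m <- .alnMatrix(aln)
    mask <- determineMatchColumns(aln, gapThreshold)
    M <- sum(mask)
    bg <- background / sum(background)

    # landmarks: match columns inherit their own label, or the nearest
    # preceding labelled column's (promoted insert columns)
    filled <- annotation@elements
    for (k in seq_along(filled))
        if (is.na(filled[k]) && k > 1) filled[k] <- filled[k - 1]
    # leading unlabelled columns inherit the first label
    if (anyNA(filled)) {
        firstLab <- filled[!is.na(filled)][1]
        filled[is.na(filled)] <- firstLab
    }
    lm <- filled[mask]

    w <- if (weighting == "henikoff") .henikoffWeights(m)
         else rep(1, nrow(m))

    # --- emissions -------------------------------------------------------
    counts <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, .AA20))
    mcols <- which(mask)
    for (r in seq_len(nrow(m))) {
        res <- m[r, mcols]
        keep <- res %in% .AA20
        if (any(keep)) {
            idx <- cbind(which(keep), match(res[keep], .AA20))
            counts[idx] <- counts[idx] + w[r]
        }
    }
    matchEmit <- counts + pseudocountWeight * matrix(bg, M, 20, byrow = TRUE)
    matchEmit <- matchEmit / rowSums(matchEmit)
    insertEmit <- matrix(bg, M + 1, 20, byrow = TRUE,
                         dimnames = list(NULL, .AA20))

    # --- transitions -----------------------------------------------------
    # per-row state path over positions 0..M; count transitions
    cMM <- cMI <- cMD <- cIM <- cII <- cDM <- cDD <- numeric(M + 1)
    colPos <- cumsum(mask)          # profile position after each column
    for (r in seq_len(nrow(m))) {
        row <- m[r, ]
        states <- character(0)      # sequence of visited states
        pos <- integer(0)
        for (k in seq_len(ncol(m))) {
            if (mask[k]) {
                states <- c(states, if (.isGapChar(row[k])) "D" else "M")
                pos <- c(pos, colPos[k])
            } else if (!.isGapChar(row[k])) {
                states <- c(states, "I")
                pos <- c(pos, colPos[k])
            }
        }
        prevS <- "M"; prevP <- 0L   # B behaves as M_0
        for (t in seq_along(states)) {
            s <- states[t]; p <- pos[t]
            key <- paste0(prevS, s)
            inc <- w[r]
            switch(key,
                   MM = cMM[prevP + 1] <- cMM[prevP + 1] + inc,
                   MI = cMI[prevP + 1] <- cMI[prevP + 1] + inc,
                   MD = cMD[prevP + 1] <- cMD[prevP + 1] + inc,
                   IM = cIM[prevP + 1] <- cIM[prevP + 1] + inc,
                   II = cII[prevP + 1] <- cII[prevP + 1] + inc,
                   DM = cDM[prevP + 1] <- cDM[prevP + 1] + inc,
                   DD = cDD[prevP + 1] <- cDD[prevP + 1] + inc)
            prevS <- s; prevP <- p
        }
        # exit to E counts as a ...->M transition from position M
        switch(prevS,
               M = cMM[prevP + 1] <- cMM[prevP + 1] + w[r],
               I = cIM[prevP + 1] <- cIM[prevP + 1] + w[r],
               D = cDM[prevP + 1] <- cDM[prevP + 1] + w[r])
    }
    a <- transitionPseudocount
    # structurally allowed transitions get the pseudocount; M_M -> D and
    # D_M -> D do not exist, D_0 does not exist
    tMM <- cMM + a; tMI <- cMI + a; tMD <- cMD + a
    tMD[M + 1] <- 0
    sM <- tMM + tMI + tMD
    degenerate <- sM == 0
    tMM[degenerate] <- 1; sM[degenerate] <- 1
    tMM <- tMM / sM; tMI <- tMI / sM; tMD <- tMD / sM

    tIM <- cIM + a; tII <- cII + a
    sI <- tIM + tII
    degenerate <- sI == 0
    tIM[degenerate] <- 1; sI[degenerate] <- 1
    tIM <- tIM / sI; tII <- tII / sI

    tDM <- cDM + a; tDD <- cDD + a
    tDD[M + 1] <- 0
    tDM[1] <- 1; tDD[1] <- 0     # D_0 placeholder
    sD <- tDM + tDD
    degenerate <- sD == 0
    tDM[degenerate] <- 1; sD[degenerate] <- 1
    tDM <- tDM / sD; tDD <- tDD / sD
    if (M >= 1) { tDM[M + 1] <- 1; tDD[M + 1] <- 0 }

    new("ProfileHMM", matchEmit = matchEmit, insertEmit = insertEmit,
        tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
        tDM = tDM, tDD = tDD,
        background = stats::setNames(bg, .AA20), landmarks = lm,
        calibration = NULL)
}
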