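# Independent oracles used across the suite.  These deliberately avoid the
# package's dynamic-programming code paths: the HMM oracle enumerates every
# glocal path recursively, the alignment oracle enumerates every global
# alignment.

AA20 <- aminoAcids()

# ---- brute-force glocal path enumeration --------------------------------
# Returns all complete-path log2 scores (and the best path's column map)
# for a profile and a sequence: every start offset, every state path
# through M/I/D that visits all columns, at least one emission.
enumerateGlocal <- function(p, residues) {
    s <- match(strsplit(residues, "")[[1]], AA20)   # NA encodes X
    L <- length(s)
    M <- nrow(p@matchEmit)
    bg <- p@background
    lem <- function(j, si) if (is.na(si)) 0 else
        log2(p@matchEmit[j, si] / bg[si])
    lins <- function(j, si) if (is.na(si)) 0 else
        log2(p@insertEmit[j + 1, si] / bg[si])
    lt <- function(x) if (x > 0) log2(x) else -Inf
    scores <- numeric(0)
    bestScore <- -Inf
    bestMap <- NULL
    # path bookkeeping: map of matched positions (0 = deletion)
    rec <- function(type, j, i, acc, emitted, map) {
        if (!is.finite(acc)) return()
        # options from current state
        if (type == "M") {          # j in 0..M (j = 0 is B)
            if (j == M) {
                if (emitted > 0) record(acc + lt(p@tMM[M + 1]), map)
            } else if (p@tMM[j + 1] > 0 && i < L) {
                rec("M", j + 1, i + 1,
                    acc + lt(p@tMM[j + 1]) + lem(j + 1, s[i + 1]),
                    emitted + 1, `[<-`(map, j + 1, i + 1))
            }
            if (p@tMI[j + 1] > 0 && i < L)
                rec("I", j, i + 1,
                    acc + lt(p@tMI[j + 1]) + lins(j, s[i + 1]),
                    emitted + 1, map)
            if (j < M && p@tMD[j + 1] > 0)
                rec("D", j + 1, i, acc + lt(p@tMD[j + 1]), emitted, map)
        } else if (type == "I") {
            if (j == M) {
                if (emitted > 0) record(acc + lt(p@tIM[M + 1]), map)
            } else if (p@tIM[j + 1] > 0 && i < L) {
                rec("M", j + 1, i + 1,
                    acc + lt(p@tIM[j + 1]) + lem(j + 1, s[i + 1]),
                    emitted + 1, `[<-`(map, j + 1, i + 1))
            }
            if (p@tII[j + 1] > 0 && i < L)
                rec("I", j, i + 1,
                    acc + lt(p@tII[j + 1]) + lins(j, s[i + 1]),
                    emitted + 1, map)
        } else {                    # D, j in 1..M
            if (j == M) {
                if (emitted > 0) record(acc + lt(p@tDM[M + 1]), map)
            } else if (p@tDM[j + 1] > 0 && i < L) {
                rec("M", j + 1, i + 1,
                    acc + lt(p@tDM[j + 1]) + lem(j + 1, s[i + 1]),
                    emitted + 1, `[<-`(map, j + 1, i + 1))
            }
            if (j < M && p@tDD[j + 1] > 0)
                rec("D", j + 1, i, acc + lt(p@tDD[j + 1]), emitted, map)
        }
    }
    record <- function(sc, map) {
        scores[length(scores) + 1L] <<- sc
        if (sc > bestScore) { bestScore <<- sc; bestMap <<- map }
    }
    for (o in 0:(L - 1))
        rec("M", 0, o, 0, 0, integer(M))
    list(scores = scores,
         viterbi = if (length(scores)) max(scores) else -Inf,
         forward = if (length(scores))
             max(scores) + log2(sum(2^(scores - max(scores)))) else -Inf,
         bestMap = bestMap)
}

# Random tiny profile for oracle comparisons (possibly including zero-mass
# transitions at the structural boundaries).
randomTinyProfile <- function(M, alphaEmit = 0.5) {
    rdir <- function(n) { x <- rgamma(n, alphaEmit) + 1e-6; x / sum(x) }
    me <- t(vapply(seq_len(M), function(j) rdir(20), numeric(20)))
    ie <- t(vapply(seq_len(M + 1), function(j) rdir(20), numeric(20)))
    r3 <- function() { x <- rgamma(3, 1) + 0.05; x / sum(x) }
    r2 <- function() { x <- rgamma(2, 1) + 0.05; x / sum(x) }
    tMM <- tMI <- tMD <- tIM <- tII <- tDM <- tDD <- numeric(M + 1)
    for (k in seq_len(M + 1)) {
        if (k < M + 1) { v <- r3(); tMM[k] <- v[1]; tMI[k] <- v[2]
                         tMD[k] <- v[3] }
        else { v <- r2(); tMM[k] <- v[1]; tMI[k] <- v[2]; tMD[k] <- 0 }
        v <- r2(); tIM[k] <- v[1]; tII[k] <- v[2]
        v <- r2(); tDM[k] <- v[1]; tDD[k] <- v[2]
    }
    tDM[1] <- 1; tDD[1] <- 0
    tDM[M + 1] <- 1; tDD[M + 1] <- 0
    toyProfile(me, tMM, tMI, tMD, tIM, tII, tDM, tDD,
               background = backgroundFrequencies("uniform"),
               insertEmit = ie)
}

randomResidues <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# ---- brute-force global affine alignment --------------------------------
# All monotone alignment paths for sequence lengths (la, lb), as op strings
# over M (aligned pair), A (gap in b), B (gap in a).
nwPaths <- local({
    cache <- list()
    function(la, lb) {
        key <- paste(la, lb)
        if (!is.null(cache[[key]])) return(cache[[key]])
        rec <- function(i, j) {
            if (i == la && j == lb) return(list(character(0)))
            out <- list()
            if (i < la && j < lb)
                out <- c(out, lapply(rec(i + 1, j + 1),
                                     function(x) c("M", x)))
            if (i < la)
                out <- c(out, lapply(rec(i + 1, j),
                                     function(x) c("A", x)))
            if (j < lb)
                out <- c(out, lapply(rec(i, j + 1),
                                     function(x) c("B", x)))
            out
        }
        res <- rec(0, 0)
        cache[[key]] <<- res
        res
    }
})

# Affine gap cost of one op path: gapOpen per maximal gap run plus
# gapExtend per gapped position.
nwPathGapCost <- function(ops, gapOpen, gapExtend) {
    isGap <- ops != "M"
    runs <- rle(ops)
    nRuns <- sum(runs$values != "M")
    gapOpen * nRuns + gapExtend * sum(isGap)
}

# Optimal global score of a single pair by exhaustive path enumeration.
nwBruteForce <- function(a, b, S, gapOpen, gapExtend) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    best <- -Inf
    for (ops in nwPaths(length(ca), length(cb))) {
        i <- 0; j <- 0; sc <- 0
        for (op in ops) {
            if (op == "M") { i <- i + 1; j <- j + 1
                             sc <- sc + S[ca[i], cb[j]] }
            else if (op == "A") i <- i + 1
            else j <- j + 1
        }
        sc <- sc - nwPathGapCost(ops, gapOpen, gapExtend)
        if (sc > best) best <- sc
    }
    best
}

# Vectorised oracle: optimal scores for every pair (rows of Am x rows of
# Bm, letter matrices), same cost model.
nwBruteForceAll <- function(Am, Bm, S, gapOpen, gapExtend) {
    la <- ncol(Am); lb <- ncol(Bm)
    nA <- nrow(Am); nB <- nrow(Bm)
    ia <- rep(seq_len(nA), times = nB)
    ib <- rep(seq_len(nB), each = nA)
    best <- rep(-Inf, nA * nB)
    for (ops in nwPaths(la, lb)) {
        sc <- rep(-nwPathGapCost(ops, gapOpen, gapExtend), nA * nB)
        i <- 0; j <- 0
        for (op in ops) {
            if (op == "M") {
                i <- i + 1; j <- j + 1
                sc <- sc + S[cbind(Am[ia, i], Bm[ib, j])]
            } else if (op == "A") i <- i + 1
            else j <- j + 1
        }
        best <- pmax(best, sc)
    }
    matrix(best, nrow = nA, ncol = nB)
}

blosum62 <- local({
    S <- NULL
    function() {
        if (is.null(S)) {
            e <- new.env()
            data(list = "BLOSUM62", package = "Biostrings", envir = e)
            S <<- get("BLOSUM62", envir = e)
        }
        S
    }
})

# ---- misc helpers -------------------------------------------------------

# Manufacture a hit table row-by-row (accession + column map [+ inserts]).
makeHits <- function(accession, maps, starts = NULL, ends = NULL,
                     inserts = NULL, multi = FALSE) {
    n <- length(accession)
    M <- length(maps[[1]])
    if (is.null(inserts))
        inserts <- replicate(n, integer(M + 1), simplify = FALSE)
    if (is.null(starts))
        starts <- vapply(maps, function(m) min(m[!is.na(m)]), numeric(1))
    if (is.null(ends))
        ends <- vapply(maps, function(m) max(m[!is.na(m)]), numeric(1))
    S4Vectors::DataFrame(
        accession = accession,
        acdStart = as.integer(starts), acdEnd = as.integer(ends),
        bitScore = rep(0, n), eValue = rep(0, n),
        multiAcd = rep(multi, length.out = n),
        columnMap = IRanges::IntegerList(maps),
        insertCounts = IRanges::IntegerList(inserts))
}

bankFromStrings <- function(res, lineage = NULL, fragment = NULL,
                            existence = NULL) {
    seqs <- Biostrings::AAStringSet(res)
    n <- length(seqs)
    meta <- S4Vectors::DataFrame(
        description = character(n),
        lineage = I(if (is.null(lineage))
            replicate(n, character(0), simplify = FALSE) else lineage),
        isFragment = if (is.null(fragment)) logical(n) else fragment,
        existenceLevel = if (is.null(existence)) rep(5L, n)
                         else as.integer(existence))
    new("SequenceBank", seqs = seqs, meta = meta)
}
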