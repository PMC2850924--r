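# Download-free synthetic databanks with planted ACDs, anchoring motifs
# and metadata, plus ground truth, so every pipeline stage is testable.

.LINEAGES <- list(
    animals = c("Eukaryota", "Metazoa"),
    plants = c("Eukaryota", "Viridiplantae"),
    fungi = c("Eukaryota", "Fungi"),
    archaea = c("Archaea"),
    bacteria = c("Bacteria", "Proteobacteria"),
    other = c("Eukaryota", "Alveolata"))

#' Synthesis parameters
#'
#' Study conditions of the synthetic benchmark.  Defaults emulate the
#' reported sHSP statistics: N-terminal length 53 +/- 35 residues, CAM
#' length 14 +/- 3 (minimum 3), short C-terminal tails (5 +/- 4, floor 0),
#' motif flanks dominated by isoleucine, and a group mix matching the
#' curated dataset's taxonomic proportions.  Fragments and low-evidence
#' records are absent by default (the generator emulates the curated set);
#' raise `fragmentFraction` / change `existenceProbs` to exercise
#' curation.
#'
#' @param nPositives,nDecoys Record counts (>= 0, not both 0 at
#'   generation time).
#' @param ntermMean,ntermSd N-terminal length distribution (truncated
#'   normal, floor 0).
#' @param camMean,camSd,camMin CAM length distribution (floor `camMin`).
#' @param tailMean,tailSd C-terminal tail length distribution (floor 0).
#' @param mutationRate Per-site substitution probability applied to
#'   sampled ACDs.
#' @param motifCentral Length-20 probability vector for the motif's
#'   central X (default: background frequencies).
#' @param motifFlank Probabilities of I/V/L at the motif flanks.
#' @param fragmentFraction Fraction of records flagged as fragments.
#' @param existenceProbs Probabilities of existence levels 1..5.
#' @param groupMix Named probabilities over
#'   animals/plants/fungi/archaea/bacteria/other.
#' @param seed Master seed.
#' @return A validated list of class `SynthesisParams`.
#' @export
synthesisParams <- function(nPositives = 50L, nDecoys = 50L,
                            ntermMean = 53, ntermSd = 35,
                            camMean = 14, camSd = 3, camMin = 3L,
                            tailMean = 5, tailSd = 4,
                            mutationRate = 0.2,
                            motifCentral = backgroundFrequencies(),
                            motifFlank = c(I = 0.55, V = 0.30, L = 0.15),
                            fragmentFraction = 0,
                            existenceProbs = c(0.2, 0.3, 0.5, 0, 0),
                            groupMix = c(animals = 0.15, plants = 0.18,
                                         fungi = 0.03, archaea = 0.04,
                                         bacteria = 0.58, other = 0.02),
                            seed = 42L) {
    stopifnot(nPositives >= 0, nDecoys >= 0,
              mutationRate >= 0, mutationRate <= 1,
              fragmentFraction >= 0, fragmentFraction <= 1,
              camMin > 0, length(existenceProbs) == 5,
              all(names(groupMix) %in% names(.LINEAGES)))
    structure(list(nPositives = as.integer(nPositives),
                   nDecoys = as.integer(nDecoys),
                   ntermMean = ntermMean, ntermSd = ntermSd,
                   camMean = camMean, camSd = camSd,
                   camMin = as.integer(camMin),
                   tailMean = tailMean, tailSd = tailSd,
                   mutationRate = mutationRate,
                   motifCentral = motifCentral / sum(motifCentral),
                   motifFlank = motifFlank / sum(motifFlank),
                   fragmentFraction = fragmentFraction,
                   existenceProbs = existenceProbs / sum(existenceProbs),
                   groupMix = groupMix / sum(groupMix),
                   seed = as.integer(seed)),
              class = "SynthesisParams")
}

.rtruncLen <- function(n, mean, sd, min) {
    pmax(round(stats::rnorm(n, mean, sd)), min)
}

#' Sample an ACD from a profile
#'
#' Draws a stochastic path through the profile's match/insert/delete
#' states, emitting residues from the corresponding emission
#' distributions, and returns the emitted domain together with the true
#' per-zone lengths implied by the path (insertions are assigned to the
#' zone of the preceding column).  Flanking insert states `I_0` / `I_M`
#' are suppressed by default so the emitted domain starts and ends on
#' profile columns.
#'
#' @param p A [ProfileHMM-class].
#' @param seed Optional seed (if `NULL`, uses the current RNG state).
#' @param suppressFlankInserts Disallow `I_0` / `I_M` (default `TRUE`).
#' @return list(residues, zoneLengths (b2b5/L57/b7b9), length).
#' @export
sampleAcd <- function(p, seed = NULL, suppressFlankInserts = TRUE) {
    stopifnot(is(p, "ProfileHMM"))
    withSeed(seed, {
        M <- profileLength(p)
        zones <- zoneOfElement(p@landmarks)
        res <- character(0)
        zcount <- c(b2b5 = 0L, L57 = 0L, b7b9 = 0L)
        emitMatch <- function(j) sample(.AA20, 1, prob = p@matchEmit[j, ])
        emitIns <- function(j) sample(.AA20, 1, prob = p@insertEmit[j + 1, ])
        j <- 0L; state <- "M"
        repeat {
            if (state == "M") {
                pr <- c(M = p@tMM[j + 1], I = p@tMI[j + 1],
                        D = p@tMD[j + 1])
                if (suppressFlankInserts && (j == 0L || j == M))
                    pr["I"] <- 0
                nxt <- sample(names(pr), 1, prob = pr)
            } else if (state == "I") {
                nxt <- sample(c("M", "I"), 1,
                              prob = c(p@tIM[j + 1], p@tII[j + 1]))
            } else {
                nxt <- sample(c("M", "D"), 1,
                              prob = c(p@tDM[j + 1], p@tDD[j + 1]))
            }
            if (nxt == "I") {
                res <- c(res, emitIns(j))
                zcount[zones[max(j, 1L)]] <-
                    zcount[zones[max(j, 1L)]] + 1L
                state <- "I"
            } else {
                if (j == M) break   # M or D from position M exits
                j <- j + 1L
                if (nxt == "M") {
                    res <- c(res, emitMatch(j))
                    zcount[zones[j]] <- zcount[zones[j]] + 1L
                }
                state <- nxt
            }
        }
        list(residues = paste(res, collapse = ""),
             zoneLengths = zcount, length = length(res))
    })
}

.sampleBg <- function(n, bg) {
    if (n <= 0) return("")
    paste(sample(.AA20, n, replace = TRUE, prob = bg), collapse = "")
}

.mutate <- function(residues, rate) {
    if (rate <= 0 || !nzchar(residues)) return(residues)
    ch <- strsplit(residues, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(.AA20, ch[i]), 1)
    paste(ch, collapse = "")
}

# CAM segment of length camLen: interior drawn from background excluding
# I/V/L (no earlier motif match can arise), final three residues realise
# the I/V/L-X-I/V/L motif, so the true CAM length is exact by construction.
.makeCam <- function(camLen, params, bg) {
    noAli <- bg[setdiff(.AA20, c("I", "V", "L"))]
    interior <- if (camLen > 3)
        paste(sample(names(noAli), camLen - 3, replace = TRUE,
                     prob = noAli), collapse = "") else ""
    flank1 <- sample(names(params$motifFlank), 1, prob = params$motifFlank)
    x <- sample(.AA20, 1, prob = params$motifCentral)
    flank2 <- sample(names(params$motifFlank), 1, prob = params$motifFlank)
    paste0(interior, flank1, x, flank2)
}

.drawMeta <- function(params) {
    grp <- sample(names(params$groupMix), 1, prob = params$groupMix)
    list(lineage = .LINEAGES[[grp]], group = grp,
         isFragment = stats::runif(1) < params$fragmentFraction,
         existenceLevel = sample(1:5, 1, prob = params$existenceProbs))
}

#' Generate one synthetic positive record
#'
#' Concatenates a random-background N-terminal region, a mutated
#' profile-sampled ACD, a CAM whose final three residues realise the
#' anchoring motif exactly `camLen` residues after the ACD, and a
#' background tail.  Metadata are drawn from the parameter distributions;
#' the truth row records all region boundaries.
#'
#' @param p Sampling [ProfileHMM-class].
#' @param params A [synthesisParams()] object.
#' @param index Record index (used in the accession).
#' @param seed Optional seed (`NULL`: current RNG state).
#' @return list(accession, residues, lineage, group, isFragment,
#'   existenceLevel, truth) where `truth` is a one-row data.frame.
#' @export
generateRecord <- function(p, params, index, seed = NULL) {
    withSeed(seed, {
        bg <- p@background
        ntermLen <- .rtruncLen(1, params$ntermMean, params$ntermSd, 0)
        camLen <- .rtruncLen(1, params$camMean, params$camSd,
                             params$camMin)
        tailLen <- .rtruncLen(1, params$tailMean, params$tailSd, 0)
        acd <- sampleAcd(p)
        acdRes <- .mutate(acd$residues, params$mutationRate)
        cam <- .makeCam(camLen, params, bg)
        resid <- paste0(.sampleBg(ntermLen, bg), acdRes, cam,
                        .sampleBg(tailLen, bg))
        meta <- .drawMeta(params)
        acc <- sprintf("SYNP%04d", index)
        truth <- data.frame(
            accession = acc, is_positive = TRUE,
            acd_start = ntermLen + 1L,
            acd_end = ntermLen + acd$length,
            b2b5_len = unname(acd$zoneLengths["b2b5"]),
            l57_len = unname(acd$zoneLengths["L57"]),
            b7b9_len = unname(acd$zoneLengths["b7b9"]),
            cam_len = camLen, tail_len = tailLen,
            group = meta$group, stringsAsFactors = FALSE)
        c(list(accession = acc, residues = resid), meta,
          list(truth = truth))
    })
}

.generateDecoy <- function(p, params, index) {
    bg <- p@background
    L <- .rtruncLen(1, params$ntermMean, params$ntermSd, 0) +
        round(stats::rnorm(1, profileLength(p), 5)) +
        .rtruncLen(1, params$camMean, params$camSd, params$camMin) +
        .rtruncLen(1, params$tailMean, params$tailSd, 0)
    L <- max(L, 30)
    meta <- .drawMeta(params)
    acc <- sprintf("SYND%04d", index)
    truth <- data.frame(accession = acc, is_positive = FALSE,
                        acd_start = NA_integer_, acd_end = NA_integer_,
                        b2b5_len = NA_integer_, l57_len = NA_integer_,
                        b7b9_len = NA_integer_, cam_len = NA_integer_,
                        tail_len = NA_integer_, group = meta$group,
                        stringsAsFactors = FALSE)
    c(list(accession = acc, residues = .sampleBg(L, bg)), meta,
      list(truth = truth))
}

#' Generate a synthetic databank with ground truth
#'
#' Positives carry a planted (mutated) profile-sampled ACD and an exact
#' CAM; decoys are background-only.  The record order is shuffled.
#' Deterministic given `params$seed`.
#'
#' @param p Sampling [ProfileHMM-class] (see [syntheticSeedProfile()]).
#' @param params A [synthesisParams()] object.
#' @return list(bank = [SequenceBank-class], truth = data.frame).
#' @export
generateDataset <- function(p, params = synthesisParams()) {
    stopifnot(inherits(params, "SynthesisParams"))
    if (params$nPositives + params$nDecoys == 0)
        stop("nPositives + nDecoys must be positive")
    withSeed(params$seed, {
        recs <- c(
            lapply(seq_len(params$nPositives), function(i)
                generateRecord(p, params, i)),
            lapply(seq_len(params$nDecoys), function(i)
                .generateDecoy(p, params, i)))
        recs <- recs[sample(length(recs))]
        seqs <- Biostrings::AAStringSet(vapply(recs, `[[`, character(1),
                                               "residues"))
        names(seqs) <- vapply(recs, `[[`, character(1), "accession")
        meta <- .emptyMeta(length(recs))
        meta$description <- ifelse(
            vapply(recs, function(r) r$truth$is_positive, logical(1)),
            "synthetic sHSP-like record", "synthetic background decoy")
        meta$lineage <- lapply(recs, `[[`, "lineage")
        meta$isFragment <- vapply(recs, `[[`, logical(1), "isFragment")
        meta$existenceLevel <- vapply(recs, function(r)
            as.integer(r$existenceLevel), integer(1))
        truth <- do.call(rbind, lapply(recs, `[[`, "truth"))
        list(bank = new("SequenceBank", seqs = seqs, meta = meta),
             truth = truth)
    })
}

#' Write a synthetic dataset to disk
#'
#' Produces `db.fasta`, `meta.tsv` (accession, lineage, fragment,
#' existence) and `truth.tsv` under `dir`.
#'
#' @param dataset From [generateDataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "db.fasta")
    writeFastaBank(dataset$bank, fa)
    meta <- file.path(dir, "meta.tsv")
    bank <- dataset$bank
    utils::write.table(
        data.frame(accession = accessions(bank),
                   lineage = vapply(lineages(bank), paste,
                                    character(1), collapse = ";"),
                   fragment = as.integer(isFragment(bank)),
                   existence = existenceLevel(bank)),
        meta, sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- file.path(dir, "truth.tsv")
    utils::write.table(dataset$truth, tr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(fasta = fa, meta = meta, truth = tr))
}
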