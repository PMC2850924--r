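# Taxonomic grouping, bacterial class A/B assignment, gap-aware logos,
# length distributions and annotation-overlap summaries.

.GROUPS <- c("animals", "plants", "fungi", "archaea",
             "bacA", "bacB", "bacOther", "other")

#' Taxonomic group of one record
#'
#' Lineage-based grouping: Metazoa -> animals, Viridiplantae -> plants,
#' Fungi -> fungi, Archaea -> archaea, other Eukaryota -> other;
#' Bacteria -> `"bacteria_pending"`, to be resolved into bacA / bacB /
#' bacOther by [classifyBacterial()].  An empty lineage maps to other.
#'
#' @param lineage Character vector of taxon names (may be empty).
#' @return One of `"animals"`, `"plants"`, `"fungi"`, `"archaea"`,
#'   `"other"`, `"bacteria_pending"`.
#' @examples
#' assignTaxonomicGroup(c("Eukaryota", "Metazoa", "Chordata"))
#' @export
assignTaxonomicGroup <- function(lineage) {
    if (!length(lineage)) return("other")
    if ("Metazoa" %in% lineage) return("animals")
    if ("Viridiplantae" %in% lineage) return("plants")
    if ("Fungi" %in% lineage) return("fungi")
    if ("Archaea" %in% lineage) return("archaea")
    if ("Bacteria" %in% lineage) return("bacteria_pending")
    "other"
}

#' Global pairwise alignment score and percent identity
#'
#' Needleman-Wunsch global alignment with affine gaps (a gap of length L
#' costs `gapOpen + L * gapExtend`), delegated to
#' [Biostrings::pairwiseAlignment()].  Percent identity is
#' `matches / alignment length * 100`, the alignment length counting gap
#' positions.
#'
#' @param a Non-empty residue string(s); vectorised (all aligned against
#'   the one subject `b` in a single call).
#' @param b A single non-empty residue string.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`) or an
#'   explicit matrix.
#' @param gapOpen,gapExtend Affine gap parameters (defaults 10 and 1).
#' @return list(score, identity), each of length `length(a)`; identity in
#'   percent.
#' @examples
#' needlemanWunsch("ACDEFG", "ACDEFG")$identity   # 100
#' @export
needlemanWunsch <- function(a, b, matrix = "BLOSUM62",
                            gapOpen = 10, gapExtend = 1) {
    stopifnot(all(nzchar(a)), length(b) == 1, nzchar(b))
    matrix <- .substMatrix(matrix)
    al <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(a), Biostrings::AAString(b),
        substitutionMatrix = matrix, gapOpening = gapOpen,
        gapExtension = gapExtend, type = "global")
    list(score = Biostrings::score(al),
         identity = 100 * Biostrings::nmatch(al) / Biostrings::nchar(al))
}

.substMatrixCache <- new.env(parent = emptyenv())

.substMatrix <- function(matrix) {
    if (!is.character(matrix)) return(matrix)
    if (is.null(.substMatrixCache[[matrix]])) {
        e <- new.env()
        utils::data(list = matrix, package = "Biostrings", envir = e)
        .substMatrixCache[[matrix]] <- get(matrix, envir = e)
    }
    .substMatrixCache[[matrix]]
}

#' Classify a bacterial sHSP into class A, class B or neither
#'
#' Compares the sequence against reference sets of the two described
#' bacterial sHSP classes by global-alignment percent identity and labels
#' it with the better-matching class when that best identity reaches
#' `minIdentity`; otherwise (including ties) `"bacOther"`.
#'
#' @param residues Query residue string.
#' @param refsA,refsB Non-empty character vectors of reference residue
#'   strings for class A and class B.
#' @param minIdentity Percent identity threshold (default 40).
#' @param ... Passed to [needlemanWunsch()].
#' @return `"bacA"`, `"bacB"` or `"bacOther"`.
#' @export
classifyBacterial <- function(residues, refsA, refsB, minIdentity = 40,
                              ...) {
    if (!length(refsA) || !length(refsB))
        stop("reference sets must be non-empty")
    bestA <- max(needlemanWunsch(unname(refsA), residues, ...)$identity)
    bestB <- max(needlemanWunsch(unname(refsB), residues, ...)$identity)
    if (bestA == bestB) return("bacOther")
    best <- max(bestA, bestB)
    if (best < minIdentity) return("bacOther")
    if (bestA > bestB) "bacA" else "bacB"
}

#' Read a bacterial class reference TSV
#'
#' Two columns: `accession`, `residues`; a `class` column (`A`/`B`) splits
#' one file into the two reference sets.  The packaged
#' `synthetic_bac_refs.tsv` is a synthetic stand-in fixture, not the
#' published class members; replace it with real reference sequences for
#' biological use.
#'
#' @param path TSV path; default the packaged synthetic fixture.
#' @return list(refsA, refsB) of named character vectors.
#' @export
readBacterialRefs <- function(path = system.file("extdata",
                                                 "synthetic_bac_refs.tsv",
                                                 package = "acdscan")) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("accession", "class", "residues") %in% colnames(tab)))
    list(refsA = stats::setNames(tab$residues[tab$class == "A"],
                                 tab$accession[tab$class == "A"]),
         refsB = stats::setNames(tab$residues[tab$class == "B"],
                                 tab$accession[tab$class == "B"]))
}

#' Group labels for a whole bank
#'
#' Applies [assignTaxonomicGroup()] to every record and resolves
#' bacterial records with [classifyBacterial()] when reference sets are
#' given (otherwise bacteria become `"bacOther"`).
#'
#' @param bank A [SequenceBank-class].
#' @param refsA,refsB Optional bacterial class references.
#' @param minIdentity Threshold for [classifyBacterial()].
#' @return Character vector of group labels, named by accession.
#' @export
assignGroups <- function(bank, refsA = NULL, refsB = NULL,
                         minIdentity = 40) {
    lin <- lineages(bank)
    g <- vapply(lin, assignTaxonomicGroup, character(1))
    pending <- g == "bacteria_pending"
    if (any(pending)) {
        if (is.null(refsA) || is.null(refsB)) {
            g[pending] <- "bacOther"
        } else {
            res <- bankResidues(bank)[pending]
            g[pending] <- vapply(res, function(s)
                classifyBacterial(s, refsA, refsB, minIdentity),
                character(1))
        }
    }
    stats::setNames(g, accessions(bank))
}

#' Gap-aware logo counts and information content
#'
#' Counts, per profile column, the residues that matched that column
#' across the hits; a deleted column counts as the explicit gap symbol
#' (21st symbol).  Insertions match no profile position and are ignored.
#' Information content is `I(c) = log2(21) - H(c)` with `H` the Shannon
#' entropy over the 21-symbol frequencies; drawn letter heights are
#' `freq(aa) * I(c)` for the 20 amino acids only (the gap is counted but
#' not drawn).  The optional small-sample correction subtracts
#' `(21 - 1) / (2 ln(2) n)` from `I(c)` (clamped at 0).
#'
#' @param hits Hit table from [scanBank()].
#' @param bank The scanned [SequenceBank-class].
#' @param p The [ProfileHMM-class].
#' @param correction `"none"` (default) or `"smallsample"`.
#' @return A [LogoMatrix-class].
#' @export
logoCounts <- function(hits, bank, p,
                       correction = c("none", "smallsample")) {
    correction <- match.arg(correction)
    stopifnot(is(bank, "SequenceBank"), is(p, "ProfileHMM"))
    M <- profileLength(p)
    counts <- matrix(0, M, 21, dimnames = list(NULL, c(.AA20, "-")))
    for (r in seq_len(nrow(hits))) {
        res <- strsplit(bankResidues(bank, hits$accession[r]), "")[[1]]
        map <- as.integer(hits$columnMap[[r]])
        for (j in seq_len(M)) {
            if (is.na(map[j]) || map[j] == 0L) {
                counts[j, 21] <- counts[j, 21] + 1
            } else {
                aa <- res[map[j]]
                if (aa %in% .AA20)
                    counts[j, aa] <- counts[j, aa] + 1
            }
        }
    }
    n <- rowSums(counts)
    info <- rep(NA_real_, M)
    heights <- matrix(0, M, 20, dimnames = list(NULL, .AA20))
    for (j in seq_len(M)) {
        if (n[j] == 0) next
        f <- counts[j, ] / n[j]
        h <- -sum(ifelse(f > 0, f * log2(f), 0))
        ic <- log2(21) - h
        if (correction == "smallsample")
            ic <- max(0, ic - 20 / (2 * log(2) * n[j]))
        info[j] <- ic
        heights[j, ] <- f[1:20] * ic
    }
    if (anyNA(info))
        warning(sum(is.na(info)),
                " profile column(s) have zero observations; ",
                "information content undefined there")
    new("LogoMatrix", counts = counts, info = info, heights = heights)
}

#' Write a logo matrix as TSV
#'
#' Long format: column, symbol, count, info_bits, height (height `NA` for
#' the gap symbol, which is counted but never drawn).
#'
#' @param logo A [LogoMatrix-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeLogo <- function(logo, path) {
    M <- nrow(logo@counts)
    sym <- colnames(logo@counts)
    df <- data.frame(
        column = rep(seq_len(M), each = 21),
        symbol = rep(sym, M),
        count = as.vector(t(logo@counts)),
        info_bits = rep(logo@info, each = 21),
        height = as.vector(t(cbind(logo@heights, NA_real_))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Integer length distribution with summary statistics
#'
#' @param values Non-negative integer lengths.
#' @param interval Optional `c(lo, hi)`: also report the fraction of
#'   values inside the closed interval.
#' @return list(histogram = data.frame(length, count), n, mean, sd,
#'   mode, fraction) — `fraction` is `NA` without an interval; all
#'   fields empty/`NA` for empty input.
#' @examples
#' lengthDistribution(c(83, 83, 90))$mode
#' @export
lengthDistribution <- function(values, interval = NULL) {
    values <- values[!is.na(values)]
    if (any(values < 0) || any(values != round(values)))
        stop("lengths must be non-negative integers")
    if (!length(values))
        return(list(histogram = data.frame(length = integer(0),
                                           count = integer(0)),
                    n = 0L, mean = NA_real_, sd = NA_real_,
                    mode = NA_integer_, fraction = NA_real_))
    tab <- table(values)
    hist <- data.frame(length = as.integer(names(tab)),
                       count = as.integer(tab))
    frac <- if (is.null(interval)) NA_real_
            else mean(values >= interval[1] & values <= interval[2])
    list(histogram = hist, n = length(values),
         mean = mean(values), sd = stats::sd(values),
         mode = hist$length[which.max(hist$count)], fraction = frac)
}

#' Overlap of a detection run with an annotated reference set
#'
#' Percentage of externally labelled accessions recovered by the
#' detection: `100 * |labelled intersect detected| / |labelled|`.
#'
#' @param detected Character vector of detected accessions.
#' @param labeled Non-empty character vector of labelled accessions.
#' @return Percentage (numeric scalar).
#' @export
annotationOverlap <- function(detected, labeled) {
    labeled <- unique(labeled)
    if (!length(labeled))
        stop("the labelled reference set is empty")
    100 * length(intersect(unique(detected), labeled)) / length(labeled)
}
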