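# Monomer architecture: N-terminal / ACD zones (b2b5, L57, b7b9) / CAM /
# C-terminal tail, C-terminal anchoring motif, hydropathy.

#' Mean Kyte-Doolittle hydropathy of a residue stretch
#'
#' Sum of the Kyte-Doolittle indices divided by the stretch length.  `X`
#' contributes 0 to the sum but counts in the length.
#'
#' @param residues Non-empty residue string.
#' @return Numeric scalar.
#' @examples
#' hydropathyScore("III")   # 4.5
#' hydropathyScore("IR")    # 0
#' @export
hydropathyScore <- function(residues) {
    if (!nzchar(residues))
        stop("cannot compute hydropathy of an empty stretch")
    ch <- strsplit(toupper(residues), "")[[1]]
    bad <- setdiff(unique(ch), .AA_ALPHABET)
    if (length(bad))
        stop("illegal residue character(s): ", paste(bad, collapse = ", "))
    v <- .KYTE_DOOLITTLE[ch]
    v[is.na(v)] <- 0      # X
    sum(v) / length(ch)
}

#' Find the C-terminal anchoring motif
#'
#' Searches the C-terminal region (residues after the ACD) for the
#' aliphatic anchor motif: `[IV].[IV]` or, with `extended = TRUE`,
#' `[IVL].[IVL]`.  The *leftmost* occurrence wins (deterministic, and it
#' yields the shortest CAM).
#'
#' @param ctermResidues C-terminal residue string (may be empty).
#' @param extended Use the extended I/V/L-X-I/V/L pattern (default `TRUE`).
#' @return Integer `c(start, end)` in C-terminal coordinates (1-based
#'   inclusive), or `NULL` if absent.
#' @examples
#' findCtermMotif("KTIPVSREEK")   # c(3, 5): "IPV"
#' findCtermMotif("IEIAIPI")      # c(1, 3): leftmost rule
#' @export
findCtermMotif <- function(ctermResidues, extended = TRUE) {
    if (!nzchar(ctermResidues)) return(NULL)
    pat <- if (extended) "[IVL].[IVL]" else "[IV].[IV]"
    m <- regexpr(pat, ctermResidues)
    if (m[1] == -1) return(NULL)
    c(start = as.integer(m[1]), end = as.integer(m[1]) + 2L)
}

#' Delineate the C-terminal Anchoring Module
#'
#' The CAM is the fragment from the end of the ACD to the end of the
#' anchoring motif; the residues after it form the C-terminal tail.
#'
#' @param acdEnd ACD end position (1-based, on the full sequence).
#' @param motifSpan Motif span in C-terminal coordinates
#'   (from [findCtermMotif()]), or `NULL`.
#' @param seqLength Full sequence length.
#' @return list(cam = c(start, end) or NULL, tail = c(start, end) or NULL,
#'   camLen, tailLen); with no motif both regions are absent and lengths
#'   are `NA`.
#' @export
delineateCam <- function(acdEnd, motifSpan, seqLength) {
    if (is.null(motifSpan))
        return(list(cam = NULL, tail = NULL,
                    camLen = NA_integer_, tailLen = NA_integer_))
    motifEnd <- acdEnd + motifSpan[["end"]]
    if (motifEnd > seqLength)
        stop("motif span extends past the sequence end")
    cam <- c(start = acdEnd + 1L, end = as.integer(motifEnd))
    tailLen <- seqLength - motifEnd
    tail <- if (tailLen > 0)
        c(start = as.integer(motifEnd) + 1L, end = as.integer(seqLength))
    else NULL
    list(cam = cam, tail = tail,
         camLen = as.integer(motifSpan[["end"]]),
         tailLen = as.integer(tailLen))
}

# Assign every envelope residue (matched or inserted) to a zone; returns
# per-zone lengths and spans.  Insertions between two columns of the same
# zone count in that zone; insertions at a zone boundary go to the
# preceding zone (inserts before column 1 go to the first zone).
.zoneSlices <- function(hit, p) {
    M <- profileLength(p)
    zones <- zoneOfElement(p@landmarks)
    map <- hit$map
    ins <- hit$inserts
    zoneOfResidue <- rep(NA_character_,
                         hit$envEnd - hit$envStart + 1)
    off <- function(pos) pos - hit$envStart + 1
    for (j in seq_len(M)) {
        if (!is.na(map[j])) zoneOfResidue[off(map[j])] <- zones[j]
    }
    # insert residues: fill gaps left of first assignment forward,
    # others inherit the zone of the residue to their left
    first <- which(!is.na(zoneOfResidue))[1]
    if (is.na(first)) stop("hit has no matched column")
    if (first > 1) zoneOfResidue[seq_len(first - 1)] <- zoneOfResidue[first]
    for (k in seq_along(zoneOfResidue))
        if (is.na(zoneOfResidue[k])) zoneOfResidue[k] <- zoneOfResidue[k - 1]
    lens <- c(b2b5 = sum(zoneOfResidue == "b2b5"),
              L57 = sum(zoneOfResidue == "L57"),
              b7b9 = sum(zoneOfResidue == "b7b9"))
    spans <- lapply(c("b2b5", "L57", "b7b9"), function(z) {
        w <- which(zoneOfResidue == z)
        if (!length(w)) return(NULL)
        c(start = hit$envStart + min(w) - 1L,
          end = hit$envStart + max(w) - 1L)
    })
    names(spans) <- c("b2b5", "L57", "b7b9")
    list(lengths = lens, spans = spans)
}

#' Slice one monomer into its architectural regions
#'
#' From a detected ACD envelope, delineates the N-terminal region (before
#' the envelope), the ACD with its three zones (beta2-beta5, L57 loop,
#' beta7-beta9; insertions at a zone boundary are assigned to the
#' preceding zone, deletions contribute zero length), the C-terminal
#' Anchoring Module ending at the anchoring motif, and the C-terminal
#' tail.  Region coordinates are 1-based inclusive and the three top-level
#' regions partition the sequence.
#'
#' @param residues Full-length residue string of the record.
#' @param hit A single hit as returned by [viterbiScore()] (list with
#'   `map`, `inserts`, `envStart`, `envEnd`) or one row of a [scanBank()]
#'   table (see [annotateArchitecture()] for the vectorised path).
#' @param p The [ProfileHMM-class] that produced the hit.
#' @param extended Use the extended motif for CAM delineation (default
#'   `TRUE`).
#' @return A list with regions (`nterm`, `acd`, `cterm`, zone spans,
#'   `cam`, `tail` as `c(start, end)` or `NULL`), zone lengths, motif
#'   information and per-zone hydropathy scores.
#' @export
sliceRegions <- function(residues, hit, p, extended = TRUE) {
    stopifnot(length(residues) == 1)
    residues <- unname(residues)
    L <- nchar(residues)
    stopifnot(hit$envStart >= 1, hit$envEnd <= L,
              hit$envStart <= hit$envEnd)
    zs <- .zoneSlices(hit, p)
    acd <- c(start = hit$envStart, end = hit$envEnd)
    nterm <- if (hit$envStart > 1) c(start = 1L, end = hit$envStart - 1L)
             else NULL
    cterm <- if (hit$envEnd < L) c(start = hit$envEnd + 1L, end = L)
             else NULL
    ctermStr <- if (is.null(cterm)) ""
                else substr(residues, cterm[["start"]], cterm[["end"]])
    motif <- findCtermMotif(ctermStr, extended = extended)
    basic <- findCtermMotif(ctermStr, extended = FALSE)
    cam <- delineateCam(hit$envEnd, motif, L)
    motifKind <- if (is.null(motif)) "none" else {
        flanks <- substring(ctermStr,
                            c(motif[["start"]], motif[["end"]]),
                            c(motif[["start"]], motif[["end"]]))
        if (all(flanks %in% c("I", "V"))) "IVxIV" else "IVLxIVL"
    }
    motifSeq <- if (is.null(motif)) NA_character_
                else substr(ctermStr, motif[["start"]], motif[["end"]])
    hyd <- lapply(zs$spans, function(sp) {
        if (is.null(sp)) return(NA_real_)
        hydropathyScore(substr(residues, sp[["start"]], sp[["end"]]))
    })
    zeroZones <- names(zs$lengths)[zs$lengths == 0]
    list(nterm = nterm, acd = acd, cterm = cterm,
         zones = zs$spans, zoneLengths = zs$lengths,
         ntermLen = if (is.null(nterm)) 0L
                    else nterm[["end"]] - nterm[["start"]] + 1L,
         acdLen = acd[["end"]] - acd[["start"]] + 1L,
         ctermLen = if (is.null(cterm)) 0L
                    else cterm[["end"]] - cterm[["start"]] + 1L,
         motifKind = motifKind, motifSeq = motifSeq,
         motifSpan = motif, hasBasicMotif = !is.null(basic),
         cam = cam$cam, tail = cam$tail,
         camLen = cam$camLen, tailLen = cam$tailLen,
         hydropathy = c(b2b5 = hyd$b2b5, L57 = hyd$L57, b7b9 = hyd$b7b9),
         flaggedZones = zeroZones)
}

#' Architecture table for a set of hits
#'
#' Vectorised [sliceRegions()] over a hit table: one row per hit with the
#' region lengths, zone lengths, motif call, CAM/tail lengths and per-zone
#' hydropathy.  Write with [writeArchitecture()].
#'
#' @param hits Hit table from [scanBank()] / [iterateProfile()].
#' @param bank The [SequenceBank-class].
#' @param p The [ProfileHMM-class].
#' @param extended Use the extended motif (default `TRUE`).
#' @return A `data.frame` with columns accession, L, nterm_len, acd_start,
#'   acd_end, acd_len, b2b5_len, l57_len, b7b9_len, motif_kind, motif_seq,
#'   has_basic_motif, cam_len, tail_len, hydropathy_b2b5, hydropathy_l57,
#'   hydropathy_b7b9.
#' @export
annotateArchitecture <- function(hits, bank, p, extended = TRUE) {
    stopifnot(is(bank, "SequenceBank"), is(p, "ProfileHMM"))
    out <- vector("list", nrow(hits))
    for (r in seq_len(nrow(hits))) {
        res <- bankResidues(bank, hits$accession[r])
        hit <- list(map = as.integer(hits$columnMap[[r]]),
                    inserts = as.integer(hits$insertCounts[[r]]),
                    envStart = hits$acdStart[r], envEnd = hits$acdEnd[r])
        hit$map[hit$map == 0L] <- NA_integer_
        a <- sliceRegions(res, hit, p, extended = extended)
        out[[r]] <- data.frame(
            accession = hits$accession[r], L = nchar(res),
            nterm_len = a$ntermLen, acd_start = hit$envStart,
            acd_end = hit$envEnd, acd_len = a$acdLen,
            b2b5_len = unname(a$zoneLengths["b2b5"]),
            l57_len = unname(a$zoneLengths["L57"]),
            b7b9_len = unname(a$zoneLengths["b7b9"]),
            motif_kind = a$motifKind, motif_seq = a$motifSeq,
            has_basic_motif = a$hasBasicMotif,
            cam_len = a$camLen, tail_len = a$tailLen,
            hydropathy_b2b5 = unname(a$hydropathy["b2b5"]),
            hydropathy_l57 = unname(a$hydropathy["L57"]),
            hydropathy_b7b9 = unname(a$hydropathy["b7b9"]),
            stringsAsFactors = FALSE)
    }
    if (!length(out)) return(data.frame())
    do.call(rbind, out)
}

#' Write an architecture table as TSV
#'
#' @param arch Table from [annotateArchitecture()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeArchitecture <- function(arch, path) {
    utils::write.table(arch, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export regions in BED-like 0-based half-open coordinates
#'
#' Converts the 1-based inclusive regions of an architecture table to
#' BED-style rows (`start0 = start - 1`, `end` unchanged), one row per
#' region per record, for genome-browser-style viewing.
#'
#' @param arch Table from [annotateArchitecture()].
#' @return A `data.frame` with columns name, start, end, region.
#' @export
architectureToBed <- function(arch) {
    rows <- list()
    for (r in seq_len(nrow(arch))) {
        a <- arch[r, ]
        add <- function(region, s1, e1) {
            if (is.na(s1) || is.na(e1) || e1 < s1) return(NULL)
            data.frame(name = a$accession, start = s1 - 1L, end = e1,
                       region = region, stringsAsFactors = FALSE)
        }
        camEnd <- if (is.na(a$cam_len)) NA_integer_
                  else a$acd_end + a$cam_len
        rows <- c(rows, list(
            if (a$nterm_len > 0) add("nterm", 1L, a$nterm_len),
            add("acd", a$acd_start, a$acd_end),
            if (!is.na(a$cam_len)) add("cam", a$acd_end + 1L, camEnd),
            if (!is.na(a$tail_len) && a$tail_len > 0)
                add("cter_tail", camEnd + 1L, a$L),
            if (is.na(a$cam_len) && a$L > a$acd_end)
                add("cterm", a$acd_end + 1L, a$L)))
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(name = character(0), start = integer(0),
                          end = integer(0), region = character(0)))
    do.call(rbind, rows)
}
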