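# Readers and writers: FASTA databanks, metadata sidecar TSV, seed
# alignments (Stockholm or aligned FASTA + landmark TSV), hit tables.

.emptyMeta <- function(n, accession = character(n)) {
    DataFrame(description = character(n),
              lineage = I(replicate(n, character(0), simplify = FALSE)),
              isFragment = logical(n),
              existenceLevel = rep(5L, n),
              row.names = NULL)
}

#' Read a protein databank from FASTA
#'
#' Parses a FASTA file into a [SequenceBank-class].  The accession is the
#' first whitespace-delimited token of each header; the remainder is kept
#' as the description.  Metadata fields are defaulted (empty lineage, not a
#' fragment, existence level 5 = unknown) until [readMetadata()] merges the
#' sidecar TSV.  Residues outside the 20 canonical amino acids plus `X`
#' (e.g. ambiguity codes `B`, `J`, `Z`) are a parse error naming the
#' offending line.
#'
#' @param path Path to a FASTA file.
#' @return A [SequenceBank-class]; empty file gives an empty bank.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">A demo", "MKT", ">B", "ACDE"), f)
#' readFastaBank(f)
#' @export
readFastaBank <- function(path) {
    if (!file.exists(path)) stop("file does not exist: ", path)
    raw <- readLines(path, warn = FALSE)
    if (!length(raw) || !any(grepl("^>", raw))) {
        if (any(nzchar(trimws(raw))))
            stop("malformed FASTA in ", path,
                 ": sequence data before any '>' header (line ",
                 which(nzchar(trimws(raw)))[1], ")")
        return(new("SequenceBank",
                   seqs = Biostrings::AAStringSet(), meta = .emptyMeta(0)))
    }
    if (nzchar(trimws(raw[1])) && !grepl("^>", raw[1]))
        stop("malformed FASTA in ", path,
             ": sequence data before any '>' header (line 1)")
    # alphabet check with line numbers before delegating assembly
    isHeader <- grepl("^>", raw)
    bodies <- toupper(gsub("[ \t]", "", raw))
    for (i in which(!isHeader)) {
        if (!nzchar(bodies[i])) next
        ch <- strsplit(bodies[i], "")[[1]]
        bad <- setdiff(unique(ch), .AA_ALPHABET)
        if (length(bad))
            stop("illegal residue character '", bad[1], "' in ", path,
                 " (line ", i, ")")
    }
    set <- Biostrings::readBStringSet(path)
    headers <- names(set)
    acc <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    seqs <- Biostrings::AAStringSet(toupper(as.character(set)))
    names(seqs) <- acc
    if (any(Biostrings::width(seqs) == 0))
        stop("entry with empty sequence in ", path, ": ",
             acc[Biostrings::width(seqs) == 0][1])
    meta <- .emptyMeta(length(seqs))
    meta$description <- desc
    new("SequenceBank", seqs = seqs, meta = meta)
}

#' Write a SequenceBank to FASTA
#'
#' Round-trip companion of [readFastaBank()]: accession order and residues
#' are preserved exactly.
#'
#' @param bank A [SequenceBank-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeFastaBank <- function(bank, path) {
    stopifnot(is(bank, "SequenceBank"))
    out <- bank@seqs
    hdr <- names(out)
    withDesc <- nzchar(bank@meta$description)
    hdr[withDesc] <- paste(hdr[withDesc], bank@meta$description[withDesc])
    names(out) <- hdr
    Biostrings::writeXStringSet(out, filepath = path, width = 60L)
    invisible(path)
}

#' Merge curation metadata from a sidecar TSV
#'
#' Fills `lineage`, `isFragment` and `existenceLevel` of a
#' [SequenceBank-class] from a TSV with columns `accession`, `lineage`
#' (semicolon-joined taxon names, may be empty), `fragment` (0/1) and
#' `existence` (1-5).  Records without a TSV row keep their defaults; TSV
#' rows whose accession is not in the bank are reported via a message and
#' returned in the `"unmatched"` attribute.
#'
#' @param path Path to the metadata TSV.
#' @param bank A [SequenceBank-class].
#' @return The updated bank (with attribute `"unmatched"`).
#' @export
readMetadata <- function(path, bank) {
    stopifnot(is(bank, "SequenceBank"))
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("accession", "lineage", "fragment", "existence")
    if (!all(need %in% colnames(tab)))
        stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
    ex <- suppressWarnings(as.integer(tab$existence))
    if (any(is.na(ex)) || any(!ex %in% 1:5))
        stop("existence level outside 1..5 in metadata row(s): ",
             paste(which(is.na(ex) | !ex %in% 1:5), collapse = ", "))
    fr <- suppressWarnings(as.integer(tab$fragment))
    if (any(is.na(fr)) || any(!fr %in% 0:1))
        stop("fragment flag must be 0 or 1 in metadata row(s): ",
             paste(which(is.na(fr) | !fr %in% 0:1), collapse = ", "))
    idx <- match(tab$accession, names(bank@seqs))
    unmatched <- tab$accession[is.na(idx)]
    if (length(unmatched))
        message(length(unmatched), " metadata row(s) match no record: ",
                paste(utils::head(unmatched, 5), collapse = ", "),
                if (length(unmatched) > 5) ", ..." else "")
    keep <- !is.na(idx)
    meta <- bank@meta
    lin <- strsplit(tab$lineage, ";", fixed = TRUE)
    lin <- lapply(lin, function(x) trimws(x[nzchar(trimws(x))]))
    meta$lineage[idx[keep]] <- lin[keep]
    meta$isFragment[idx[keep]] <- fr[keep] == 1L
    meta$existenceLevel[idx[keep]] <- ex[keep]
    out <- new("SequenceBank", seqs = bank@seqs, meta = meta)
    attr(out, "unmatched") <- unmatched
    out
}

.annotationFromCodes <- function(codes) {
    ch <- strsplit(codes, "")[[1]]
    el <- rep(NA_character_, length(ch))
    known <- ch %in% names(.ELEMENT_CODES)
    el[known] <- .ELEMENT_CODES[ch[known]]
    bad <- !known & !ch %in% c(".", "-", " ")
    if (any(bad))
        stop("unknown landmark code(s): ",
             paste(unique(ch[bad]), collapse = ", "))
    SeedAnnotation(el)
}

.annotationFromTable <- function(path, nCol) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("column_index", "element")
    if (!all(need %in% colnames(tab)))
        stop("landmark TSV must have columns: ", paste(need, collapse = ", "))
    ci <- as.integer(tab$column_index)
    if (any(is.na(ci)) || any(ci < 1) || any(ci > nCol))
        stop("landmark column_index outside 1..", nCol)
    if (anyDuplicated(ci)) stop("duplicated landmark column_index")
    el <- rep(NA_character_, nCol)
    el[ci] <- tab$element
    SeedAnnotation(el)
}

#' Read the seed alignment and its structural landmarks
#'
#' The seed is the structure-anchored multiple alignment of reference
#' ACDs.  Two formats are accepted: Stockholm, with the landmark string on
#' a `#=GC ACD_elements` line (one code per column: `2` = b2, `a` = L23,
#' `3` = b3, `b` = L34, `4` = b4, `c` = L45, `5` = b5, `L` = L57, `7` = b7,
#' `d` = L78, `8` = b8, `e` = L89, `9` = b9, `.` = unlabelled), or aligned
#' FASTA plus a separate landmark TSV (`column_index`, `element`).
#'
#' @param path Alignment file (Stockholm or aligned FASTA).
#' @param annotationPath Landmark TSV (required for FASTA input; ignored
#'   for Stockholm).
#' @return A list with components `alignment` ([AcdAlignment-class]) and
#'   `annotation` ([SeedAnnotation-class]).
#' @export
readSeedAlignment <- function(path, annotationPath = NULL) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) && grepl("^# STOCKHOLM", lines[1])) {
        msa <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
        rows <- as.character(msa)
        gc <- grep("^#=GC\\s+ACD_elements\\s+", lines, value = TRUE)
        if (!length(gc))
            stop("Stockholm seed lacks a '#=GC ACD_elements' landmark line")
        codes <- paste(sub("^#=GC\\s+ACD_elements\\s+", "", gc),
                       collapse = "")
        aln <- AcdAlignment(toupper(rows))
        if (nchar(codes) != nColumns(aln))
            stop("landmark string length (", nchar(codes),
                 ") differs from alignment width (", nColumns(aln), ")")
        ann <- .annotationFromCodes(codes)
    } else {
        set <- Biostrings::readBStringSet(path)
        acc <- sub("\\s.*$", "", names(set))
        rows <- toupper(as.character(set))
        names(rows) <- acc
        aln <- AcdAlignment(rows)
        if (is.null(annotationPath))
            stop("aligned FASTA seed requires a landmark TSV (annotationPath)")
        ann <- .annotationFromTable(annotationPath, nColumns(aln))
    }
    validObject(aln); validObject(ann)
    list(alignment = aln, annotation = ann)
}

#' Write an alignment as Stockholm
#'
#' @param aln An [AcdAlignment-class].
#' @param path Output file.
#' @param annotation Optional [SeedAnnotation-class]; if given, landmark
#'   codes are written on a `#=GC ACD_elements` line.
#' @return Invisibly, `path`.
#' @export
writeStockholm <- function(aln, path, annotation = NULL) {
    stopifnot(is(aln, "AcdAlignment"))
    acc <- names(aln@sequences)
    w <- max(nchar(c(acc, "#=GC ACD_elements"))) + 2L
    con <- file(path, "w"); on.exit(close(con))
    writeLines("# STOCKHOLM 1.0", con)
    writeLines(sprintf("%-*s%s", w, acc, aln@sequences), con)
    if (!is.null(annotation)) {
        rev <- stats::setNames(names(.ELEMENT_CODES), .ELEMENT_CODES)
        codes <- ifelse(is.na(annotation@elements), ".",
                        rev[annotation@elements])
        writeLines(sprintf("%-*s%s", w, "#=GC ACD_elements",
                           paste(codes, collapse = "")), con)
    }
    writeLines("//", con)
    invisible(path)
}

#' Write a hit table as TSV
#'
#' Columns: accession, acd_start, acd_end, bits, evalue (and multi_acd
#' when present).  Coordinates are 1-based inclusive.
#'
#' @param hits A hit [S4Vectors::DataFrame] from [scanBank()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeHits <- function(hits, path) {
    df <- data.frame(accession = hits$accession,
                     acd_start = hits$acdStart,
                     acd_end = hits$acdEnd,
                     bits = hits$bitScore,
                     evalue = hits$eValue)
    if (!is.null(hits$multiAcd)) df$multi_acd <- as.integer(hits$multiAcd)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
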