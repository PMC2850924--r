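# Generics, accessors and show methods for the core classes.

#' @name accessors
#' @title Accessors for acdscan objects
#' @description Small accessor family: use these instead of reaching into
#'   slots.
#' @param x,object An object of the documented class.
#' @param value Replacement value.
#' @param i Index for subsetting.
#' @return The accessed component (see the individual generic).
NULL

#' @describeIn accessors Accession identifiers of a [SequenceBank-class],
#'   [AcdAlignment-class] or hit table.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @describeIn accessors Per-record taxonomic lineages (list of character
#'   vectors).
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @describeIn accessors Logical fragment flags.
#' @export
setGeneric("isFragment", function(x) standardGeneric("isFragment"))

#' @describeIn accessors Protein-existence levels (1..5, 5 = unknown).
#' @export
setGeneric("existenceLevel", function(x) standardGeneric("existenceLevel"))

#' @describeIn accessors Number of match states M of a [ProfileHMM-class].
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' @describeIn accessors Structural element label of each profile column.
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @describeIn accessors Match emission probability matrix (M x 20).
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))

#' @describeIn accessors Gumbel calibration of a profile ([GumbelFit-class]
#'   or `NULL`).
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @describeIn accessors Set/replace the calibration of a profile.
#' @export
setGeneric("calibration<-",
           function(x, value) standardGeneric("calibration<-"))

#' @describeIn accessors Accessions of a SequenceBank.
#' @export
setMethod("accessions", "SequenceBank", function(x) names(x@seqs))

#' @describeIn accessors Accessions (row names) of an alignment.
#' @export
setMethod("accessions", "AcdAlignment", function(x) names(x@sequences))

#' @describeIn accessors Lineages of a SequenceBank.
#' @export
setMethod("lineages", "SequenceBank", function(x) as.list(x@meta$lineage))

#' @describeIn accessors Fragment flags of a SequenceBank.
#' @export
setMethod("isFragment", "SequenceBank", function(x) x@meta$isFragment)

#' @describeIn accessors Existence levels of a SequenceBank.
#' @export
setMethod("existenceLevel", "SequenceBank",
          function(x) x@meta$existenceLevel)

#' @describeIn accessors Number of records in the bank.
#' @export
setMethod("length", "SequenceBank", function(x) length(x@seqs))

#' @describeIn accessors Subset a bank by index or accession.
#' @export
setMethod("[", "SequenceBank", function(x, i) {
    if (is.character(i)) i <- match(i, names(x@seqs))
    new("SequenceBank", seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

#' Residues of one or all records
#'
#' @param x A [SequenceBank-class].
#' @param accession Optional single accession; if omitted, a named
#'   character vector of all residue strings is returned.
#' @return Character residue string(s).
#' @export
bankResidues <- function(x, accession = NULL) {
    stopifnot(is(x, "SequenceBank"))
    if (is.null(accession)) return(as.character(x@seqs))
    i <- match(accession, names(x@seqs))
    if (any(is.na(i)))
        stop("unknown accession(s): ",
             paste(accession[is.na(i)], collapse = ", "))
    as.character(x@seqs[i])
}

#' @describeIn accessors Alignment row strings (named character vector).
#' @export
alignedSequences <- function(x) {
    stopifnot(is(x, "AcdAlignment"))
    x@sequences
}

#' @describeIn accessors Number of columns of an alignment.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @describeIn accessors Number of columns of an alignment.
#' @export
setMethod("nColumns", "AcdAlignment",
          function(x) nchar(x@sequences[[1]]))

#' @describeIn accessors Element labels per column of a SeedAnnotation.
#' @export
elementOfColumn <- function(x) {
    stopifnot(is(x, "SeedAnnotation"))
    x@elements
}

#' @describeIn accessors Profile length.
#' @export
setMethod("profileLength", "ProfileHMM", function(x) nrow(x@matchEmit))

#' @describeIn accessors Profile landmarks.
#' @export
setMethod("landmarks", "ProfileHMM", function(x) x@landmarks)

#' @describeIn accessors Match emissions.
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmit)

#' @describeIn accessors Profile calibration.
#' @export
setMethod("calibration", "ProfileHMM", function(x) x@calibration)

#' @describeIn accessors Replace profile calibration.
#' @export
setMethod("calibration<-", "ProfileHMM", function(x, value) {
    x@calibration <- value
    validObject(x)
    x
})

setMethod("show", "SequenceBank", function(object) {
    cat("SequenceBank with", length(object@seqs), "records\n")
    if (length(object@seqs)) {
        w <- Biostrings::width(object@seqs)
        cat("  residue lengths:", min(w), "-", max(w), "\n")
        cat("  fragments:", sum(object@meta$isFragment),
            "| existence <= 3:", sum(object@meta$existenceLevel <= 3), "\n")
    }
})

setMethod("show", "AcdAlignment", function(object) {
    cat("AcdAlignment:", length(object@sequences), "rows x",
        nchar(object@sequences[[1]]), "columns\n")
})

setMethod("show", "ProfileHMM", function(object) {
    M <- nrow(object@matchEmit)
    z <- zoneOfElement(object@landmarks)
    cat("ProfileHMM with", M, "match states\n")
    cat("  zones (columns): b2b5 =", sum(z == "b2b5"),
        "| L57 =", sum(z == "L57"), "| b7b9 =", sum(z == "b7b9"), "\n")
    if (is.null(object@calibration)) {
        cat("  calibration: none\n")
    } else {
        cat(sprintf("  calibration: Gumbel mu = %.2f bits, lambda = %.3f\n",
                    object@calibration@mu, object@calibration@lambda))
    }
})

setMethod("show", "GumbelFit", function(object) {
    cat(sprintf(
        "GumbelFit: mu = %.3f bits, lambda = %.4f (n = %d, length = %d)\n",
        object@mu, object@lambda, object@nSamples, object@sampleLength))
})

setMethod("show", "LogoMatrix", function(object) {
    cat("LogoMatrix over", nrow(object@counts), "profile columns;",
        "max information", sprintf("%.2f", max(object@info, na.rm = TRUE)),
        "bits\n")
})
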