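# Versioned JSON serialisation of profiles.  Emissions are stored as
# log2-odds against the profile background (the scale scoring uses);
# probabilities are reconstructed on read.

.PROFILE_FORMAT <- "acdscan-profile-1"

#' Write a profile to a JSON text file
#'
#' @param p A [ProfileHMM-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @seealso [readProfileHMM()]
#' @export
writeProfileHMM <- function(p, path) {
    stopifnot(is(p, "ProfileHMM"))
    bg <- p@background
    obj <- list(
        format = .PROFILE_FORMAT,
        M = profileLength(p),
        alphabet = paste(.AA20, collapse = ""),
        background = unname(bg),
        landmarks = p@landmarks,
        # zero probabilities floor at -99999 (JSON has no -Inf)
        match_log2odds = unname(pmax(log2(sweep(p@matchEmit, 2, bg, "/")),
                                     -99999)),
        insert_log2odds = unname(pmax(log2(sweep(p@insertEmit, 2, bg,
                                                 "/")), -99999)),
        transitions = list(MM = p@tMM, MI = p@tMI, MD = p@tMD,
                           IM = p@tIM, II = p@tII,
                           DM = p@tDM, DD = p@tDD),
        calibration = if (is.null(p@calibration)) NULL else list(
            mu = p@calibration@mu, lambda = p@calibration@lambda,
            n_samples = p@calibration@nSamples,
            sample_length = p@calibration@sampleLength,
            seed = p@calibration@seed))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' Read a profile from its JSON serialisation
#'
#' @param path File written by [writeProfileHMM()].
#' @return A [ProfileHMM-class].
#' @export
readProfileHMM <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, .PROFILE_FORMAT))
        stop("unrecognised profile format: ", obj$format)
    bg <- stats::setNames(obj$background, .AA20)
    me <- 2^obj$match_log2odds
    me <- sweep(matrix(me, obj$M, 20), 2, bg, "*")
    me <- me / rowSums(me)
    colnames(me) <- .AA20
    ie <- 2^obj$insert_log2odds
    ie <- sweep(matrix(ie, obj$M + 1, 20), 2, bg, "*")
    ie <- ie / rowSums(ie)
    colnames(ie) <- .AA20
    cal <- if (is.null(obj$calibration)) NULL else
        new("GumbelFit", mu = obj$calibration$mu,
            lambda = obj$calibration$lambda,
            nSamples = as.integer(obj$calibration$n_samples),
            sampleLength = as.integer(obj$calibration$sample_length),
            seed = as.integer(obj$calibration$seed))
    new("ProfileHMM", matchEmit = me, insertEmit = ie,
        tMM = obj$transitions$MM, tMI = obj$transitions$MI,
        tMD = obj$transitions$MD, tIM = obj$transitions$IM,
        tII = obj$transitions$II, tDM = obj$transitions$DM,
        tDD = obj$transitions$DD,
        background = bg, landmarks = obj$landmarks, calibration = cal)
}
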