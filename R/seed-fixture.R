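# Packaged synthetic seed: a structure-annotated reference alignment of
# ACD-like sequences, generated deterministically in code.  It is a
# synthetic stand-in for a curated structural alignment of reference ACDs
# (real seeds are PDB-derived); sequence patterns follow the family's
# published conservation (P-G doublet in loop L34, charged first half of
# the L57 loop, F-X-R in strand b7, L-P at the start of loop L78,
# N-G-hydrophobic-L around loop L89, D/E-L at the end of strand b9).

.SEED_CONSENSUS <- paste0(
    "EVKVDV",            # b2
    "DNGS",              # L23
    "VLVIEG",            # b3
    "APGLKSED",          # L34 (P-G doublet)
    "VKVNVLE",           # b4
    "NG",                # L45
    "TLVVA",             # b5 (terminal G/A)
    "GKHEEREDEHGKRE",    # L57 loop: charged, hydrophilic
    "VKFQRSV",           # b7 (F-X-R with the conserved arginine)
    "LPDAE",             # L78 (L-P start)
    "VSGLSAE",           # b8
    "NGVL",              # L89 (N-G-hydrophobic-L)
    "AKIRVDEL")          # b9 (D/E-L end)

.SEED_ELEMENT_SPANS <- c(b2 = 6L, L23 = 4L, b3 = 6L, L34 = 8L, b4 = 7L,
                         L45 = 2L, b5 = 5L, L57 = 14L, b7 = 7L, L78 = 5L,
                         b8 = 7L, L89 = 4L, b9 = 8L)

#' The packaged synthetic seed alignment
#'
#' A deterministic, ungapped 12-row alignment of 83 columns: the family
#' consensus above, with each row mutated at a fixed fraction of sites.
#' Zone geometry is 38 columns (beta2-beta5), 14 (L57 loop) and 31
#' (beta7-beta9) -- the alpha-crystallin-like architecture with an ACD of
#' exactly 83 residues.  This is a synthetic stand-in for a curated
#' structural seed, suitable for benchmarks and examples; it ships in
#' `inst/extdata/` as `synthetic_seed.sto` as well.
#'
#' @param nRows Number of rows (default 12).
#' @param divergence Per-site substitution fraction per row (default
#'   0.22).
#' @param seed RNG seed fixing the alignment (default 7121).
#' @return list(alignment = [AcdAlignment-class],
#'   annotation = [SeedAnnotation-class]).
#' @examples
#' s <- syntheticSeedAlignment()
#' nColumns(s$alignment)
#' @export
syntheticSeedAlignment <- function(nRows = 12L, divergence = 0.22,
                                   seed = 7121L) {
    stopifnot(nRows >= 2, divergence >= 0, divergence < 1)
    cons <- strsplit(.SEED_CONSENSUS, "")[[1]]
    rows <- withSeed(seed, {
        vapply(seq_len(nRows), function(r) {
            ch <- cons
            k <- round(divergence * length(ch))
            if (k > 0) {
                at <- sample(length(ch), k)
                for (i in at) ch[i] <- sample(setdiff(.AA20, ch[i]), 1)
            }
            paste(ch, collapse = "")
        }, character(1))
    })
    names(rows) <- sprintf("SEED%02d", seq_len(nRows))
    elements <- rep(names(.SEED_ELEMENT_SPANS), .SEED_ELEMENT_SPANS)
    list(alignment = AcdAlignment(rows),
         annotation = SeedAnnotation(elements))
}

#' Profiles of the packaged synthetic seed
#'
#' Convenience builders on [syntheticSeedAlignment()].  The *sampling*
#' profile (`role = "sampling"`) is sharpened -- emission pseudocount
#' weight 1 and no transition smoothing -- so that sequences drawn from it
#' form a coherent family with the seed's exact ungapped geometry (every
#' sampled ACD spans the 83 columns; all sequence-level noise comes from
#' the generator's mutation rate).  The *detection* profile
#' (`role = "detection"`) uses the standard build defaults
#' (pseudocount weight 20, Laplace transition smoothing) and is what the
#' enrichment loop would construct itself.
#'
#' @param role `"sampling"` (default) or `"detection"`.
#' @param background Passed to [buildProfile()].
#' @return A [ProfileHMM-class] (uncalibrated).
#' @export
syntheticSeedProfile <- function(role = c("sampling", "detection"),
                                 background = backgroundFrequencies()) {
    role <- match.arg(role)
    s <- syntheticSeedAlignment()
    if (role == "sampling")
        buildProfile(s$alignment, s$annotation, pseudocountWeight = 1,
                     transitionPseudocount = 0, background = background)
    else
        buildProfile(s$alignment, s$annotation, background = background)
}
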