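# Monomer slicing, motif search, CAM delineation, hydropathy.

# A constructed profile whose 86 columns map 1:1 onto targets 55..140 of a
# 200-residue record: N-term 54, ACD 86 (zones 38/21/27 with the L57 loop
# on targets 93..113), C-term 60.
.constructedCase <- function() {
    landmarks <- rep(c("b2", "L23", "b3", "L34", "b4", "L45", "b5",
                       "L57", "b7", "L78", "b8", "L89", "b9"),
                     c(10, 5, 5, 8, 5, 2, 3, 21, 10, 5, 7, 2, 3))
    p <- toyProfile(matrix(rep(0.05, 20 * 86), 86, 20),
                    landmarks = landmarks)
    res <- paste(rep("A", 200), collapse = "")
    hit <- list(map = 55:140, inserts = integer(87),
                envStart = 55L, envEnd = 140L)
    list(p = p, res = res, hit = hit)
}

test_that("region slicing partitions the monomer and its zones", {
    cc <- .constructedCase()
    a <- sliceRegions(cc$res, cc$hit, cc$p)
    expect_equal(a$ntermLen, 54L)
    expect_equal(a$acdLen, 86L)
    expect_equal(unname(a$zoneLengths),
                 c(38L, 21L, 27L))
    expect_equal(sum(a$zoneLengths), a$acdLen)
    expect_equal(unname(a$zones$L57), c(93L, 113L))
    expect_equal(a$ntermLen + a$acdLen + a$ctermLen, 200L)
})

test_that("a hit covering the whole sequence leaves empty termini", {
    p <- toyProfile(matrix(rep(0.05, 60), 3, 20),
                    landmarks = c("b2", "L57", "b9"))
    hit <- list(map = 1:3, inserts = integer(4), envStart = 1L,
                envEnd = 3L)
    a <- sliceRegions("ACD", hit, p)
    expect_equal(a$ntermLen, 0L)
    expect_equal(a$ctermLen, 0L)
    expect_null(a$nterm)
    expect_null(a$cterm)
    expect_equal(a$motifKind, "none")
})

test_that("alpha-crystallin-like geometry gives an 83-residue ACD", {
    # zone lengths 38 / 14 / 31 -> ACD length exactly 83
    samp <- syntheticSeedProfile("sampling")
    acd <- sampleAcd(samp, seed = 5)
    expect_equal(unname(acd$zoneLengths), c(38L, 14L, 31L))
    expect_equal(acd$length, 83L)
    p <- calibrateProfile(syntheticSeedProfile("detection"), n = 120,
                          seed = 2)
    res <- paste0("MKTSSLF", acd$residues, "KTEIPVRHE")
    v <- viterbiScore(p, res)
    hit <- list(map = v$map, inserts = v$inserts, envStart = v$envStart,
                envEnd = v$envEnd)
    a <- sliceRegions(res, hit, p)
    expect_equal(a$acdLen, 83L)
    expect_equal(unname(a$zoneLengths), c(38L, 14L, 31L))
})

test_that("boundary insertions are assigned to the preceding zone", {
    p <- toyProfile(matrix(rep(0.05, 80), 4, 20),
                    landmarks = c("b2", "b5", "L57", "b9"))
    # 2-residue insert between column 2 (end of b2b5) and column 3 (L57)
    hit <- list(map = c(1L, 2L, 5L, 6L),
                inserts = c(0L, 0L, 2L, 0L, 0L),
                envStart = 1L, envEnd = 6L)
    a <- sliceRegions("AAWWAA", hit, p)
    expect_equal(unname(a$zoneLengths), c(4L, 1L, 1L))
    # deletions contribute zero length
    hit2 <- list(map = c(1L, 2L, NA, 3L), inserts = integer(5),
                 envStart = 1L, envEnd = 3L)
    a2 <- sliceRegions("AAA", hit2, p)
    expect_equal(unname(a2$zoneLengths), c(2L, 0L, 1L))
    expect_equal(a2$flaggedZones, "L57")
})

test_that("motif search is leftmost and pattern-correct", {
    expect_equal(unname(findCtermMotif("KTIPVSREEK")), c(3L, 5L))
    expect_null(findCtermMotif("AAAAA"))
    expect_equal(unname(findCtermMotif("IEIAIPI")), c(1L, 3L))
    # basic motif excludes leucine flanks
    expect_null(findCtermMotif("LELAA", extended = FALSE))
    expect_equal(unname(findCtermMotif("LELAA", extended = TRUE)),
                 c(1L, 3L))
    expect_null(findCtermMotif(""))
})

test_that("CAM spans from the ACD end to the motif end", {
    cam <- delineateCam(140L, c(start = 12L, end = 14L), 200L)
    expect_equal(cam$camLen, 14L)
    expect_equal(unname(cam$cam), c(141L, 154L))
    expect_equal(cam$tailLen, 46L)
    # motif ending on the last residue: empty tail
    cam2 <- delineateCam(140L, c(start = 58L, end = 60L), 200L)
    expect_equal(cam2$tailLen, 0L)
    expect_null(cam2$tail)
    cam3 <- delineateCam(140L, NULL, 200L)
    expect_true(is.na(cam3$camLen))
    expect_null(cam3$cam)
})

test_that("hydropathy is the mean Kyte-Doolittle index", {
    expect_equal(hydropathyScore("III"), 4.5)
    expect_equal(hydropathyScore("RRRR"), -4.5)
    expect_equal(hydropathyScore("IR"), 0)
    expect_equal(hydropathyScore("IXI"), 3)   # X contributes 0
    expect_error(hydropathyScore(""), "empty")
})

test_that("architecture invariants hold across a synthetic cohort", {
    samp <- syntheticSeedProfile("sampling")
    ds <- generateDataset(samp, synthesisParams(nPositives = 25L,
                                                nDecoys = 0L, seed = 123L))
    p <- calibrateProfile(syntheticSeedProfile("detection"), seed = 6)
    hits <- scanBank(p, ds$bank, 1e-5)
    expect_equal(nrow(hits), 25L)
    arch <- annotateArchitecture(hits, ds$bank, p)
    # region-length conservation for every record
    cterm <- ifelse(is.na(arch$cam_len), arch$L - arch$acd_end,
                    arch$cam_len + arch$tail_len)
    expect_true(all(arch$nterm_len + arch$acd_len + cterm == arch$L))
    # zone-length additivity
    expect_true(all(arch$b2b5_len + arch$l57_len + arch$b7b9_len ==
                    arch$acd_len))
    # exact CAM recovery under the leftmost-motif construction
    i <- match(arch$accession, ds$truth$accession)
    expect_true(all(arch$cam_len == ds$truth$cam_len[i]))
    # charged L57 loop is more hydrophilic than the strand-rich b2b5 zone
    expect_lt(mean(arch$hydropathy_l57), mean(arch$hydropathy_b2b5))
})

test_that("BED export converts to 0-based half-open coordinates", {
    cc <- .constructedCase()
    hits <- makeHits("r1", list(cc$hit$map), starts = 55, ends = 140,
                     inserts = list(cc$hit$inserts))
    bank <- bankFromStrings(c(r1 = cc$res))
    arch <- annotateArchitecture(hits, bank, cc$p)
    bed <- architectureToBed(arch)
    acd <- bed[bed$region == "acd", ]
    expect_equal(acd$start, 54L)
    expect_equal(acd$end, 140L)
    nt <- bed[bed$region == "nterm", ]
    expect_equal(nt$start, 0L)
    expect_equal(nt$end, 54L)
})
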