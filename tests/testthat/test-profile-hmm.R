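# Profile construction and glocal scoring.

test_that("match columns follow the gap-fraction rule", {
    aln <- AcdAlignment(c(a = "AC-", b = "A-G", c = "ACG"))
    expect_equal(determineMatchColumns(aln, 0.5), c(TRUE, TRUE, TRUE))
    aln2 <- AcdAlignment(c(a = "A-", b = "A-", c = "AG"))
    expect_equal(determineMatchColumns(aln2, 0.5), c(TRUE, FALSE))
    aln3 <- AcdAlignment(c(a = "-", b = "-"))
    expect_error(determineMatchColumns(aln3, 0.5), "no column")
})

test_that("emission pseudocounts follow the background-mixture formula", {
    aln <- AcdAlignment(c(a = "AA", b = "AA"))
    ann <- SeedAnnotation(c("b2", "b2"))
    # weight -> 0 limit: pure observed frequencies
    p0 <- buildProfile(aln, ann, pseudocountWeight = 1e-9,
                       background = backgroundFrequencies("uniform"))
    expect_equal(unname(matchEmissions(p0)[1, "A"]), 1, tolerance = 1e-8)
    # uniform background, weight 20: (2 + 20 * 0.05) / (2 + 20)
    p <- buildProfile(aln, ann,
                      background = backgroundFrequencies("uniform"))
    expect_equal(unname(matchEmissions(p)[1, "A"]), 3 / 22)
    expect_equal(unname(matchEmissions(p)[1, "C"]), 1 / 22)
    expect_equal(profileLength(p), 2L)
    expect_true(validObject(p))
})

test_that("insert-masked columns surface as match-to-insert transitions", {
    # column 2 is gapped in 2 of 3 rows -> insert column; M = 1
    aln <- AcdAlignment(c(a = "A-", b = "A-", c = "AG"))
    ann <- SeedAnnotation(c("b2", NA))
    p <- buildProfile(aln, ann,
                      background = backgroundFrequencies("uniform"))
    expect_equal(profileLength(p), 1L)
    # observed I-state usage after the only column: M->I > M->D (which is
    # structurally impossible past the last column)
    expect_gt(p@tMI[2], p@tMD[2])
    expect_equal(p@tMD[2], 0)
    # row paths: two of three rows exit directly
    expect_gt(p@tMM[2], p@tMI[2])
})

test_that("landmarks propagate through the match-column mask", {
    # col 3 is gap-majority -> insert column; its label is dropped with it
    aln <- AcdAlignment(c(a = "AC-G", b = "AC-G", c = "ACTG"))
    ann <- SeedAnnotation(c("b2", "b2", "b2", "L23"))
    p <- buildProfile(aln, ann)
    expect_equal(landmarks(p), c("b2", "b2", "L23"))
    # leading unlabelled columns inherit the first label
    aln2 <- AcdAlignment(c(a = "ACTG", b = "ACTG"))
    ann2 <- SeedAnnotation(c(NA, "b2", "b2", "L23"))
    p2 <- buildProfile(aln2, ann2)
    expect_equal(landmarks(p2), c("b2", "b2", "b2", "L23"))
})

test_that("single-path toys give closed-form scores", {
    em <- matrix(c(1, rep(0, 19)), 1, 20, byrow = TRUE)
    p <- toyProfile(em)
    v <- viterbiScore(p, "A")
    expect_equal(v$score, log2(20))
    expect_equal(v$map, 1L)
    expect_equal(forwardScore(p, "A"), log2(20))
    # glocal: envelope found inside flanks, X scores as background
    v2 <- viterbiScore(p, "CXAWC")
    expect_equal(v2$score, log2(20))
    expect_equal(v2$envStart, 3L)
    expect_equal(v2$envEnd, 3L)
})

test_that("DP scores match brute-force path enumeration on tiny models", {
    set.seed(11)
    for (rep in 1:40) {
        M <- sample(1:3, 1)
        p <- randomTinyProfile(M)
        s <- randomResidues(sample(1:6, 1))
        oracle <- enumerateGlocal(p, s)
        v <- viterbiScore(p, s)
        expect_equal(v$score, oracle$viterbi, tolerance = 1e-9)
        expect_equal(forwardScore(p, s), oracle$forward,
                     tolerance = 1e-9)
        expect_gte(forwardScore(p, s) - v$score, -1e-9)
    }
})

test_that("Viterbi traceback agrees with the enumerated argmax path", {
    set.seed(12)
    for (rep in 1:20) {
        M <- sample(2:3, 1)
        p <- randomTinyProfile(M)
        s <- randomResidues(sample(3:6, 1))
        oracle <- enumerateGlocal(p, s)
        v <- viterbiScore(p, s)
        # unique argmax only (continuous scores: ties are accidental)
        near <- sum(abs(oracle$scores - oracle$viterbi) < 1e-12)
        if (near == 1) {
            mp <- v$map; mp[is.na(mp)] <- 0L
            expect_equal(mp, oracle$bestMap)
        }
    }
})

test_that("profile-consistent sequences outscore their reversals", {
    p <- calibrateProfile(syntheticSeedProfile("detection"), seed = 3)
    samp <- syntheticSeedProfile("sampling")
    set.seed(21)
    for (rep in 1:20) {
        s <- sampleAcd(samp)$residues
        rev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
        expect_gte(viterbiScore(p, s)$score, viterbiScore(p, rev)$score)
    }
})

test_that("column maps satisfy the envelope bookkeeping invariant", {
    p <- calibrateProfile(syntheticSeedProfile("detection"), seed = 3)
    ds <- generateDataset(syntheticSeedProfile("sampling"),
                          synthesisParams(nPositives = 10L, nDecoys = 0L,
                                          seed = 99L))
    hits <- scanBank(p, ds$bank, 1e-3)
    expect_gt(nrow(hits), 0)
    for (r in seq_len(nrow(hits))) {
        map <- as.integer(hits$columnMap[[r]])
        matched <- map[!is.na(map) & map > 0]
        expect_true(all(diff(matched) > 0))
        nIns <- sum(as.integer(hits$insertCounts[[r]]))
        expect_equal(hits$acdEnd[r] - hits$acdStart[r] + 1L,
                     length(matched) + nIns)
    }
})

test_that("calibration is deterministic and rejects degenerate input", {
    p <- syntheticSeedProfile("detection")
    c1 <- calibrateProfile(p, n = 120, seed = 7)
    c2 <- calibrateProfile(p, n = 120, seed = 7)
    expect_identical(calibration(c1)@mu, calibration(c2)@mu)
    expect_identical(calibration(c1)@lambda, calibration(c2)@lambda)
    expect_error(calibrateProfile(p, n = 99), ">= 100")
    expect_error(fitGumbel(rep(1, 500)), "degenerate")
})

test_that("E-values follow the Gumbel tail formula and monotonicity", {
    fit <- new("GumbelFit", mu = 10, lambda = 0.7, nSamples = 1000L,
               sampleLength = 150L, seed = 1L)
    expect_equal(eValue(10, fit, 1000), 1000 * (1 - exp(-1)))
    expect_equal(eValue(20, fit, 1000),
                 1000 * (1 - exp(-exp(-7))))
    sc <- seq(-20, 60, by = 0.5)
    ev <- eValue(sc, fit, 1000)
    expect_true(all(diff(ev) <= 0))
    # strictly decreasing away from the double-precision saturation at
    # both ends of the tail
    expect_true(all(diff(ev[sc >= 5 & sc <= 35]) < 0))
    expect_lt(eValue(200, fit, 1000), 1e-12)
})

test_that("scan keeps planted sequences and rejects background decoys", {
    samp <- syntheticSeedProfile("sampling")
    p <- calibrateProfile(syntheticSeedProfile("detection"), seed = 5)
    set.seed(31)
    pos <- vapply(1:5, function(i) sampleAcd(samp)$residues, character(1))
    dec <- vapply(1:5, function(i) randomResidues(120), character(1))
    bank <- bankFromStrings(setNames(c(pos, dec),
                                     c(paste0("P", 1:5), paste0("D", 1:5))))
    hits <- scanBank(p, bank, 1e-3)
    expect_setequal(hits$accession, paste0("P", 1:5))
    # decoys really are above threshold
    for (d in paste0("D", 1:5)) {
        sc <- viterbiScore(p, bankResidues(bank, d))$score
        expect_gt(eValue(sc, calibration(p), 10), 1e-3)
    }
    expect_equal(nrow(scanBank(p, bankFromStrings(c(A = "MKT"))[0], 1e-3)),
                 0L)
    expect_equal(nrow(scanBank(p, bank, 0)), 0L)
    expect_error(scanBank(syntheticSeedProfile("detection"), bank, 1e-3),
                 "not calibrated")
})

test_that("the seed's own sequences are recovered at E <= 1e-3", {
    s <- syntheticSeedAlignment()
    p <- calibrateProfile(buildProfile(s$alignment, s$annotation),
                          seed = 13)
    rows <- gsub("[-.]", "", alignedSequences(s$alignment))
    bank <- bankFromStrings(rows)
    hits <- scanBank(p, bank, 1e-3)
    expect_setequal(hits$accession, names(rows))
    expect_true(all(hits$eValue <= 1e-3))
})

test_that("profiles survive a serialisation round trip", {
    p <- calibrateProfile(syntheticSeedProfile("detection"), n = 120,
                          seed = 2)
    f <- withr::local_tempfile(fileext = ".json")
    writeProfileHMM(p, f)
    q <- readProfileHMM(f)
    expect_equal(matchEmissions(q), matchEmissions(p), tolerance = 1e-12)
    expect_equal(landmarks(q), landmarks(p))
    expect_equal(q@tMM, p@tMM, tolerance = 1e-12)
    expect_equal(calibration(q)@lambda, calibration(p)@lambda,
                 tolerance = 1e-12)
    s <- sampleAcd(syntheticSeedProfile("sampling"), seed = 4)$residues
    expect_equal(viterbiScore(q, s)$score, viterbiScore(p, s)$score,
                 tolerance = 1e-9)
})
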