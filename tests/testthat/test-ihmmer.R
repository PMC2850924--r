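# Iterative enrichment loop and curation.

test_that("length filtering keeps envelopes at or below the cap", {
    hits <- makeHits(c("a", "b", "c"),
                     maps = list(1L, 1L, 1L),
                     starts = c(1, 1, 1), ends = c(90, 101, 100))
    kept <- filterHits(hits, 100)
    expect_setequal(kept$accession, c("a", "c"))
    expect_equal(nrow(filterHits(hits[0, ], 100)), 0L)
    expect_warning(filterHits(hits, 10), "exceed the ACD length cap")
})

test_that("hit realignment reproduces profile columns and inserts", {
    p <- calibrateProfile(syntheticSeedProfile("detection"), n = 120,
                          seed = 2)
    M <- profileLength(p)
    bank <- bankFromStrings(c(
        h1 = sampleAcd(syntheticSeedProfile("sampling"), seed = 1)$residues,
        h2 = sampleAcd(syntheticSeedProfile("sampling"), seed = 2)$residues))
    hits <- scanBank(p, bank, 1e-3)
    expect_equal(nrow(hits), 2L)
    re <- hitsToAlignment(p, hits, bank)
    # gap-free column maps: exactly M columns, rows are the ACD envelopes
    expect_equal(nColumns(re$alignment), M)
    expect_equal(length(elementOfColumn(re$annotation)), M)
    # rebuilding from the realignment reproduces M (round trip)
    p2 <- buildProfile(re$alignment, re$annotation)
    expect_equal(profileLength(p2), M)
    expect_equal(landmarks(p2), landmarks(p))
})

test_that("insert envelopes open dedicated lowercase insert columns", {
    # M = 2 profile; plant a 2-residue insert between the columns of one
    # hit by constructing the column maps directly
    p <- toyProfile(matrix(rep(0.05, 40), 2, 20))
    bank <- bankFromStrings(c(h1 = "AC", h2 = "AWWC"))
    hits <- makeHits(c("h1", "h2"),
                     maps = list(c(1L, 2L), c(1L, 4L)),
                     inserts = list(c(0L, 0L, 0L), c(0L, 2L, 0L)))
    re <- hitsToAlignment(p, hits, bank)
    rows <- alignedSequences(re$alignment)
    expect_equal(unname(rows["h1"]), "A..C")
    expect_equal(unname(rows["h2"]), "AwwC")
    expect_equal(elementOfColumn(re$annotation),
                 c("b2", "b2", "b2", "b2"))
    expect_error(hitsToAlignment(p, makeHits("nope", list(c(1L, 2L))),
                                 bank), "unknown accession")
})

test_that("a start=end configuration runs a single enrichment iteration", {
    s <- syntheticSeedAlignment()
    ds <- generateDataset(syntheticSeedProfile("sampling"),
                          synthesisParams(nPositives = 12L, nDecoys = 8L,
                                          seed = 7L))
    cfg <- iterationConfig(startExponent = -6L, endExponent = -6L,
                           finalExponent = -6L)
    run <- iterateProfile(s$alignment, s$annotation, ds$bank,
                          config = cfg, seed = 5L, calibrationN = 120L)
    expect_equal(nrow(run$trace), 1L)
    expect_equal(run$trace$exponent, -6L)
    expect_equal(run$finalPass$threshold, 1e-6)
})

test_that("reruns with the same seed give identical traces", {
    s <- syntheticSeedAlignment()
    ds <- generateDataset(syntheticSeedProfile("sampling"),
                          synthesisParams(nPositives = 10L, nDecoys = 5L,
                                          seed = 9L))
    cfg <- iterationConfig(startExponent = -8L, endExponent = -6L)
    r1 <- iterateProfile(s$alignment, s$annotation, ds$bank, config = cfg,
                         seed = 17L, calibrationN = 120L)
    r2 <- iterateProfile(s$alignment, s$annotation, ds$bank, config = cfg,
                         seed = 17L, calibrationN = 120L)
    expect_identical(r1$trace$checksum, r2$trace$checksum)
    expect_identical(r1$trace$nHits, r2$trace$nHits)
    expect_identical(r1$hits$bitScore, r2$hits$bitScore)
    # thresholds relax by exactly one order of magnitude per iteration
    expect_equal(diff(r1$trace$exponent), rep(1L, nrow(r1$trace) - 1))
})

test_that("an empty first iteration aborts with a diagnostic", {
    s <- syntheticSeedAlignment()
    set.seed(4)
    bank <- bankFromStrings(setNames(
        vapply(1:6, function(i) randomResidues(150), character(1)),
        paste0("D", 1:6)))
    expect_error(
        iterateProfile(s$alignment, s$annotation, bank,
                       config = iterationConfig(), seed = 1L,
                       calibrationN = 120L),
        "no hits at the first iteration")
})

test_that("curation applies the fragment / existence / single-ACD rules", {
    bank <- bankFromStrings(
        c(a = "MKT", b = "MKT", c = "MKT", d = "MKT", e = "MKT"),
        fragment = c(TRUE, FALSE, FALSE, FALSE, FALSE),
        existence = c(1L, 3L, 4L, 2L, 2L))
    hits <- makeHits(c("a", "b", "c", "d", "e"),
                     maps = rep(list(1L), 5),
                     multi = c(FALSE, FALSE, FALSE, TRUE, FALSE))
    cur <- curateHits(hits, bank)
    # a: fragment; c: existence 4; d: two ACDs; b (level 3) and e stay
    expect_setequal(cur$accession, c("b", "e"))
    expect_true(all(cur$accession %in% hits$accession))
})

test_that("multi-ACD records are flagged by the masked rescan", {
    samp <- syntheticSeedProfile("sampling")
    p <- calibrateProfile(syntheticSeedProfile("detection"), n = 120,
                          seed = 2)
    one <- sampleAcd(samp, seed = 11)$residues
    two <- paste0(one, "GSGSGSGS", sampleAcd(samp, seed = 12)$residues)
    bank <- bankFromStrings(c(single = one, tandem = two))
    hits <- scanBank(p, bank, 1e-4, flagMultiAcd = TRUE)
    expect_false(hits$multiAcd[hits$accession == "single"])
    expect_true(hits$multiAcd[hits$accession == "tandem"])
})
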