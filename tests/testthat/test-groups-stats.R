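# Taxonomic grouping, global alignment, logos, distributions, overlap.

test_that("lineages map onto the taxonomic groups", {
    expect_equal(assignTaxonomicGroup(c("Eukaryota", "Metazoa",
                                        "Chordata")), "animals")
    expect_equal(assignTaxonomicGroup(c("Eukaryota", "Viridiplantae")),
                 "plants")
    expect_equal(assignTaxonomicGroup(c("Eukaryota", "Fungi")), "fungi")
    expect_equal(assignTaxonomicGroup("Archaea"), "archaea")
    expect_equal(assignTaxonomicGroup(c("Bacteria", "Proteobacteria")),
                 "bacteria_pending")
    expect_equal(assignTaxonomicGroup(c("Eukaryota", "Alveolata")),
                 "other")
    expect_equal(assignTaxonomicGroup(character(0)), "other")
})

test_that("global alignment scores match exhaustive enumeration", {
    S <- blosum62()
    set.seed(41)
    for (rep in 1:25) {
        a <- paste(sample(c("A", "C", "D", "E"), sample(1:4, 1), TRUE),
                   collapse = "")
        b <- paste(sample(c("A", "C", "D", "E"), sample(1:4, 1), TRUE),
                   collapse = "")
        expect_equal(needlemanWunsch(a, b)$score,
                     nwBruteForce(a, b, S, 10, 1),
                     info = paste(a, b))
    }
})

test_that("alignment identity and symmetry behave as specified", {
    expect_equal(needlemanWunsch("ACDEFG", "ACDEFG")$identity, 100)
    nw1 <- needlemanWunsch("MKTAYIAK", "MKTAYIAR")
    nw2 <- needlemanWunsch("MKTAYIAR", "MKTAYIAK")
    expect_equal(nw1$score, nw2$score)
    expect_equal(nw1$identity, 7 / 8 * 100)
    # identity denominator counts gap columns
    nw3 <- needlemanWunsch("ACDE", "ACE")
    expect_equal(nw3$identity, 3 / 4 * 100)
})

test_that("bacterial classification follows best identity with ties out", {
    refs <- readBacterialRefs()
    expect_equal(classifyBacterial(refs$refsA[[1]], refs$refsA,
                                   refs$refsB), "bacA")
    expect_equal(classifyBacterial(refs$refsB[[2]], refs$refsA,
                                   refs$refsB), "bacB")
    set.seed(51)
    rnd <- randomResidues(140)
    idA <- max(needlemanWunsch(unname(refs$refsA), rnd)$identity)
    idB <- max(needlemanWunsch(unname(refs$refsB), rnd)$identity)
    expect_lt(max(idA, idB), 40)
    expect_equal(classifyBacterial(rnd, refs$refsA, refs$refsB),
                 "bacOther")
    # tie rule: identical best identities on both sides
    expect_equal(classifyBacterial("MKTA", c(x = "MKTA"), c(y = "MKTA")),
                 "bacOther")
    expect_error(classifyBacterial("MKTA", character(0), c(y = "MKTA")),
                 "non-empty")
})

test_that("whole-bank grouping resolves bacteria through references", {
    refs <- readBacterialRefs()
    bank <- bankFromStrings(
        c(an = "MKT", pl = "MKT", ba = refs$refsA[[2]], bo = "MKTWWHH"),
        lineage = list(c("Eukaryota", "Metazoa"),
                       c("Eukaryota", "Viridiplantae"),
                       c("Bacteria"), c("Bacteria")))
    g <- assignGroups(bank, refs$refsA, refs$refsB)
    expect_equal(unname(g), c("animals", "plants", "bacA", "bacOther"))
    expect_true(all(g[c("ba", "bo")] %in% c("bacA", "bacB", "bacOther")))
})

test_that("logo information content matches the closed forms", {
    p1 <- toyProfile(matrix(rep(0.05, 20), 1, 20))
    # 10 observations of I in a single column
    bankI <- bankFromStrings(setNames(rep("I", 10), paste0("s", 1:10)))
    hitsI <- makeHits(paste0("s", 1:10), rep(list(1L), 10))
    logoI <- logoCounts(hitsI, bankI, p1)
    expect_equal(logoI@info[1], log2(21))
    expect_equal(unname(logoI@heights[1, "I"]), log2(21))
    expect_equal(sum(logoI@heights[1, setdiff(colnames(logoI@heights),
                                              "I")]), 0)

    # uniform over all 21 symbols: 20 residues + one deletion
    res <- aminoAcids()
    bankU <- bankFromStrings(setNames(res, paste0("u", 1:20)))
    maps <- c(rep(list(1L), 20), list(NA_integer_))
    hitsU <- makeHits(c(paste0("u", 1:20), "u21"), maps,
                      starts = rep(1, 21), ends = rep(1, 21))
    bankU2 <- bankFromStrings(c(setNames(res, paste0("u", 1:20)),
                                u21 = "A"))
    logoU <- logoCounts(hitsU, bankU2, p1)
    expect_equal(logoU@info[1], 0, tolerance = 1e-12)

    # half gap / half A: drawn height of A is 0.5 * (log2(21) - 1)
    acc <- paste0("h", 1:10)
    hitsH <- makeHits(acc, c(rep(list(1L), 5),
                             rep(list(NA_integer_), 5)),
                      starts = rep(1, 10), ends = rep(1, 10))
    bankH <- bankFromStrings(setNames(rep("A", 10), acc))
    logoH <- logoCounts(hitsH, bankH, p1)
    expect_equal(logoH@info[1], log2(21) - 1)
    expect_equal(unname(logoH@heights[1, "A"]), 0.5 * (log2(21) - 1),
                 tolerance = 1e-6)
})

test_that("reinforcing the modal symbol never lowers information", {
    p1 <- toyProfile(matrix(rep(0.05, 20), 1, 20))
    set.seed(61)
    for (rep in 1:10) {
        n <- sample(3:12, 1)
        res <- sample(aminoAcids(), n, TRUE)
        acc <- paste0("s", seq_len(n))
        logo0 <- logoCounts(makeHits(acc, rep(list(1L), n)),
                            bankFromStrings(setNames(res, acc)), p1)
        modal <- aminoAcids()[which.max(logo0@counts[1, 1:20])]
        acc2 <- c(acc, "extra")
        logo1 <- logoCounts(makeHits(acc2, rep(list(1L), n + 1)),
                            bankFromStrings(setNames(c(res, modal),
                                                     acc2)), p1)
        expect_gte(logo1@info[1], logo0@info[1] - 1e-12)
    }
})

test_that("zero-observation columns are flagged, bounds respected", {
    p2 <- toyProfile(matrix(rep(0.05, 40), 2, 20))
    hits <- makeHits("s1", list(c(1L, NA_integer_)), starts = 1,
                     ends = 1, inserts = list(integer(3)))
    bank <- bankFromStrings(c(s1 = "F"))
    logo <- logoCounts(hits, bank, p2)
    # a deleted column still counts (gap symbol): info defined everywhere
    expect_false(anyNA(logo@info))
    expect_true(all(logo@info <= log2(21) + 1e-12))
    expect_true(all(logo@info >= -1e-12))
    # with no hits at all, information is undefined and flagged
    expect_warning(logo0 <- logoCounts(hits[0, ], bank, p2),
                   "zero observations")
    expect_true(all(is.na(logo0@info)))
})

test_that("length distributions summarise counts, mode and fractions", {
    d <- lengthDistribution(c(83, 83, 90))
    expect_equal(d$mode, 83L)
    expect_equal(d$mean, 256 / 3)
    expect_equal(d$histogram$count[d$histogram$length == 83], 2L)
    d2 <- lengthDistribution(c(80, 85, 101), interval = c(82, 100))
    expect_equal(d2$fraction, 1 / 3)
    d3 <- lengthDistribution(integer(0))
    expect_equal(d3$n, 0L)
    expect_equal(nrow(d3$histogram), 0L)
    expect_error(lengthDistribution(c(-1, 3)), "non-negative")
})

test_that("annotation overlap is the recovered fraction of labels", {
    labeled <- paste0("u", 1:100)
    detected <- c(paste0("u", 1:95), paste0("x", 1:50))
    expect_equal(annotationOverlap(detected, labeled), 95)
    expect_equal(annotationOverlap("a", c("b", "c")), 0)
    expect_equal(annotationOverlap(c("a", "b", "c"), c("a", "b")), 100)
    expect_error(annotationOverlap("a", character(0)), "empty")
})
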