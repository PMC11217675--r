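test_that("GpC and CC+GG frequencies match hand counts", {
  expect_equal(gpcFrequency("GCGCGC"), 100 * 3 / 5)
  expect_equal(ccggFrequency("GCGCGC"), 0)
  expect_equal(gpcFrequency("CCCC"), 0)
  expect_equal(ccggFrequency("CCCC"), 100)
  expect_error(gpcFrequency("N"), "no valid")
})

test_that("10 kb equal-composition sequence has F1 near the binomial expectation", {
  s <- randomSeq(10000, seed = 19)
  # expectation 100/16 = 6.25; 4 sigma of the ~1e4-window binomial ~ 0.97
  expect_lt(abs(gpcFrequency(s) - 6.25), 1)
})

test_that("the F1/F2 ratio R reproduces the worked arithmetic", {
  expect_equal(ratioR(10, 20), 100)
  expect_equal(round(ratioR(13.33, 11.9), 2), 224.03)
  expect_equal(ratioR(0, 5), 0)
  expect_warning(r <- ratioR(3, 0), "undefined")
  expect_true(is.na(r))
})

test_that("the L4/L3 spacing ratio handles signal, balance and sentinel cases", {
  # an isolated planted L4 occurrence with no L3 occurrence -> undefined
  expect_true(is.na(l4l3Ratio(paste0(strrep("A", 20), "TACCGC", strrep("A", 20)))))
  # engineered sequence with exactly one L3 and one L4 occurrence
  s <- "TAGCAAAAAATAGGCA"
  expect_identical(oracleF3(s), 100)
  expect_equal(l4l3Ratio(s), 100)
  withr::with_seed(23, {
    for (i in 1:20) {
      s <- randomSeq(sample(200:600, 1))
      expect_equal(l4l3Ratio(s), oracleF3(s))
    }
  })
})

test_that("triplet and pair frequencies match hand counts and the oracle", {
  expect_equal(gcTripletFrequency("GGGG"), 100) # GGG twice / 2 windows
  expect_equal(atTripletFrequency("TTAA"), 100) # TTA, TAA / 2 windows
  expect_equal(adjacentPairFrequency("AATT"), 100)
  expect_equal(oneSpacerPairFrequency("ACAGC"), 100)
  withr::with_seed(29, {
    s <- randomSeq(5000)
    o <- oracleFeatures(s)
    expect_equal(gcTripletFrequency(s), unname(o["F4"]))
    expect_equal(atTripletFrequency(s), unname(o["F5"]))
    expect_equal(adjacentPairFrequency(s), unname(o["F6"]))
    expect_equal(oneSpacerPairFrequency(s), unname(o["F7"]))
  })
})

test_that("alternating/homotype ratio covers the degenerate denominator", {
  expect_equal(altDinucleotideRatio("AGAGAG"), 0)
  expect_equal(altDinucleotideRatio("ACAG"), 2) # (AC + CA) / AG
  expect_true(is.na(altDinucleotideRatio("ACAC")))
})

test_that("GC content is case-insensitive, N-excluding and bounded", {
  expect_equal(gcContent("GCGC"), 100)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("ACGT"), 50)
  expect_equal(gcContent("acgtNN"), 50)
  expect_error(gcContent("NNN"), "no A/C/G/T")
})

test_that("computeFeatures is deterministic and equals its components", {
  s <- randomSeq(300, seed = 31)
  v1 <- computeFeatures(s)
  v2 <- computeFeatures(s)
  expect_identical(v1, v2)
  expect_equal(v1[["F1"]], gpcFrequency(s))
  expect_equal(v1[["F3"]], l4l3Ratio(s))
  expect_equal(v1[["F9"]], gcContent(s))
  expect_error(computeFeatures(randomSeq(100, seed = 1)), "below the minimum")
  expect_silent(computeFeatures(randomSeq(100, seed = 1), minLength = 50))
})

test_that("every feature is invariant to residue case", {
  s <- randomSeq(400, seed = 37)
  lower <- tolower(s)
  mixed <- paste0(substr(s, 1, 200), tolower(substr(s, 201, 400)))
  expect_identical(computeFeatures(s), computeFeatures(lower))
  expect_identical(computeFeatures(s), computeFeatures(mixed))
})

test_that("GC content is exactly preserved by dinucleotide-preserving shuffles", {
  withr::with_seed(41, {
    for (i in 1:10) {
      s <- randomSeq(300)
      expect_identical(gcContent(s), gcContent(dinucleotideShuffle(s, seed = i)))
    }
  })
})

test_that("feature tables are labelled, sentinel-filled and TSV round-trippable", {
  withr::with_seed(43, {
    pos <- setNames(vapply(1:5, function(i) randomSeq(250), ""), paste0("p", 1:5))
    neg <- setNames(vapply(1:5, function(i) randomSeq(250), ""), paste0("n", 1:5))
  })
  tab <- buildFeatureTable(pos, neg)
  expect_identical(names(tab), c("ID", paste0("F", 1:9), "Class"))
  expect_identical(tab$Class, rep(c(1L, 0L), each = 5))
  expect_false(anyNA(tab[paste0("F", 1:9)]))
  expect_error(buildFeatureTable(pos, character(0)), "non-empty")
  expect_error(buildFeatureTable(pos, pos), "duplicate")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(tab, f)
  back <- readFeatureTable(f)
  expect_equal(back, tab, ignore_attr = TRUE)
})

test_that("undefined ratios are replaced by the column maximum with a warning", {
  # one planted L4 occurrence (TAnnGC), zero L3 occurrences -> F3 undefined
  pos <- c(p1 = paste0(strrep("A", 50), "TACCGC", strrep("A", 50)))
  neg <- c(n1 = randomSeq(300, seed = 47), n2 = randomSeq(300, seed = 48))
  # the poly-A fixture has no homotype dinucleotide either, so both the F3
  # and the F8 sentinel paths fire
  warns <- capture_warnings(tab <- buildFeatureTable(pos, neg, minLength = 50))
  expect_match(warns, "undefined F3", all = FALSE)
  expect_match(warns, "undefined F8", all = FALSE)
  expect_equal(tab$F3[1], max(tab$F3[2:3]))
  expect_equal(tab$F8[1], max(tab$F8[2:3]))
})

test_that("single-feature prediction power matches the exhaustive threshold oracle", {
  expect_equal(singleFeaturePower(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # brute force over cuts and both directions gives 0.75 for alternating labels
  expect_equal(singleFeaturePower(c(1, 2, 3, 4), c(1, 0, 1, 0)), 0.75)
  expect_equal(singleFeaturePower(c(5, 5, 1, 1), c(1, 1, 0, 0)), 1)
  expect_error(singleFeaturePower(1:4, c(1, 1, 1, 1)), "both classes")
  # labels independent of values: power ~ class prior at large n
  withr::with_seed(53, {
    v <- runif(2000)
    l <- rep(0:1, 1000)
    expect_lt(singleFeaturePower(v, l), 0.56)
  })
  # agrees with a naive O(n^2) scan on small random cases
  withr::with_seed(59, {
    for (i in 1:20) {
      v <- sample(1:8, 12, replace = TRUE)
      l <- sample(0:1, 12, replace = TRUE)
      if (length(unique(l)) < 2) next
      cuts <- c(-Inf, sort(unique(v)))
      naive <- max(vapply(cuts, function(t) {
        max(mean((v > t) == l), mean((v <= t) == l))
      }, numeric(1)))
      expect_equal(singleFeaturePower(v, l), naive)
    }
  })
})
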