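# Frozen expected values for the published five-score example are asserted in
# test-acceptance.R; here the remaining worked cases, edge cases and the
# method-specific invariants.

test_that("empiricalQuantile selects the ceil(q*n)-th ascending element", {
    expect_equal(empiricalQuantile(c(2, 4, 4, 8, 12), 0.8), 8)
    expect_equal(empiricalQuantile(5, 0.1), 5)
    expect_equal(empiricalQuantile(5, 1), 5)
    expect_equal(empiricalQuantile(c(1, 2, 3, 4), 1.0), 4)
    expect_equal(empiricalQuantile(c(3, 1, 2), 1 / 3), 1)  # unsorted input
    expect_error(empiricalQuantile(numeric(), 0.5), "empty")
    expect_error(empiricalQuantile(1:3, 0), "in \\(0, 1\\]")
})

test_that("normal normalization standardizes, shifts, scales and rounds up", {
    x <- makeCallerPeaks("pf", c(0, 100, 200), c(50, 150, 250), c(1, 2, 3))
    # mean 2, sample sd 1, shift 3, max 3: ((s-2)/1 + 3) * 3 = 6, 9, 12
    expect_equal(scores(normalizePeaks(x, "normal", maxNoOfPeaks = 3)),
                 c(6, 9, 12))
    # non-integer results round up
    y <- makeCallerPeaks("pf", c(0, 100), c(50, 150), c(1, 2))
    # mean 1.5, sd ~0.7071: z = -/+ 0.7071; (z+3)*5 = 11.46.., 18.53..
    expect_equal(scores(normalizePeaks(y, "normal", maxNoOfPeaks = 5)),
                 c(12, 19))
})

test_that("normal normalization truncates deep negative outliers to 0 but keeps the peaks", {
    sc <- c(rep(100, 30), 0)   # the lone 0 sits ~5.4 sample sd below the mean
    x <- makeCallerPeaks("pf", (seq_along(sc) - 1) * 10,
                         (seq_along(sc) - 1) * 10 + 5, sc)
    out <- normalizePeaks(x, "normal", maxNoOfPeaks = 31)
    expect_identical(nPeaks(out), 31L)          # kept for voting
    expect_equal(min(scores(out)), 0)           # truncated, not negative
    expect_true(all(scores(out) >= 0))
    # coordinates and caller untouched
    expect_identical(regionCoords(granges(out)), regionCoords(granges(x)))
    expect_identical(caller(out), "pf")
})

test_that("normal normalization with zero spread warns and maps to ceil(shift*max)", {
    x <- makeCallerPeaks("pf", c(0, 100), c(50, 150), c(7, 7))
    expect_warning(out <- normalizePeaks(x, "normal", maxNoOfPeaks = 10),
                   "identical")
    expect_equal(scores(out), c(30, 30))
})

test_that("naive quantile normalization divides by the chosen quantile and rounds up", {
    allEq <- makeCallerPeaks("pf", c(0, 100, 200), c(50, 150, 250),
                             c(5, 5, 5))
    expect_equal(scores(normalizePeaks(allEq, "naive_quantile",
                                       maxNoOfPeaks = 7, quantile = 0.4)),
                 c(7, 7, 7))
    single <- makeCallerPeaks("pf", 0, 50, 4)
    expect_equal(scores(normalizePeaks(single, "naive_quantile",
                                       maxNoOfPeaks = 2, quantile = 0.5)), 2)
    zeroQ <- makeCallerPeaks("pf", c(0, 100), c(50, 150), c(0, 4))
    expect_error(normalizePeaks(zeroQ, "naive_quantile", maxNoOfPeaks = 2,
                                quantile = 0.5), "quantile value is 0")
})

test_that("average normalization divides by the mean and rounds half-up", {
    x <- makeCallerPeaks("pf", c(0, 100), c(50, 150), c(1, 3))
    expect_equal(scores(normalizePeaks(x, "average", maxNoOfPeaks = 4)),
                 c(2, 6))
    allEq <- makeCallerPeaks("pf", c(0, 100), c(50, 150), c(3, 3))
    expect_equal(scores(normalizePeaks(allEq, "average", maxNoOfPeaks = 9)),
                 c(9, 9))
    zeros <- makeCallerPeaks("pf", c(0, 100), c(50, 150), c(0, 0))
    expect_error(normalizePeaks(zeros, "average", maxNoOfPeaks = 2),
                 "mean score is 0")
})

test_that("rank normalization scores clusters ascending", {
    single <- makeCallerPeaks("pf", 0, 50, 4)
    expect_equal(scores(normalizePeaks(single, "rank", maxNoOfPeaks = 7)),
                 4)   # ceil(7/2)
    x <- makeCallerPeaks("pf", c(0, 100, 200), c(50, 150, 250), c(5, 7, 9))
    # three singleton clusters, max = n = 3: raw 0.5, 1.5, 2.5
    expect_equal(rankScores(c(5, 7, 9), 3, rounded = FALSE),
                 c(0.5, 1.5, 2.5))
    expect_equal(scores(normalizePeaks(x, "rank", maxNoOfPeaks = 3)),
                 c(1, 2, 3))
})

test_that("top rank normalization scores clusters descending from the maximum", {
    single <- makeCallerPeaks("pf", 0, 50, 4)
    expect_equal(scores(normalizePeaks(single, "top_rank",
                                       maxNoOfPeaks = 11)), 11)
    # k tied peaks in one cluster all get max - (k-1)/2
    expect_equal(topRankScores(rep(6, 4), 10, rounded = FALSE),
                 rep(10 - 3 / 2, 4))
    # the top cluster reaches max iff it is a singleton
    expect_equal(max(topRankScores(c(9, 5, 5), 10, rounded = FALSE)), 10)
    expect_lt(max(topRankScores(c(9, 9, 5), 10, rounded = FALSE)), 10)
})

test_that("rank cluster scores match a brute-force cluster enumeration", {
    bruteRank <- function(s, maxN) {
        lev <- sort(unique(s))
        out <- numeric(length(s))
        below <- 0
        for (v in lev) {
            n <- sum(s == v)
            out[s == v] <- (n / 2 + below) * maxN / length(s)
            below <- below + n
        }
        out
    }
    for (seed in 1:25) {
        set.seed(seed)
        s <- sample.int(12L, sample(1:30, 1), replace = TRUE)
        maxN <- length(s) + sample(0:10, 1)
        expect_equal(rankScores(s, maxN, rounded = FALSE), bruteRank(s, maxN))
    }
    # all-distinct scores with n == max: raw ranks are 0.5, 1.5, ..., n-0.5
    s <- sample(100, 20)
    expect_equal(sort(rankScores(s, 20, rounded = FALSE)), seq(20) - 0.5)
})

test_that("normal-normalization truncation frequency matches the gaussian tail", {
    set.seed(42)
    z <- rnorm(1e6, mean = 50, sd = 8)
    z <- pmax(z, 0)   # raw caller scores are non-negative
    norm <- MetaPeaks:::.normalScores(z, normalShift = 3, maxNoOfPeaks = 1000)
    p <- mean(norm == 0)
    se <- sqrt(pnorm(-3) * (1 - pnorm(-3)) / 1e6)
    expect_lt(abs(p - pnorm(-3)), 3 * se)
})

test_that("normalization preserves coordinates, counts and caller identity", {
    x <- sissrExample()
    for (m in c("normal", "naive_quantile", "average", "rank", "top_rank")) {
        out <- normalizePeaks(x, m, maxNoOfPeaks = 10, quantile = 0.8)
        expect_identical(regionCoords(granges(out)),
                         regionCoords(granges(x)))
        expect_identical(caller(out), "sissr")
        expect_identical(nPeaks(out), nPeaks(x))
    }
    expect_error(normalizePeaks(x, "rank", maxNoOfPeaks = 3),
                 "smaller than the caller's own peak count")
})
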