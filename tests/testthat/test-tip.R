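test_that("characteristic profile of constant signal is flat", {
  len <- 2000
  tr <- signal_track(data.frame(chrom = "chr1", start = 0, end = len,
                                value = 2), c(chr1 = len))
  tss <- toy_tss(4, len = len, seed = 2)
  h <- 50
  prof <- characteristic_profile(tr, tss, h = h)
  expect_equal(prof$profile, rep(2, 2 * h + 1))
  expect_equal(prof$weights, rep(1 / (2 * h + 1), 2 * h + 1))
})

test_that("single point of signal lands at the right profile offset", {
  len <- 2000
  pos <- 1000
  h <- 200
  tr <- signal_track(data.frame(chrom = "chr1", start = pos + 100,
                                end = pos + 101, value = 1), c(chr1 = len))
  tss <- as_tss_table(data.frame(chrom = "chr1", pos = pos, strand = "+",
                                 gene_id = "g1", category = "protein_coding"))
  prof <- characteristic_profile(tr, tss, h = h)
  expect_equal(which(prof$profile != 0), h + 1 + 100)
  expect_equal(prof$weights[h + 1 + 100], 1)
  # the same signal for a '-' strand gene appears mirrored (upstream)
  tss$strand <- "-"
  prof2 <- characteristic_profile(tr, tss, h = h)
  expect_equal(which(prof2$profile != 0), h + 1 - 100)
})

test_that("profile averaging equals an independent per-position loop", {
  len <- 3000
  h <- 50
  for (seed in 1:5) {
    iv <- random_intervals(60, len, seed)
    tr <- signal_track(iv, c(chr1 = len))
    tss <- toy_tss(5, len = len, seed = seed + 10)
    flat <- flat_signal(iv, len)
    # oracle: position-by-position averaging over genes on the flat array
    expected <- numeric(2 * h + 1)
    for (k in -h:h) {
      vals <- vapply(seq_len(nrow(tss)), function(i) {
        off <- if (tss$strand[i] == "+") k else -k
        p <- tss$pos[i] + off
        if (p < 0 || p >= len) 0 else flat[p + 1]
      }, 0)
      expected[k + h + 1] <- mean(vals)
    }
    prof <- characteristic_profile(tr, tss, h = h)
    expect_equal(prof$profile, expected, tolerance = 1e-12)
  }
})

test_that("degenerate all-zero profile errors out", {
  tr <- signal_track(data.frame(chrom = "chr1", start = 0, end = 1,
                                value = 0), c(chr1 = 1000))
  expect_error(characteristic_profile(tr, toy_tss(3), h = 20), "degenerate")
})

test_that("regulatory score is the stated weighted sum", {
  len <- 2000
  iv <- random_intervals(40, len, 3)
  tr <- signal_track(iv, c(chr1 = len))
  tss1 <- toy_tss(1, len = len, seed = 4, strand = "+")
  flat <- flat_signal(iv, len)
  h <- 5
  # flat weights: score equals the plain mean of the 11-base window
  prof <- list(h = h, weights = rep(1 / (2 * h + 1), 2 * h + 1))
  class(prof) <- "binding_profile"
  win <- flat[(tss1$pos + 1 - h):(tss1$pos + 1 + h)]
  expect_equal(regulatory_score(prof, tr, tss1), mean(win))
  # point-mass weights: score equals the signal at the TSS base
  prof$weights <- c(rep(0, h), 1, rep(0, h))
  expect_equal(regulatory_score(prof, tr, tss1), flat[tss1$pos + 1])
  # explicit 11-term dot product with stated weights
  w <- c(0.01, 0.02, 0.03, 0.04, 0.1, 0.6, 0.1, 0.04, 0.03, 0.02, 0.01)
  prof$weights <- w
  expect_equal(regulatory_score(prof, tr, tss1),
               w[1] * win[1] + w[2] * win[2] + w[3] * win[3] + w[4] * win[4] +
               w[5] * win[5] + w[6] * win[6] + w[7] * win[7] + w[8] * win[8] +
               w[9] * win[9] + w[10] * win[10] + w[11] * win[11])
})

test_that("batch regulatory scores match the single-record path", {
  len <- 4000
  iv <- random_intervals(80, len, 11)
  tr <- signal_track(iv, c(chr1 = len))
  tss <- toy_tss(6, len = len, seed = 12)
  prof <- characteristic_profile(tr, tss, h = 40)
  batch <- regulatory_scores(prof, tr, tss)
  single <- vapply(seq_len(nrow(tss)), function(i)
    regulatory_score(prof, tr, tss[i, ]), 0)
  expect_equal(unname(batch), single, tolerance = 1e-12)
})

test_that("standardisation gives symmetric z and calibrated null calls", {
  expect_error(standardize_and_call(setNames(rep(2, 5), letters[1:5])),
               "equal")
  s <- standardize_and_call(setNames(c(1, 2, 3), c("a", "b", "c")),
                            q_threshold = 0.01)
  expect_equal(unname(s$z), c(-1, 0, 1))
  expect_equal(unname(s$p["b"]), 0.5)
  # null scores: target count at q < 0.01 stays within false-positive bounds
  set.seed(42)
  null <- standardize_and_call(setNames(rnorm(1000), sprintf("g%04d", 1:1000)),
                               q_threshold = 0.01)
  expect_lte(length(null$targets), 25) # BH controls FDR; expect ~0 calls
})

test_that("average signal matches a brute-force window mean", {
  len <- 3000
  tr <- signal_track(data.frame(chrom = "chr1", start = 0, end = len,
                                value = 3.5), c(chr1 = len))
  tss1 <- toy_tss(1, len = len, seed = 5)
  expect_equal(average_signal(tr, tss1, 100), 3.5)

  # signal on exactly half of the window
  pos <- 1000
  tr2 <- signal_track(data.frame(chrom = "chr1", start = pos, end = pos + 100,
                                 value = 1), c(chr1 = len))
  rec <- as_tss_table(data.frame(chrom = "chr1", pos = pos, strand = "+",
                                 gene_id = "x", category = "protein_coding"))
  expect_equal(average_signal(tr2, rec, 100), 0.5)

  iv <- random_intervals(50, len, 6)
  tr3 <- signal_track(iv, c(chr1 = len))
  flat <- flat_signal(iv, len)
  tss <- toy_tss(5, len = len, seed = 7)
  for (i in seq_len(nrow(tss))) {
    expect_equal(average_signal(tr3, tss[i, ], 50),
                 mean(flat[(tss$pos[i] - 50 + 1):(tss$pos[i] + 50)]))
  }
  # truncated window is zero padded, denominator unchanged
  edge <- as_tss_table(data.frame(chrom = "chr1", pos = 10, strand = "+",
                                  gene_id = "e", category = "protein_coding"))
  expect_equal(average_signal(tr3, edge, 50),
               sum(flat[1:60]) / 100)
})

test_that("uniform-weight regulatory score equals the flat window mean", {
  len <- 3000
  iv <- random_intervals(70, len, 8)
  tr <- signal_track(iv, c(chr1 = len))
  flat <- flat_signal(iv, len)
  tss <- toy_tss(5, len = len, seed = 9)
  h <- 100
  prof <- structure(list(h = h, weights = rep(1 / (2 * h + 1), 2 * h + 1)),
                    class = "binding_profile")
  for (i in seq_len(nrow(tss))) {
    expect_equal(regulatory_score(prof, tr, tss[i, ]),
                 mean(flat[(tss$pos[i] - h + 1):(tss$pos[i] + h + 1)]),
                 tolerance = 1e-12)
  }
})

test_that("regulatory scores are invariant under genome mirroring", {
  # mirroring the chromosome (reverse the signal, flip strands, reflect
  # positions) must leave every TIP score unchanged
  len <- 5000
  iv <- random_intervals(80, len, 13)
  tr <- signal_track(iv, c(chr1 = len))
  tss <- toy_tss(6, len = len, seed = 14)
  flat <- flat_signal(iv, len)
  mirror <- data.frame(chrom = "chr1", start = 0, end = len, value = 0)
  runs <- rle(rev(flat))
  ends <- cumsum(runs$lengths)
  mirror <- data.frame(chrom = "chr1", start = ends - runs$lengths,
                       end = ends, value = runs$values)
  mirror <- mirror[mirror$value != 0, ]
  tr_m <- signal_track(mirror, c(chr1 = len))
  tss_m <- tss
  tss_m$pos <- len - 1 - tss$pos
  tss_m$strand <- ifelse(tss$strand == "+", "-", "+")
  tss_m <- as_tss_table(tss_m)

  h <- 60
  prof <- characteristic_profile(tr, tss, h = h)
  prof_m <- characteristic_profile(tr_m, tss_m, h = h)
  expect_equal(prof$profile, prof_m$profile, tolerance = 1e-12)
  s1 <- sort(regulatory_scores(prof, tr, tss))
  s2 <- sort(regulatory_scores(prof_m, tr_m, tss_m))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("class contrast reproduces the Welch t-test", {
  set.seed(21)
  x <- rnorm(200)
  lab <- rep(c(1, 0), 100)
  ct <- score_class_contrast(x, lab)
  expect_lt(abs(ct$t), 2.5) # identical distributions: near zero

  # 3-vs-3 toy against the textbook Welch formula
  a <- c(1, 2, 4)
  b <- c(0, 1, 1)
  ct2 <- score_class_contrast(c(a, b), c(1, 1, 1, 0, 0, 0))
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(ct2$t, tw, tolerance = 1e-12)

  # strongly separated classes at n = 500 are overwhelmingly significant
  ok <- vapply(1:3, function(s) {
    set.seed(s)
    sc <- c(rnorm(500, 1), rnorm(500, 0))
    score_class_contrast(sc, rep(c(1, 0), each = 500))$p < 1e-10
  }, TRUE)
  expect_true(all(ok))
})
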