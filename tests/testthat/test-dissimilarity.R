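# hand-made binned samples and centralized vectors for arithmetic checks
fake_counts <- function(k, values) {
  counts <- setNames(numeric(4^k), all_ktuples(k))
  counts[names(values)] <- values
  structure(list(k = k, counts = counts, n = sum(counts)),
            class = "ktuple_counts")
}

fake_sample <- function(k, bins) {
  structure(list(C = length(bins), k = k,
                 per_bin_counts = lapply(bins, `[[`, "counts_obj"),
                 per_bin_models = lapply(bins, `[[`, "model"),
                 n_reads_per_bin = rep(1L, length(bins)), n_dropped = 0L),
            class = "binned_sample")
}

fake_centralized <- function(xbar, expected = abs(xbar) + 1) {
  k <- as.integer(round(log(length(xbar), 4)))
  structure(list(k = k, xbar = xbar, expected = expected),
            class = "centralized_kmers")
}

uniform_model0 <- markov_model(matrix(0.25, 1, 4), order = 0)

test_that("centralization subtracts bin-wise expected counts and sums bins", {
  # one bin, uniform order-0 background: expected count = n / 16 per 2-tuple
  cnt <- fake_counts(2, c(AA = 10, CC = 90))   # n = 100
  s <- fake_sample(2, list(list(counts_obj = cnt, model = uniform_model0)))
  cen <- centralize(s)
  expect_equal(unname(cen$expected["AA"]), 100 / 16)
  expect_equal(unname(cen$xbar["AA"]), 10 - 100 / 16)
  expect_equal(unname(cen$xbar["GG"]), 0 - 100 / 16)
  expect_equal(cen$xbar, cnt$counts - cen$expected, tolerance = 1e-9)

  # two bins combine additively: (4 - 1) + (1 - 3) = 1, expected 1 + 3 = 4
  b1 <- fake_counts(2, c(AA = 4, TT = 4, GC = 8))   # n = 16, n p_AA = 1
  b2 <- fake_counts(2, c(AA = 1, TT = 1, CG = 46))  # n = 48, n p_AA = 3
  s2 <- fake_sample(2, list(list(counts_obj = b1, model = uniform_model0),
                            list(counts_obj = b2, model = uniform_model0)))
  cen2 <- centralize(s2)
  expect_equal(unname(cen2$xbar["AA"]), 1)
  expect_equal(unname(cen2$expected["AA"]), 4)

  # counts equal to expectations give the zero vector
  flat <- fake_counts(2, setNames(rep(2, 16), all_ktuples(2)))   # n = 32
  s3 <- fake_sample(2, list(list(counts_obj = flat, model = uniform_model0)))
  expect_equal(max(abs(centralize(s3)$xbar)), 0)

  expect_error(centralize(fake_sample(2, list(list(
    counts_obj = fake_counts(2, c(AA = 5)),
    model = markov_model(matrix(0.25, 4, 4), order = 1))))),
    "order must be <= k - 2")
})

test_that("d2S matches its closed-form special cases", {
  x <- fake_centralized(c(3, -1, 2, 0.5))
  expect_equal(d2s(x, x), 0)

  # disjoint supports: numerator 0, dissimilarity 1/2
  a <- fake_centralized(c(5, 0, 0, 0))
  b <- fake_centralized(c(0, 7, 0, 0))
  expect_equal(d2s(a, b), 0.5)

  # anti-correlated vectors reach the upper bound
  y <- fake_centralized(-x$xbar)
  expect_equal(d2s(x, y), 1)

  z <- fake_centralized(rep(0, 4))
  expect_error(d2s(z, z), "degenerate")
})

test_that("d2* matches hand evaluation and its special cases", {
  # single supported tuple: D2* = 6 / sqrt(9 * 4) = 1, normalizers 1
  x <- fake_centralized(c(3, 0, 0, 0), expected = c(9, 0, 0, 0))
  y <- fake_centralized(c(2, 0, 0, 0), expected = c(4, 0, 0, 0))
  expect_equal(d2star(x, y), 0)

  xx <- fake_centralized(c(3, -1, 2, 0.5), expected = c(4, 2, 3, 1))
  expect_equal(d2star(xx, xx), 0)

  # orthogonal supports with positive expectations: numerator 0
  a <- fake_centralized(c(5, 0, 0, 0), expected = rep(2, 4))
  b <- fake_centralized(c(0, 7, 0, 0), expected = rep(2, 4))
  expect_equal(d2star(a, b), 0.5)

  # zero-expectation tuple with signal is skipped with a warning
  w <- fake_centralized(c(3, 1, 0, 0), expected = c(4, 0, 1, 1))
  expect_warning(v <- d2star(w, a), "zero expectation")
  expect_gte(v, 0)
})

test_that("both measures obey the [0,1] bounds and symmetry on random input", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(c(16, 64), 1)
    x <- fake_centralized(rnorm(n, sd = 5), expected = abs(rnorm(n)) + 0.1)
    y <- fake_centralized(rnorm(n, sd = 5), expected = abs(rnorm(n)) + 0.1)
    s1 <- d2s(x, y); s2 <- d2star(x, y)
    expect_gte(s1, 0); expect_lte(s1, 1)
    expect_gte(s2, 0); expect_lte(s2, 1)
    expect_identical(s1, d2s(y, x))
    expect_identical(s2, d2star(y, x))
  }
})

test_that("C = 1 binning reproduces the classic un-binned statistics", {
  set.seed(43)
  panel <- list(g1 = random_reads(1, 4000, gc = 0.45))
  b1 <- build_genome_bins(panel, C = 1, order = 1)
  for (rep in 1:3) {
    rx <- random_reads(40, 100, gc = 0.4)
    ry <- random_reads(40, 100, gc = 0.6)
    bx <- bin_sample(rx, b1, k = 4, background_order = 1)
    by <- bin_sample(ry, b1, k = 4, background_order = 1)
    cx <- centralize(bx); cy <- centralize(by)
    want <- oracle_d2_nobin(rx, ry, k = 4, r = 1)
    expect_equal(d2s(cx, cy), unname(want["d2s"]), tolerance = 1e-12)
    expect_equal(d2star(cx, cy), unname(want["d2star"]), tolerance = 1e-12)
  }
})

test_that("pairwise matrices are symmetric, zero-diagonal and label-aware", {
  set.seed(47)
  panel <- synth_genomes(2, gc_range = c(0.35, 0.65), length = 10000,
                         order = 1)
  b <- build_genome_bins(panel, C = 2, order = 1)
  mk <- function(gc) bin_sample(random_reads(30, 120, gc), b, k = 4,
                                background_order = 1)
  samples <- list(s1 = mk(0.4), s2 = mk(0.6), s3 = mk(0.5))
  samples$dup <- samples$s1
  dm <- pairwise_dissimilarity(samples, "d2s")
  expect_equal(rownames(dm), c("s1", "s2", "s3", "dup"))
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_equal(unclass(dm), t(unclass(dm)))
  expect_equal(dm["s1", "dup"], 0)
  expect_true(all(dm >= 0 & dm <= 1))
  expect_error(pairwise_dissimilarity(samples[1], "d2s"), "at least 2")
})

test_that("between-group dissimilarity exceeds within-group dissimilarity", {
  set.seed(53)
  panel <- synth_genomes(6, gc_range = c(0.3, 0.7), length = 20000, order = 2)
  b <- build_genome_bins(panel, C = 2, order = 1)
  gaps <- replicate(5, {
    p1 <- zipf_abundance(1.2, 6, sample.int(6, 6))
    p2 <- zipf_abundance(1.2, 6, sample.int(6, 6))
    mk <- function(p) {
      sm <- simulate_sample(panel, perturb_abundance(p, "sd1"), 400)
      bin_sample(c(sm$mate1, sm$mate2), b, k = 4, background_order = 1)
    }
    samples <- list(a1 = mk(p1), a2 = mk(p1), b1 = mk(p2), b2 = mk(p2))
    dm <- pairwise_dissimilarity(samples, "d2s")
    within <- mean(c(dm["a1", "a2"], dm["b1", "b2"]))
    between <- mean(c(dm["a1", "b1"], dm["a1", "b2"],
                      dm["a2", "b1"], dm["a2", "b2"]))
    between - within
  })
  expect_gt(mean(gaps), 0)
})

test_that("dissimilarity matrices round-trip through TSV", {
  m <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("x", "y"),
                                                       c("x", "y")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dissimilarity(m, f)
  m2 <- read_dissimilarity(f)
  expect_equal(unclass(m2), m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rownames(m2), c("x", "y"))
  # PHYLIP square variant is parseable by ape
  f2 <- withr::local_tempfile(fileext = ".phy")
  write_dissimilarity(m, f2, format = "phylip")
  expect_equal(readLines(f2)[1], "    2")
})
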