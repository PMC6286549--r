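test_that("fisher_combine matches its closed forms", {
  r <- fisher_combine(c(1, 1))
  expect_equal(r$X2, 0)
  expect_equal(r$p_combined, 1)
  expect_equal(r$df, 4L)

  # k = 1 identity: p_combined = exp(-X2/2) = p
  for (p in c(1e-8, 0.01, 0.3, 0.9999)) {
    expect_equal(fisher_combine(p)$p_combined, p, tolerance = 1e-12)
  }

  # df = 4 closed form: survival S(x) = exp(-x/2) * (1 + x/2)
  r2 <- fisher_combine(c(0.05, 0.05))
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(r2$X2, x, tolerance = 1e-12)
  expect_equal(r2$p_combined, exp(-x / 2) * (1 + x / 2), tolerance = 1e-9)

  expect_error(fisher_combine(numeric(0)), "no p-values")
  expect_error(fisher_combine(c(0.5, 1.2)), "\\[0, 1\\]")
  # p = 0 is clamped, keeping X2 finite
  rc <- fisher_combine(c(0, 0.5))
  expect_true(is.finite(rc$X2))
  expect_equal(rc$n_clamped, 1L)
})

test_that("fisher_combine is monotone in each p-value", {
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:6, 1))
    j <- sample(length(p), 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    a <- fisher_combine(p)
    b <- fisher_combine(p2)
    expect_gt(b$X2, a$X2)
    expect_lte(b$p_combined, a$p_combined)
  }
})

test_that("bh_adjust equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(0.2), 0.2)

  set.seed(17)
  for (i in 1:100) {
    n <- sample(1:50, 1)
    p <- runif(n)^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    m <- n + sample(0:20, 1)
    q <- bh_adjust(p, m = m)
    expect_equal(q, oracle_bh(p, m))
    # monotone: smaller p never gets the larger q
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("combine_windows pools comparisons per window", {
  mk <- function(p, tested = rep(TRUE, length(p)),
                 dir = rep("+", length(p)), id = "a_vs_b") {
    out <- data.frame(chrom = "chrT", start = (seq_along(p) - 1) * 500,
                      end = seq_along(p) * 500, p = p, direction = dir,
                      tested = tested, stringsAsFactors = FALSE)
    attr(out, "comparison_id") <- id
    out
  }
  cmb <- combine_windows(list(mk(c(0.05, 0.5, 1)), mk(c(0.05, 0.5, 1),
                                                      dir = c("+", "-", "0"))))
  expect_equal(cmb$k, rep(2L, 3))
  expect_equal(cmb$df, rep(4L, 3))
  expect_equal(cmb$X2[1], -4 * log(0.05), tolerance = 1e-12)
  expect_equal(cmb$p_combined[3], 1)
  expect_equal(cmb$direction, c("+", "mixed", "mixed"))
  expect_equal(cmb$q, bh_adjust(cmb$p_combined, m = 3))

  # a window untested in any comparison is untested overall, q = NA,
  # and the BH family size shrinks to the tested count
  cmb2 <- combine_windows(list(mk(c(0.05, 1, 0.2), tested = c(TRUE, FALSE, TRUE)),
                               mk(c(0.05, 1, 0.2))))
  expect_equal(cmb2$tested, c(TRUE, FALSE, TRUE))
  expect_true(is.na(cmb2$q[2]))
  expect_equal(cmb2$q[c(1, 3)],
               bh_adjust(cmb2$p_combined[c(1, 3)], m = 2))

  expect_error(combine_windows(list()), "no comparisons")
  expect_error(combine_windows(list(mk(0.1), mk(c(0.1, 0.2)))),
               "different windows")
})

test_that("call_dmrs uses a strict threshold and nests across cutoffs", {
  comb <- data.frame(chrom = "chrT", start = c(0, 500, 1000),
                     end = c(500, 1000, 1500),
                     q = c(0.009, 0.04, 0.2),
                     direction = c("+", "-", "+"),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(call_dmrs(comb, 0.01)), 1L)
  expect_equal(nrow(call_dmrs(comb, 0.05)), 2L)
  # boundary is strict
  comb$q[2] <- 0.05
  expect_equal(nrow(call_dmrs(comb, 0.05)), 1L)
  expect_equal(nrow(call_dmrs(data.frame(chrom = "c", start = 0, end = 500,
                                         q = 1, direction = "+"), 0.05)), 0L)

  set.seed(23)
  for (i in 1:20) {
    qs <- data.frame(chrom = "chrT", start = 0:49 * 500, end = 1:50 * 500,
                     q = runif(50)^2, direction = "+",
                     stringsAsFactors = FALSE)
    d01 <- call_dmrs(qs, 0.01)
    d05 <- call_dmrs(qs, 0.05)
    expect_true(all(d01$start %in% d05$start))
    expect_true(all(d05$q_value < 0.05))
  }
})

test_that("DMR BED output caps the score and survives a round trip", {
  tmp <- withr::local_tempfile()
  dmrs <- data.frame(chrom = "chrT", start = c(0, 500), end = c(500, 1000),
                     q_value = c(1e-200, 0.04), direction = c("+", "-"),
                     threshold = 0.05, stringsAsFactors = FALSE)
  write_dmr_bed(dmrs, tmp)
  back <- read_bed(tmp)
  expect_equal(back$start, dmrs$start)
  scores <- as.numeric(vapply(strsplit(readLines(tmp), "\t"), `[[`, "", 5L))
  expect_equal(scores[1], 1000)  # capped
  expect_equal(scores[2], round(-10 * log10(0.04)))
})
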