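test_that("spectrum construction validates shape against n and folding", {
  s <- sfs_spectrum(c(3, 2, 1), n = 4)
  expect_equal(s$L, 6)
  expect_error(sfs_spectrum(c(3, 2), n = 4), "length 3")
  expect_error(sfs_spectrum(c(3, 2, 1), n = 4, folded = TRUE), "length 2")
  expect_error(sfs_spectrum(c(-1, 2, 1), n = 4), "nonnegative")
})

test_that("folding merges mirror classes and conserves totals", {
  expect_equal(fold_sfs(sfs_spectrum(c(3, 2, 1), n = 4))$counts, c(4, 2))
  s5 <- fold_sfs(sfs_spectrum(c(5, 7, 11, 13), n = 5))
  expect_equal(s5$counts, c(5 + 13, 7 + 11))
  set.seed(1)
  for (n in c(6, 9, 20)) {
    x <- rpois(n - 1, 10)
    f <- fold_sfs(sfs_spectrum(x, n = n, L = 999))
    expect_equal(sum(f$counts), sum(x))
    expect_equal(f$L, 999)
    expect_true(f$folded)
  }
  expect_error(fold_sfs(fold_sfs(sfs_spectrum(c(1, 2, 3), n = 4))),
               "already folded")
})

test_that("splitting conserves every class and is seed-deterministic", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    s <- sfs_spectrum(rpois(n - 1, 20), n = n, L = 500)
    h <- split_sfs(s, seed = rep)
    expect_equal(h[[1]]$counts + h[[2]]$counts, s$counts)
    expect_equal(h[[1]]$L + h[[2]]$L, s$L)
    expect_true(all(h[[1]]$counts >= 0) && all(h[[2]]$counts >= 0))
    h2 <- split_sfs(s, seed = rep)
    expect_identical(h[[1]]$counts, h2[[1]]$counts)
  }
  expect_error(split_sfs(sfs_spectrum(c(1.5, 2, 1), n = 4, L = 10), 1),
               "integer")
})

test_that("split halves are unbiased (Monte Carlo, fair assignment)", {
  s <- sfs_spectrum(c(40, 20, 10), n = 4, L = 70)
  R <- 2000
  first <- matrix(0, R, 3)
  for (r in seq_len(R)) first[r, ] <- split_sfs(s, seed = r)[[1]]$counts
  se <- sqrt(s$counts * 0.25 / R)
  expect_true(all(abs(colMeans(first) - s$counts / 2) < 3 * se))
})

test_that("weighted averaging is idempotent, selective and scale-free", {
  a <- sfs_spectrum(c(10, 5, 2), n = 4, L = 100)
  b <- sfs_spectrum(c(4, 4, 4), n = 4, L = 60)
  expect_equal(weighted_average_sfs(list(a, a), c(1, 1))$counts, a$counts)
  expect_equal(weighted_average_sfs(list(a, b), c(1, 0))$counts, a$counts)
  w1 <- weighted_average_sfs(list(a, b), c(1, 1))
  w2 <- weighted_average_sfs(list(a, b), c(2, 2))
  expect_equal(w1$counts, w2$counts)
  expect_equal(w1$L, 80)
  expect_equal(w1$counts, (a$counts + b$counts) / 2)
  expect_error(weighted_average_sfs(
    list(a, sfs_spectrum(c(1, 1, 1, 1), n = 5)), c(1, 1)), "share n")
  expect_error(weighted_average_sfs(list(a, b), c(0, 0)), "positive")
})

test_that("pN/pS handles raw and per-site conventions", {
  expect_equal(pnps(poly_counts(5, 10)), 0.5)
  expect_equal(pnps(poly_counts(5, 10, l_n = 100, l_s = 200),
                    per_site = TRUE), 1.0)
  expect_error(pnps(poly_counts(5, 0)), "p_s is zero")
  expect_error(pnps(poly_counts(5, 10), per_site = TRUE), "per-site")
})

test_that("dofe files round-trip exactly and are byte-stable", {
  recs <- list(
    list(name = "unit_a",
         sel = sfs_spectrum(c(12, 5, 3), n = 4, L = 1000),
         neu = sfs_spectrum(c(30, 14, 9), n = 4, L = 2000),
         div = div_counts(d_sel = 7, d_neu = 25, l_sel = 5e4, l_neu = 9e4)),
    list(name = "unit_b",
         sel = sfs_spectrum(c(2, 1, 0), n = 4, L = 50),
         neu = sfs_spectrum(c(5, 2, 2), n = 4, L = 80),
         div = div_counts(d_sel = 1, d_neu = 3, l_sel = 100, l_neu = 200)))
  f1 <- tempfile(fileext = ".dofe"); f2 <- tempfile(fileext = ".dofe")
  write_dofe(recs, f1, unfolded = TRUE)
  write_dofe(recs, f2, unfolded = TRUE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_dofe(f1)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$name, recs[[i]]$name)
    expect_equal(back[[i]]$sel$counts, recs[[i]]$sel$counts)
    expect_equal(back[[i]]$neu$counts, recs[[i]]$neu$counts)
    expect_false(back[[i]]$sel$folded)
    expect_equal(back[[i]]$div$d_neu, recs[[i]]$div$d_neu)
    expect_equal(back[[i]]$div$l_sel, recs[[i]]$div$l_sel)
  }
  # n = 4 records emit exactly 3 + 3 count fields (14 fields total:
  # name, n, two L + counts blocks, four divergence fields)
  lines <- readLines(f1)
  expect_equal(lines[2], "#unfolded")
  expect_length(strsplit(lines[3], "\t")[[1]], 14L)
})

test_that("malformed dofe input is rejected with the line number", {
  f <- tempfile(fileext = ".dofe")
  writeLines(c("header", "#unfolded",
               paste(c("bad", 4, 10, 1, 2), collapse = "\t")), f)
  expect_error(read_dofe(f), "line 3")
  # folded records cannot be written with the unfolded marker
  rec <- list(list(name = "x",
                   sel = fold_sfs(sfs_spectrum(c(1, 2, 3), n = 4)),
                   neu = fold_sfs(sfs_spectrum(c(1, 2, 3), n = 4)),
                   div = div_counts(1, 1, 10, 10)))
  expect_error(write_dofe(rec, tempfile(), unfolded = TRUE), "folded")
})
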