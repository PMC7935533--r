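lengths1k <- function(ids, L = 1000L) stats::setNames(rep(L, length(ids)), ids)

test_that("rpkm implements RC_g * 1e9 / (RC_pc * L_g)", {
  # one gene carries 100 of 1e6 total reads, L = 1000
  counts <- ev(G = 100, FILL = 1e6 - 100)
  ann <- c(G = 1000L, FILL = 1000L)
  expect_equal(rpkm(counts, ann)$values[["G"]], 100)

  expect_equal(rpkm(ev(A = 0, B = 10), c(A = 500L, B = 100L))$values[["A"]], 0)

  two <- rpkm(ev(g1 = 10, g2 = 990), c(g1 = 500L, g2 = 2000L))
  expect_equal(two$values[["g1"]], 10 * 1e9 / (1000 * 500))  # 20000
  expect_equal(two$norm_state, "rpkm")

  expect_error(rpkm(ev(A = 1), c(B = 100L)), "no coding-sequence length")
  expect_error(rpkm(ev(A = 0, B = 0), c(A = 1L, B = 1L)), "all counts are zero")
})

test_that("rpkm_upper shrinks the library denominator by delta", {
  counts <- ev(G = 100, FILL = 1e6 - 100)
  ann <- c(G = 1000L, FILL = 1000L)
  v <- rpkm_upper(counts, ann, delta = 0.05)
  expect_equal(v$values[["G"]], 1e11 / 9.5e8)  # 105.2631...
  expect_equal(v$norm_state, "rpkm_upper")

  # delta = 0.25 scales every value by 1/0.75 relative to rpkm
  v25 <- rpkm_upper(counts, ann, delta = 0.25)
  expect_equal(v25$values, rpkm(counts, ann)$values / 0.75)

  expect_error(rpkm_upper(counts, ann, delta = 1), "delta")
})

test_that("rpkm_upper at delta = 0 equals rpkm to machine precision", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    ids <- paste0("g", seq_len(n))
    counts <- expression_vector(stats::setNames(rpois(n, 200), ids))
    ann <- stats::setNames(sample(100:5000, n), ids)
    expect_identical(rpkm_upper(counts, ann, delta = 0, .state = "rpkm")$values,
                     rpkm(counts, ann)$values)
  }
})

test_that("upper_quartile scales by the 75th percentile of nonzero counts", {
  ids <- paste0("g", 1:101)
  counts <- expression_vector(stats::setNames(c(1:100, 0), ids))
  ann <- lengths1k(ids)
  v <- upper_quartile(counts, ann)
  # RC_g75 of 1..100 by linear interpolation is 75.25
  expect_equal(v$values[["g10"]], 10 * 1e9 / (75.25 * 1000))
  expect_equal(v$values[["g101"]], 0)

  single <- upper_quartile(ev(a = 7, b = 0), c(a = 250L, b = 100L))
  expect_equal(single$values[["a"]], 1e9 / 250)

  expect_error(upper_quartile(ev(a = 0), c(a = 10L)), "all counts are zero")
})

test_that("lognorm matches the double-log closed form and maps 0 to 0", {
  x <- ev(zero = 0, ten = 10, norm_state = "raw_counts")
  x$norm_state <- "rpkm_upper"
  out <- lognorm(x, C = 20, b = 1.1)
  expect_equal(out$values[["zero"]], 0)
  # frozen from a 30-digit independent evaluation of 20*10*(log_1.1(log_1.1(11))+1)
  expect_equal(out$values[["ten"]], 6967.81860040229, tolerance = 1e-12)
  expect_equal(out$norm_state, "lognorm")

  # monotone on x >= 1
  grid <- expression_vector(
    stats::setNames(10^seq(0, 6, length.out = 400), paste0("x", 1:400)),
    norm_state = "external")
  vals <- lognorm(grid, 20, 1.1)$values
  expect_true(all(diff(vals) > 0))
  # finite everywhere on [0, 1e8]
  wide <- expression_vector(
    stats::setNames(c(0, 10^seq(-6, 8, length.out = 100)), paste0("w", 1:101)),
    norm_state = "external")
  expect_true(all(is.finite(lognorm(wide, 20, 1.1)$values)))
  expect_true(all(is.finite(log2norm(wide)$values)))
})

test_that("log2norm computes x * log_b(x + 1)", {
  x <- expression_vector(c(a = 1, b = 3, z = 0), norm_state = "external")
  out <- log2norm(x, b = 2)
  expect_equal(out$values, c(a = 1, b = 6, z = 0))
  expect_equal(out$norm_state, "log2")
})

test_that("all transforms preserve within-sample rank order on x >= 1", {
  set.seed(55)
  ids <- paste0("g", 1:50)
  counts <- expression_vector(stats::setNames(sample(1:10000, 50), ids))
  base_rank <- rank(counts$values)
  # with equal lengths the per-gene scaling is shared, so each transform must
  # leave the within-sample ordering of counts untouched
  annc <- lengths1k(ids)
  for (method in c("rpkm", "rpkm-upper", "uq", "lognorm", "log2"))
    expect_equal(rank(normalize_counts(counts, annc, method)$values), base_rank)
})

test_that("rpkm is invariant under library duplication", {
  set.seed(9)
  ids <- paste0("g", 1:30)
  base <- stats::setNames(rpois(30, 100), ids)
  ann <- stats::setNames(sample(100:2000, 30), ids)
  expect_equal(rpkm(expression_vector(base * 2), ann)$values,
               rpkm(expression_vector(base), ann)$values)
})
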