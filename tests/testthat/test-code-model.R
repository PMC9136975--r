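test_that("random codes are deterministic, in-domain, and uniform", {
  a <- random_code(7, seed = 0)
  b <- random_code(7, seed = 0)
  expect_true(a == b)
  expect_equal(dim(a$cells), c(7, 7))
  expect_true(all(a$cells %in% 0:3))

  # binomial oracle: over 10,000 draws each symbol's frequency lies
  # within 3 sigma of 1/4 (N = 490,000 cells)
  set.seed(123)
  cells <- unlist(lapply(1:10000, function(i) random_code(7)$cells))
  N <- length(cells)
  p_hat <- tabulate(cells + 1L, 4L) / N
  tol <- 3 * sqrt(0.25 * 0.75 / N)
  expect_true(all(abs(p_hat - 0.25) < tol))

  expect_error(random_code(4), "not one of the supported")
  expect_silent(random_code(11, seed = 1, allow_other_n = TRUE))
})

test_that("channel encoding maps symbols to per-channel bits", {
  empty <- matrix_code(matrix(0L, 7, 7))
  keys <- encode_channels(empty)
  expect_named(keys, c("ECFP", "EGFP", "MKATE2"))
  for (k in keys) {
    expect_length(k$bits, 49)
    expect_true(all(k$bits == 0L))
  }

  # single EGFP in the top-left cell, row-major bit 1
  cells <- matrix(0L, 7, 7); cells[1, 1] <- code_symbols[["EGFP"]]
  keys <- encode_channels(matrix_code(cells))
  expect_equal(keys$ECFP$bits, rep(0L, 49))
  expect_equal(keys$EGFP$bits, c(1L, rep(0L, 48)))
  expect_equal(keys$MKATE2$bits, rep(0L, 49))

  # row-major scan order: cell (row 2, col 1) is bit position 8 for n=7
  cells <- matrix(0L, 7, 7); cells[2, 1] <- code_symbols[["ECFP"]]
  keys <- encode_channels(matrix_code(cells))
  expect_equal(which(keys$ECFP$bits == 1L), 8L)
})

test_that("digitized keys concatenate to 3n^2 bits in fixed channel order", {
  for (n in c(5L, 7L, 9L)) {
    key <- concat_key(encode_channels(random_code(n, seed = n)))
    expect_length(key$bits, 3 * n^2)
    expect_equal(key$channel_order, c("ECFP", "EGFP", "MKATE2"))
  }
  zero <- concat_key(channel_key("ECFP", rep(0, 49)),
                     channel_key("EGFP", rep(0, 49)),
                     channel_key("MKATE2", rep(0, 49)))
  expect_true(all(zero$bits == 0L))

  expect_error(concat_key(channel_key("ECFP", rep(0, 49)),
                          channel_key("EGFP", rep(0, 25)),
                          channel_key("MKATE2", rep(0, 49))),
               "mismatched")
  expect_error(concat_key(channel_key("EGFP", rep(0, 49)),
                          channel_key("ECFP", rep(0, 49)),
                          channel_key("MKATE2", rep(0, 49))),
               "order")
})

test_that("key-to-matrix is the exact inverse of encoding", {
  expect_true(key_to_matrix(digitized_key(rep(0L, 147))) ==
                matrix_code(matrix(0L, 7, 7)))
  for (seed in 1:50) {
    m <- random_code(7, seed = seed)
    expect_true(key_to_matrix(concat_key(encode_channels(m))) == m)
  }
  # conflicting bits (ECFP and EGFP at cell 5, 0-based) are an error
  bits <- rep(0L, 147)
  bits[6] <- 1L          # ECFP block, cell index 5
  bits[49 + 6] <- 1L     # EGFP block, same cell
  expect_error(key_to_matrix(digitized_key(bits)), "cell\\(s\\) 5")
})

test_that("quaternary and double binary reconstructions follow base-4 expansion", {
  zero <- digitized_key(rep(0L, 147))
  expect_equal(to_quaternary(zero)$digits, rep(0L, 49))
  expect_length(to_double_binary(zero), 98)

  bits <- rep(0L, 147); bits[49 + 1] <- 1L  # EGFP at cell 0
  q <- to_quaternary(digitized_key(bits))
  expect_equal(q$digits[1], 2L)
  expect_true(all(q$digits[-1] == 0L))

  # base-4 digit expansion, MSB first: 3 -> (1,1), 1 -> (0,1)
  m <- random_code(7, seed = 4)
  key <- concat_key(encode_channels(m))
  q <- to_quaternary(key)$digits
  db <- to_double_binary(key)
  expect_equal(db, as.integer(rbind(q %/% 2L, q %% 2L)))
  expect_equal(matrix(db, 2)[, q == 3][, 1], c(1L, 1L))
})

test_that("encoding capacity is exact arbitrary-precision arithmetic", {
  # 2^147: decimal expansion frozen from an independent big-integer oracle
  expect_equal(format(capacity(2, 147)),
               "178405961588244985132285746181186892047843328")
  expect_equal(bigint_scientific(capacity(2, 147)), "1.78e+44")
  expect_equal(format(capacity(2, 0)), "1")
  expect_equal(format(capacity(4, 49)),
               "316912650057057350374175801344")
  # physically realizable space is strictly below the nominal key space
  for (n in c(5L, 7L, 9L)) {
    cs <- capacity_summary(n)
    expect_true(silkcode:::bigint_lt(cs$physical, cs$nominal))
  }
})

test_that("keys and codes round-trip through their JSON schema", {
  m <- random_code(7, seed = 9)
  key <- concat_key(encode_channels(m))
  key2 <- code_from_json(code_to_json(key))
  expect_equal(key2$bits, key$bits)
  expect_equal(key2$n, 7L)
  m2 <- code_from_json(code_to_json(m))
  expect_true(m2 == m)
})
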