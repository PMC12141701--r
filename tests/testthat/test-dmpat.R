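test_that("pair_distance is the two-channel amplitude norm", {
  expect_equal(pair_distance(3, 4), 5)
  expect_equal(pair_distance(0, 0), 0)
  expect_equal(pair_distance(-3, 4), 5)     # squaring removes sign
  expect_equal(pair_distance(4, -3), 5)     # symmetric
  expect_error(pair_distance(NA, 1), "non-finite")
  expect_error(pair_distance(Inf, 1), "non-finite")
})

test_that("encode_sample finds extremal pairs with scan-order tie-breaks", {
  ## hand-enumerated: DM(1,2)=5, DM(1,3)=3, DM(2,3)=4
  expect_equal(encode_sample(c(3, 4, 0)),
               c(val_min = 2, val_max = 1))
  ## all distances tie: first upper-triangle pair (1,2) wins both
  expect_equal(encode_sample(rep(1, 14)), c(val_min = 1, val_max = 1))
  expect_error(encode_sample(5), "at least 2 channels")
  ## 14 channels: codes stay inside the 196-bin range
  set.seed(1)
  for (i in 1:20) {
    v <- encode_sample(rnorm(14))
    expect_true(all(v >= 0 & v <= 195))
  }
})

test_that("encode_sample matches brute-force pair enumeration", {
  set.seed(99)
  for (i in 1:300) {
    nc <- sample(2:5, 1)
    col <- rnorm(nc)
    expect_identical(unname(encode_sample(col)),
                     unname(brute_encode_sample(col)))
  }
})

test_that("decode_code inverts the pair encoding", {
  expect_equal(decode_code(1, 14), c(a1 = 1L, a2 = 2L))
  expect_equal(decode_code(2, 3), c(a1 = 1L, a2 = 3L))
  ## arithmetic holds outside the encoder image too
  expect_equal(decode_code(195, 14), c(a1 = 14L, a2 = 14L))
  expect_error(decode_code(196, 14), "out of range")
  expect_error(decode_code(-1, 14), "out of range")
  ## exact round trip on the encoder's image (codes with a1 < a2)
  for (nc in 2:6) {
    pairs <- soxfe:::pair_index_table(nc)
    for (r in seq_len(nrow(pairs))) {
      val <- (pairs[r, 1] - 1) * nc + (pairs[r, 2] - 1)
      expect_equal(unname(decode_code(val, nc)), unname(pairs[r, ]))
    }
  }
})

test_that("encode_segment encodes columns independently and deterministically", {
  set.seed(5)
  sig <- matrix(rnorm(6 * 30), nrow = 6)
  codes <- encode_segment(sig)
  expect_length(codes$codes_min, 30L)
  expect_length(codes$codes_max, 30L)
  ## column-wise agreement with the scalar encoder
  per_col <- apply(sig, 2L, encode_sample)
  expect_equal(codes$codes_min, unname(per_col[1, ]))
  expect_equal(codes$codes_max, unname(per_col[2, ]))
  ## constant segment: constant codes
  const <- encode_segment(matrix(rep(c(3, 4, 0), 10), nrow = 3))
  expect_true(all(const$codes_min == 2) && all(const$codes_max == 1))
  ## permuting samples permutes codes identically
  perm <- sample(30)
  codes_p <- encode_segment(sig[, perm])
  expect_equal(codes_p$codes_min, codes$codes_min[perm])
  ## positive rescaling never changes the argmin/argmax pairs
  codes_s <- encode_segment(sig * 17.3)
  expect_identical(codes_s$codes_min, codes$codes_min)
  expect_identical(codes_s$codes_max, codes$codes_max)
})

test_that("histogram features conserve counts over the nc^2 bins", {
  set.seed(6)
  sig <- matrix(rnorm(14 * 1920), nrow = 14)
  h <- histogram_features(encode_segment(sig))
  expect_length(h$f1, 196L)
  expect_length(h$f2, 196L)
  expect_equal(sum(h$f1), 1920)
  expect_equal(sum(h$f2), 1920)
  expect_equal(names(h$f1)[18], "min_017")
  ## degenerate: one populated bin
  hc <- histogram_features(encode_segment(matrix(rep(c(3, 4, 0), 7), nrow = 3)))
  expect_equal(unname(hc$f1[3]), 7)       # code 2 -> bin index 3
  expect_equal(sum(hc$f1 > 0), 1L)
})

test_that("merged vector concatenates f1 and f2", {
  set.seed(7)
  h <- histogram_features(encode_segment(matrix(rnorm(14 * 100), nrow = 14)))
  f3 <- merge_features(h$f1, h$f2)
  expect_length(f3, 392L)
  expect_equal(unname(f3[1:196]), unname(h$f1))
  expect_equal(unname(f3[197:392]), unname(h$f2))
  expect_equal(sum(f3), 200)
  expect_error(merge_features(1:4, 1:5), "equal length")
})

test_that("dmpat_features stacks per-segment vectors in order", {
  set.seed(8)
  segs <- lapply(1:5, function(i) matrix(rnorm(14 * 50), nrow = 14))
  f <- dmpat_features(segs)
  expect_equal(dim(f$f1), c(5L, 196L))
  expect_equal(dim(f$f3), c(5L, 392L))
  h2 <- histogram_features(encode_segment(segs[[2]]))
  expect_equal(unname(f$f1[2, ]), unname(h2$f1))
  expect_identical(f, dmpat_features(segs))   # deterministic
  expect_error(dmpat_features(list(segs[[1]], matrix(0, 3, 10))),
               "inconsistent")
})
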