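test_that("bit packing round-trips and keeps canonical padding", {
  set.seed(101)
  for (s in c(1L, 7L, 8L, 9L, 63L, 64L, 65L, sample(2:200, 10))) {
    bits <- sample(0:1, s, replace = TRUE)
    x <- bitseq(bits)
    expect_identical(as_bits(x), as.integer(bits))
    expect_identical(n_markers(x), s)
    # bits beyond s are zero: AND with the pad mask is the identity
    expect_identical(as.vector(unclass(x) & sarg:::pad_mask(s)),
                     as.vector(unclass(x)))
  }
})

test_that("hamming distance matches the per-bit oracle and is a pseudometric", {
  expect_identical(hamming_distance(bitseq(c(1, 0, 1)), bitseq(c(1, 0, 1))), 0L)
  expect_identical(hamming_distance(bitseq(c(1, 1, 1, 0, 0, 0)),
                                    bitseq(c(0, 0, 0, 1, 1, 1))), 6L)
  expect_error(hamming_distance(bitseq(c(1, 0)), bitseq(c(1, 0, 1))),
               "different marker counts")
  set.seed(102)
  for (i in 1:25) {
    s <- sample(1:64, 1)
    a <- bitseq(sample(0:1, s, TRUE)); b <- bitseq(sample(0:1, s, TRUE))
    cc <- bitseq(sample(0:1, s, TRUE))
    expect_identical(hamming_distance(a, b), naive_hamming(a, b))
    expect_identical(hamming_distance(a, b), hamming_distance(b, a))
    expect_lte(hamming_distance(a, cc),
               hamming_distance(a, b) + hamming_distance(b, cc))
  }
})

test_that("left distance is the first-marker restriction of hamming", {
  expect_identical(left_distance(bitseq(c(1, 0)), bitseq(c(1, 1))), 0L)
  expect_identical(left_distance(bitseq(0), bitseq(1)), 1L)
  expect_error(left_distance(bitseq(logical(0)), bitseq(logical(0))),
               "at least one marker")
  set.seed(103)
  for (i in 1:20) {
    s <- sample(1:40, 1)
    a <- bitseq(sample(0:1, s, TRUE)); b <- bitseq(sample(0:1, s, TRUE))
    expect_identical(left_distance(a, b),
                     hamming_distance(bitseq(as_bits(a)[1]), bitseq(as_bits(b)[1])))
  }
})

test_that("biased distance handles the 0 and Inf conventions", {
  mL <- metric("left", c0 = Inf)
  # equal first markers: distance 0 regardless of the infinite bias,
  # so the pairing weight is exp(coal_log_weight(0, mu)) = 1
  d0 <- biased_distance(mL, bitseq(c(1, 0, 1)), bitseq(c(1, 1, 1)))
  expect_identical(d0, 0)
  expect_identical(coal_log_weight(d0, mu = 0.5), 0)
  # differing first markers: weight 0
  expect_identical(biased_distance(mL, bitseq(c(0, 1)), bitseq(c(1, 1))), Inf)
  expect_identical(coal_log_weight(Inf, mu = 0.5), -Inf)
  m0 <- metric("hamming", c0 = 0)
  expect_identical(biased_distance(m0, bitseq(c(0, 1)), bitseq(c(1, 0))), 0)
  m2 <- metric("hamming", c0 = 2)
  expect_identical(biased_distance(m2, bitseq(c(1, 1, 1)), bitseq(c(0, 0, 0))), 6)
})

test_that("masked_xor matches the per-bit loop and masking is monotone", {
  expect_identical(as_bits(masked_xor(bitseq(c(1, 1, 0)), bitseq(c(1, 0, 0)),
                                      bitseq(c(0, 1, 0)))),
                   c(0L, 1L, 0L))
  z <- masked_xor(bitseq(c(1, 0, 1)), bitseq(c(1, 0, 1)), bitseq(c(1, 1, 1)))
  expect_identical(seq_popcount(z), 0L)
  set.seed(104)
  for (i in 1:25) {
    s <- sample(1:80, 1)
    p <- sample(0:1, s, TRUE); ch <- sample(0:1, s, TRUE); mk <- sample(0:1, s, TRUE)
    got <- as_bits(masked_xor(bitseq(p), bitseq(ch), bitseq(mk)))
    expect_identical(got, as.integer((p != ch) & mk))
    # masked mutation count never exceeds the unmasked count
    expect_lte(sum(got), sum(p != ch))
  }
})

test_that("interval_mask sets exactly the bits whose positions fall in omega", {
  pos <- c(10, 20, 30, 40, 50)
  expect_identical(as_bits(interval_mask(pos, iset(0, 100))), rep(1L, 5))
  expect_identical(as_bits(interval_mask(pos, iset_empty())), rep(0L, 5))
  # half-open [pos[3], pos[5]): markers 3 and 4 only
  m <- interval_mask(pos, iset(pos[3], pos[5]))
  expect_identical(as_bits(m), c(0L, 0L, 1L, 1L, 0L))
  set.seed(105)
  for (i in 1:10) {
    iv <- random_iset(60, 2)
    expect_identical(as_bits(interval_mask(pos, iv)),
                     as.integer(vapply(pos, function(p) iset_contains(iv, p),
                                       logical(1))))
  }
})
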