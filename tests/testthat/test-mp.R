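test_that("snr_db follows its definition and limit conventions", {
  x <- c(1, 2, 3)
  expect_equal(snr_db(x, x), 0)
  expect_equal(snr_db(x, x / sqrt(10)), 10)  # energy ratio 10 -> 10 dB
  expect_identical(snr_db(x, c(0, 0, 0)), Inf)
  expect_error(snr_db(c(0, 0), c(1, 1)), "zero input")
})

test_that("a dictionary atom is recovered in a single iteration", {
  d <- build_dictionary(64, "db8")
  x <- wp_atom(d, 3, 2, 5)
  r <- mp_decompose(x, d, snr_stop_db = 15)
  expect_equal(r$n_iter, 1)
  expect_equal(r$atoms$coefficient, 1, tolerance = 1e-10)
  expect_equal(r$atoms[1, c("level", "node", "translate")],
               data.frame(level = 3L, node = 2L, translate = 5L),
               ignore_attr = TRUE)
  expect_lt(sum(r$residual^2), 1e-18)
  expect_identical(r$stop_reason, "zero_residual")
})

test_that("orthogonal-level composites are recovered greedily in order", {
  d <- build_dictionary(64, "db8")
  a1 <- wp_atom(d, 4, 1, 0)
  a2 <- wp_atom(d, 4, 6, 3)
  r <- mp_decompose(1.0 * a1 + 0.5 * a2, d, snr_stop_db = 100)
  expect_equal(r$n_iter, 2)
  expect_equal(r$atoms$coefficient, c(1.0, 0.5), tolerance = 1e-10)
  expect_equal(r$atoms$node, c(1, 6))
  # three-component composite from one orthogonal level
  a3 <- wp_atom(d, 4, 11, 1)
  r3 <- mp_decompose(2 * a1 + 1.5 * a2 + 0.7 * a3, d, snr_stop_db = 200)
  expect_equal(r3$n_iter, 3)
  expect_equal(sort(r3$atoms$coefficient, decreasing = TRUE),
               c(2, 1.5, 0.7), tolerance = 1e-10)
})

test_that("full trace matches the brute-force explicit-matrix oracle", {
  n <- 64
  d <- build_dictionary(n, "db8")
  dmat <- oracle_dictionary_matrix(n, "db8")
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(n)
    mine <- mp_decompose(x, d, snr_stop_db = 15, max_iter = 100)
    ref <- oracle_mp(x, dmat, snr_stop_db = 15, max_iter = 100)
    rows <- atom_row_index(n, mine$atoms$level, mine$atoms$node,
                           mine$atoms$translate)
    expect_identical(rows, ref$rows)
    expect_equal(mine$atoms$coefficient, ref$coefs, tolerance = 1e-9)
  }
})

test_that("energy is conserved at every iteration and SNR is monotone", {
  set.seed(32)
  d <- build_dictionary(128, "db8")
  x <- rnorm(128)
  r <- mp_decompose(x, d, snr_stop_db = 20, max_iter = 50)
  res <- x
  energies <- numeric(r$n_iter)
  for (i in seq_len(r$n_iter)) {
    e_before <- sum(res^2)
    atom <- wp_atom(d, r$atoms$level[i], r$atoms$node[i],
                    r$atoms$translate[i])
    res <- res - r$atoms$coefficient[i] * atom
    e_after <- sum(res^2)
    expect_equal(e_before, r$atoms$coefficient[i]^2 + e_after,
                 tolerance = 1e-9)
    energies[i] <- e_after
  }
  expect_true(all(diff(energies) <= 1e-12))
  expect_true(all(diff(r$atoms$snr_db) >= -1e-9))
})

test_that("reconstruction plus residual restores the input", {
  set.seed(33)
  d <- build_dictionary(128, "db8")
  x <- rnorm(128) + sin(2 * pi * (0:127) / 16)
  r <- mp_decompose(x, d, snr_stop_db = 15)
  rec <- reconstruct(r)
  expect_lt(sqrt(sum((x - rec - r$residual)^2) / sum(x^2)), 1e-9)
  expect_gte(snr_db(x, x - rec), 15)
  bogus <- r
  bogus$atoms$level[1] <- 99
  expect_error(reconstruct(bogus), "atom index")
  empty <- r
  empty$atoms <- r$atoms[0, ]
  expect_equal(reconstruct(empty), numeric(128))
})

test_that("mp_decompose rejects zero input and caps iterations", {
  d <- build_dictionary(64, "db8")
  expect_error(mp_decompose(numeric(64), d), "zero input")
  set.seed(34)
  r <- mp_decompose(rnorm(64), d, snr_stop_db = 500, max_iter = 3)
  expect_equal(r$n_iter, 3)
  expect_identical(r$stop_reason, "max_iter")
})

test_that("natom counts iterations and pads non-dyadic lengths", {
  d <- build_dictionary(64, "db8")
  expect_equal(natom_feature(wp_atom(d, 2, 1, 3)), 1)
  expect_length(pad_to_pow2(numeric(100)), 128)
  expect_identical(pad_to_pow2(numeric(64)), numeric(64))
  set.seed(35)
  x <- rnorm(100)  # padded internally to 128
  expect_gte(natom_feature(x, snr_stop_db = 10), 1)
})
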