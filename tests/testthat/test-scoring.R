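test_that("identical columns reach the environmental score ceiling for
           any delta", {
  set.seed(31)
  v <- matrix(runif(5 * 4), 5, 4,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:4)))
  v[, 2] <- v[, 1]
  m <- as_clag_matrix(v)
  d <- extract_distribution(m)
  for (delta in c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)) {
    g <- build_grids(d, delta)
    es <- environmental_score("c1", "c2", m, g)
    expect_equal(es$s_env, 1)
    expect_length(es$diff_set, 0L)
  }
})

test_that("binary matrices score by plain equality of entries", {
  v <- cbind(a = c(0, 0, 1, 1), b = c(1, 1, 0, 0), c = c(0, 0, 1, 0))
  rownames(v) <- paste0("x", 1:4)
  m <- as_clag_matrix(v)
  expect_true(m$is_binary)
  d <- extract_distribution(m)
  g <- build_grids(d, 0.2)
  ab <- environmental_score("a", "b", m, g)
  expect_equal(ab$k_close, 0L)
  expect_equal(ab$s_env, -1)
  expect_setequal(ab$diff_set, paste0("x", 1:4))
  ac <- environmental_score("a", "c", m, g)
  expect_equal(ac$k_close, 3L)
  expect_equal(ac$diff_set, "x4")
})

test_that("hand-placed entries hit the stated symmetric-score cases", {
  # 10x10 square matrix, 90 distinct off-diagonal values; rank == index
  # in the value pool. delta = 0.2, T = 90, q = 18:
  #   0-grid ranks 1-18 | 19-36 | 37-54 | 55-72 | 73-90
  #   1-grid ranks 1-9 | 10-27 | 28-45 | 46-63 | 64-81 | 82-90
  pool <- (seq_len(90) - 0.5) / 90
  labs <- paste0("e", 1:10)
  v <- matrix(0, 10, 10, dimnames = list(labs, labs))
  off <- which(row(v) != col(v))
  # ranks 1,2 at (e3,e4)/(e4,e3): same first 0-grid interval -> raw 0
  # ranks 15,22 at (e1,e2)/(e2,e1): different 0-grid intervals but both
  # in the second 1-grid interval -> raw 2*1+1 = 3
  v["e1", "e2"] <- pool[15]; v["e2", "e1"] <- pool[22]
  v["e3", "e4"] <- pool[1];  v["e4", "e3"] <- pool[2]
  rest <- setdiff(off, c(which(row(v) == 1 & col(v) == 2),
                         which(row(v) == 2 & col(v) == 1),
                         which(row(v) == 3 & col(v) == 4),
                         which(row(v) == 4 & col(v) == 3)))
  v[rest] <- pool[-c(15, 22, 1, 2)]
  diag(v) <- 0.5
  m <- as_clag_matrix(v)
  expect_true(m$is_square)
  d <- extract_distribution(m, symmetric_mode = TRUE)
  expect_equal(d$T, 90L)
  g <- build_grids(d, 0.2)
  s12 <- symmetric_score("e1", "e2", m, g)
  expect_equal(s12$s_sym_raw, 3L)
  expect_equal(s12$s_sym, 2 * 3 / (2 * 5 - 1) - 1)
  s34 <- symmetric_score("e3", "e4", m, g)
  expect_equal(s34$s_sym_raw, 0L)
  expect_equal(s34$s_sym, -1)
  # far-apart entry pairs leave the symmetric score undefined
  sc <- score_all_pairs(m, g, symmetric_mode = TRUE)
  expect_true(anyNA(sc$s_sym_raw))
})

test_that("pair scores match the brute-force oracle on random matrices", {
  set.seed(41)
  for (i in 1:40) {
    square <- i %% 2 == 0
    binary <- i %% 5 == 0
    m <- if (square) random_clag_matrix(7, 7, square = TRUE,
                                        binary = binary)
         else random_clag_matrix(sample(4:7, 1), sample(4:7, 1),
                                 binary = binary)
    delta <- sample(c(0.1, 0.2, 0.25), 1)
    d <- extract_distribution(m, symmetric_mode = square)
    g <- build_grids(d, delta)
    sc <- score_all_pairs(m, g, symmetric_mode = square)
    recs <- oracle_pair_scores(m, delta, symmetric = square)
    expect_equal(nrow(sc), length(recs))
    for (j in seq_along(recs)) {
      r <- recs[[j]]
      row <- sc[sc$v == r$v & sc$z == r$z]
      expect_equal(row$k_close, r$K,
                   info = sprintf("iter %d pair %d-%d", i, r$v, r$z))
      expect_setequal(
        m$character_labels[clagr:::decode_diff(row$diff_key,
                                               nrow(m$values))],
        r$diff)
      if (square)
        expect_equal(row$s_sym_raw, r$sraw,
                     info = sprintf("iter %d sym %d-%d", i, r$v, r$z))
    }
  }
})

test_that("score bookkeeping invariants hold on random matrices", {
  set.seed(51)
  for (i in 1:10) {
    m <- random_clag_matrix(6, 8)
    d <- extract_distribution(m)
    g <- build_grids(d, 0.15)
    sc <- score_all_pairs(m, g)
    expect_equal(nrow(sc), choose(8, 2))
    M <- nrow(m$values)
    ndiff <- vapply(sc$diff_key, function(k)
      length(clagr:::decode_diff(k, M)), integer(1))
    expect_equal(sc$k_close + unname(ndiff), rep(M, nrow(sc)))
    expect_equal(sc$s_env, 2 * sc$k_close / M - 1)
    # the pair record is orientation-free by construction
    e12 <- environmental_score(1, 2, m, g)
    e21 <- environmental_score(2, 1, m, g)
    expect_equal(e12$k_close, e21$k_close)
    expect_setequal(e12$diff_set, e21$diff_set)
  }
})

test_that("symmetric score is undefined off square matrices and symmetric
           when defined", {
  m <- random_clag_matrix(5, 4)
  expect_error(symmetric_score(1, 2, m,
                               build_grids(extract_distribution(m), 0.2)),
               "square")
  set.seed(61)
  msq <- random_clag_matrix(6, 6, square = TRUE)
  d <- extract_distribution(msq, symmetric_mode = TRUE)
  g <- build_grids(d, 0.2)
  for (p in list(c(1, 2), c(3, 5), c(2, 6))) {
    a <- symmetric_score(p[1], p[2], msq, g)
    b <- symmetric_score(p[2], p[1], msq, g)
    expect_identical(a$s_sym_raw, b$s_sym_raw)
  }
})

test_that("diff-set encoding round-trips beyond one 40-bit chunk", {
  M <- 95L
  set.seed(71)
  for (i in 1:20) {
    idx <- sort(sample(M, sample(0:M, 1)))
    mask <- matrix(FALSE, M, 1)
    mask[idx, 1] <- TRUE
    key <- clagr:::encode_diff(mask, clagr:::diff_weights(M))
    expect_equal(clagr:::decode_diff(key, M), idx)
  }
})
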