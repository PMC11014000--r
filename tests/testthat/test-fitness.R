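# A wpt_packet with prescribed coefficients, for direct evaluation of the
# fitness statistics.
packet_with <- function(coefs, nodes = 1L) {
  structure(
    list(wavelet_name = "haar", level = as.integer(log2(nodes)),
         nodes = split(coefs, rep(seq_len(nodes), each = length(coefs) / nodes)),
         original_length = length(coefs), padded_length = length(coefs)),
    class = "wpt_packet"
  )
}

test_that("energy, probabilities and entropy match hand-computed values", {
  p <- packet_with(c(3, 4))
  expect_equal(level_energy(p), 25)
  expect_equal(energy_probabilities(p), c(9 / 25, 16 / 25))
  expect_equal(shannon_entropy(p), -(0.36 * log(0.36) + 0.64 * log(0.64)),
               tolerance = 1e-12)
  expect_equal(shannon_entropy(p), 0.6534177, tolerance = 1e-6)

  u <- packet_with(c(2, 2, 2, 2))
  expect_equal(energy_probabilities(u), rep(0.25, 4))
  expect_equal(shannon_entropy(u), log(4), tolerance = 1e-12)
  expect_equal(energy_entropy_ratio(packet_with(rep(1, 4))), 4 / log(4),
               tolerance = 1e-12)

  expect_equal(level_energy(packet_with(numeric(8))), 0)
})

test_that("probability normalization and entropy bounds hold on random packets", {
  set.seed(31)
  for (i in 1:50) {
    nm <- sample(candidate_wavelets(), 1)
    x <- rnorm(125) * 10^runif(1, -2, 2)
    p <- wpt_decompose(x, nm, 3)
    probs <- energy_probabilities(p)
    expect_lt(abs(sum(probs) - 1), 1e-12)
    expect_true(all(probs >= 0 & probs <= 1))
    s <- shannon_entropy(p)
    expect_gte(s, 0)
    expect_lte(s, log(p$padded_length) + 1e-12)
  }
})

test_that("a single nonzero coefficient gives zero entropy and an undefined ratio", {
  p <- packet_with(c(0, 0, 5, 0))
  expect_equal(shannon_entropy(p), 0)
  expect_error(energy_entropy_ratio(p), "undefined ratio",
               class = "mwselect_degenerate")
  expect_error(energy_probabilities(packet_with(numeric(4))),
               "degenerate", class = "mwselect_degenerate")
})

test_that("probabilities are scale invariant and the ratio obeys the a^2 law", {
  set.seed(41)
  x <- rnorm(125)
  for (a in c(0.1, 3, 9.80665)) {
    p1 <- wpt_decompose(x, "coif14", 3)
    p2 <- wpt_decompose(a * x, "coif14", 3)
    expect_equal(energy_probabilities(p2), energy_probabilities(p1),
                 tolerance = 1e-10)
    expect_equal(energy_entropy_ratio(p2), a^2 * energy_entropy_ratio(p1),
                 tolerance = 1e-8)
  }
})

test_that("fitness statistics agree with the coefficient-by-coefficient oracle", {
  set.seed(51)
  for (nm in c("haar", "db5", "coif14", "bior5.5")) {
    x <- rnorm(125)
    p <- wpt_decompose(x, nm, 3)
    ref <- oracle_fitness(unlist(p$nodes))
    expect_equal(level_energy(p), ref$energy, tolerance = 1e-10)
    expect_equal(shannon_entropy(p), ref$entropy, tolerance = 1e-10)
    expect_equal(energy_entropy_ratio(p), ref$ratio, tolerance = 1e-10)
  }
})

test_that("score_wavelet averages per-segment ratios over axes then segments", {
  seg1 <- make_test_segment(1)
  seg2 <- make_test_segment(2)
  xi_of <- function(seg) {
    mean(vapply(1:3, function(a) {
      energy_entropy_ratio(wpt_decompose(seg$samples[, a], "db5", 3))
    }, numeric(1)))
  }
  fr1 <- score_wavelet(list(seg1), "db5")
  expect_equal(fr1$mean_ratio, xi_of(seg1), tolerance = 1e-10)
  expect_identical(fr1$n_segments, 1L)

  fr12 <- score_wavelet(list(seg1, seg2), "db5")
  expect_equal(fr12$mean_ratio, (xi_of(seg1) + xi_of(seg2)) / 2,
               tolerance = 1e-10)
  # mean is idempotent under duplication
  fr_dup <- score_wavelet(list(seg1, seg2, seg1, seg2), "db5")
  expect_equal(fr_dup$mean_ratio, fr12$mean_ratio, tolerance = 1e-12)
})

test_that("degenerate segments are excluded with a warning, all-degenerate errors", {
  flat <- har_segment(matrix(0, 125, 3), "flat")
  good <- make_test_segment(3)
  expect_warning(fr <- score_wavelet(list(good, flat), "haar"), "degenerate")
  expect_identical(fr$n_segments, 1L)
  expect_identical(fr$n_degenerate, 1L)
  expect_error(suppressWarnings(score_wavelet(list(flat), "haar")),
               "all segments")
})

test_that("selection ranks by descending ratio with deterministic tie-break", {
  set.seed(61)
  segs <- lapply(1:6, function(i) make_test_segment(i, label = c("a", "b")[1 + i %% 2]))
  rep <- select_mother_wavelet(segs, candidates = c("haar", "db5", "coif14"))
  expect_s3_class(rep, "selection_report")
  expect_identical(rep$overall$rank, 1:3)
  expect_true(all(diff(rep$overall$mean_ratio) <= 0))
  expect_identical(rep$selected, rep$overall$wavelet[1])
  # per-activity tables cover both activities with full candidate sets
  expect_identical(sort(unique(rep$per_activity$activity)), c("a", "b"))
  expect_identical(nrow(rep$per_activity), 6L)
  # singleton candidate list selects that wavelet
  expect_identical(select_mother_wavelet(segs, "sym5")$selected, "sym5")
  expect_error(select_mother_wavelet(segs, character(0)), "empty")
})

test_that("rankings are invariant to the entropy log base and segment order", {
  set.seed(71)
  segs <- lapply(1:8, function(i) make_test_segment(i))
  cands <- c("haar", "db5", "sym18", "coif14", "rbio1.3")
  r_ln <- select_mother_wavelet(segs, cands)
  r_l2 <- select_mother_wavelet(segs, cands, base = 2)
  expect_identical(r_ln$overall$wavelet, r_l2$overall$wavelet)
  # every ratio rescales by the same constant, log(2)
  expect_equal(r_l2$overall$mean_ratio / r_ln$overall$mean_ratio,
               rep(log(2), length(cands)), tolerance = 1e-10)
  r_rev <- select_mother_wavelet(rev(segs), cands)
  expect_identical(r_rev$overall$wavelet, r_ln$overall$wavelet)
  expect_equal(r_rev$overall$mean_ratio, r_ln$overall$mean_ratio,
               tolerance = 1e-12)
})

test_that("signals built from sparse coif14 packets rank coif14 above haar", {
  wins <- 0L
  for (s in 1:20) {
    segs <- matched_wavelet_signals("coif14", n_signals = 8, sparsity = 2,
                                    noise_sd = 0.02, seed = s)
    r_c <- score_wavelet(segs, "coif14")$mean_ratio
    r_h <- score_wavelet(segs, "haar")$mean_ratio
    wins <- wins + (r_c > r_h)
  }
  expect_gte(wins, 18L)
})

test_that("selection report round-trips through its delimited export", {
  segs <- lapply(1:4, function(i) make_test_segment(i, label = "a"))
  rep <- select_mother_wavelet(segs, c("haar", "db5"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_selection_report(rep, path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("wavelet", "activity", "mean_energy",
                                 "mean_entropy", "mean_ratio", "n_segments",
                                 "rank"))
  expect_identical(nrow(tab), 4L)  # overall + one activity, 2 candidates each
})
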