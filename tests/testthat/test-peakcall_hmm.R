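# Simulate observations from a known 2-state NB HMM.
sim_hmm_track <- function(n, mu = c(2, 30), alpha = c(0.05, 0.05),
                          stay = c(0.99, 0.95), seed = 1) {
  set.seed(seed)
  st <- integer(n); st[1] <- 1L
  for (t in 2:n)
    st[t] <- if (runif(1) < stay[st[t - 1]]) st[t - 1] else 3L - st[t - 1]
  x <- rnbinom(n, mu = mu[st], size = 1 / alpha[st])
  list(track = mk_track(x), states = st)
}

test_that("Baum-Welch recovers well-separated emission means", {
  s <- sim_hmm_track(500, seed = 11)  # 50 kb of 100 bp bins
  fit <- fit_hmm(s$track)
  expect_lt(abs(fit$emission$mu[1] - 2) / 2, 0.10)
  expect_lt(abs(fit$emission$mu[2] - 30) / 30, 0.10)
  expect_gt(fit$emission$mu[2], fit$emission$mu[1])
  expect_equal(rowSums(fit$A), c(1, 1), tolerance = 1e-9)
})

test_that("degenerate tracks are flagged", {
  expect_error(fit_hmm(mk_track(rep(0, 200))), "all zero")
  expect_error(fit_hmm(mk_track(rep(5, 200))), "constant")
  expect_error(fit_hmm(mk_track(rep(1, 50))), "100 unmasked")
})

test_that("fit is independent across chromosomes", {
  s1 <- sim_hmm_track(400, seed = 3)$track
  s2 <- sim_hmm_track(400, seed = 4)$track
  two <- function(a, b) {
    cs <- c(chrA = 40000L, chrB = 40000L)
    binned_track(list(chrA = a$values$chr1, chrB = b$values$chr1), 100L, cs)
  }
  f12 <- fit_hmm(two(s1, s2))
  f21 <- fit_hmm(two(s2, s1))
  expect_equal(f12$emission$mu, f21$emission$mu, tolerance = 1e-6)
})

test_that("viterbi handles trivial inputs and symmetries", {
  params <- rloopshift:::new_hmm_params(
    c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
    list(type = "nb", mu = c(1, 20), alpha = c(0.1, 0.1)))
  expect_identical(viterbi(params, numeric(0)), integer(0))
  expect_true(all(viterbi(params, rep(0, 50)) == 1L))
  expect_true(all(viterbi(params, rep(40, 50)) == 2L))
  post <- state_posterior(params, c(0, 1, 30, 25, 0))
  expect_equal(rowSums(post), rep(1, 5), tolerance = 1e-10)
})

test_that("decoding recovers a planted block and its trailing tail", {
  set.seed(9)
  n <- 2000
  x <- rnbinom(n, mu = 2, size = 20)
  # planted 2 kb block at 20x background (bins 501-520), plus replicas so
  # the fit sees enough peak mass
  for (s0 in c(500, 1000, 1500))
    x[(s0 + 1):(s0 + 20)] <- rnbinom(20, mu = 40, size = 20)
  tr <- mk_track(x)
  fit <- fit_hmm(tr)
  pk <- decode_peaks(fit, tr, mode = "standard")
  planted <- GRanges("chr1", IRanges(50001, 52000))
  hit <- pk[IRanges::overlapsAny(pk, planted)]
  expect_length(hit, 1L)
  expect_gte(jaccard_vs(planted, hit), 0.8)

  # containment: every standard peak inside some high-sensitivity peak
  hs0 <- decode_peaks(fit, tr, mode = "high_sensitivity")
  ov <- findOverlaps(pk, hs0, type = "within")
  expect_equal(length(unique(queryHits(ov))), length(pk))
})

test_that("a low trailing shoulder is captured by lowering p_tail", {
  # Deterministic construction: a strong 2 kb block followed by a 2 kb
  # shoulder whose per-bin log odds hover just below zero. Viterbi cuts
  # near the block edge; the posterior decays slowly, so extending through
  # bins above a sub-0.5 tail threshold reaches far into the shoulder.
  params <- rloopshift:::new_hmm_params(
    c(0.95, 0.05), matrix(c(0.995, 0.005, 0.03, 0.97), 2, 2, byrow = TRUE),
    list(type = "nb", mu = c(2, 15), alpha = c(1, 1)), bin_width = 100L)
  y <- rep(1, 1000)
  y[301:320] <- 25
  y[321:340] <- rep(c(5, 5, 5, 4), 5)
  tr <- mk_track(y)
  std <- decode_peaks(params, tr, mode = "standard")
  hs <- decode_peaks(params, tr, mode = "high_sensitivity", p_tail = 0.3)
  expect_gte(max(end(hs)), max(end(std)) + 500)
  # default p_tail still never reaches less far than the standard call
  hs_def <- decode_peaks(params, tr, mode = "high_sensitivity")
  expect_gte(max(end(hs_def)), max(end(std)))
  ov <- findOverlaps(std, hs_def, type = "within")
  expect_equal(length(unique(queryHits(ov))), length(std))
})

test_that("zero-coverage decoding yields no peaks", {
  params <- rloopshift:::new_hmm_params(
    c(0.9, 0.1), matrix(c(0.99, 0.01, 0.05, 0.95), 2, 2, byrow = TRUE),
    list(type = "nb", mu = c(2, 30), alpha = c(0.05, 0.05)),
    bin_width = 100L)
  expect_length(decode_peaks(params, mk_track(rep(0, 500))), 0L)
})

test_that("lowering p_tail never shrinks high-sensitivity peaks", {
  set.seed(21)
  x <- rnbinom(1500, mu = 2, size = 20)
  for (s0 in seq(100, 1400, by = 250))
    x[(s0 + 1):(s0 + 15)] <- rnbinom(15, mu = 25, size = 20)
  tr <- mk_track(x)
  fit <- fit_hmm(tr)
  hi <- decode_peaks(fit, tr, mode = "high_sensitivity", p_tail = 0.6)
  lo <- decode_peaks(fit, tr, mode = "high_sensitivity", p_tail = 0.3)
  expect_gte(sum(width(lo)), sum(width(hi)))
  ov <- findOverlaps(hi, lo, type = "within")
  expect_equal(length(unique(queryHits(ov))), length(hi))
})

test_that("masked bins break the chain and are never called", {
  s <- sim_hmm_track(600, seed = 13)
  tr <- exclude_regions(s$track, GRanges("chr1", IRanges(20001, 25000)))
  fit <- fit_hmm(tr)
  pk <- decode_peaks(fit, tr, mode = "standard")
  if (length(pk))
    expect_false(any(IRanges::overlapsAny(
      pk, GRanges("chr1", IRanges(20001, 25000)))))
})

test_that("union peaks merge across samples per strand", {
  p1 <- GRanges("chr1", IRanges(101, 300), strand = "+")
  mcols(p1)$sample <- "a"
  p2 <- GRanges("chr1", IRanges(101, 300), strand = "+")
  mcols(p2)$sample <- "b"
  un <- union_peaks(list(p1, p2))
  expect_length(un, 1L)
  expect_equal(un$samples, "a,b")

  q2 <- GRanges("chr1", IRanges(1001, 1200), strand = "+")
  mcols(q2)$sample <- "b"
  expect_length(union_peaks(list(p1, q2)), 2L)

  # overlapping [100,300) and [250,500) give one union peak [100,500)
  r1 <- GRanges("chr1", IRanges(101, 300), strand = "+")
  mcols(r1)$sample <- "a"
  r2 <- GRanges("chr1", IRanges(251, 500), strand = "+")
  mcols(r2)$sample <- "b"
  un <- union_peaks(list(r1, r2))
  expect_equal(c(start(un), end(un)), c(101L, 500L))

  # strands kept apart
  m1 <- GRanges("chr1", IRanges(101, 300), strand = "-")
  mcols(m1)$sample <- "a"
  expect_length(union_peaks(list(p1, m1)), 2L)
})
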