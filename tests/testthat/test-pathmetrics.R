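# synthetic probe over k offsets with given pair-coherence curve and a
# shared 4-node coherence matrix per offset
mk_probe <- function(curve, n = 4, pair = c(1, 2), fill = 0.5) {
  offs <- seq(0, 2 * pi, length.out = length(curve) + 1)[-(length(curve) + 1)]
  coh_list <- lapply(curve, function(cv) {
    M <- matrix(fill, n, n); diag(M) <- 1
    M[pair[1], pair[2]] <- M[pair[2], pair[1]] <- cv
    M
  })
  probe_result(pair, offs, coh_list)
}

test_that("PSF is max minus min of the pair coherence curve", {
  expect_equal(psf(c(0.7, 0.7, 0.7)), 0)
  expect_equal(psf(c(0.2, 0.9, 0.5)), 0.7)
  expect_equal(psf(mk_probe(c(0.2, 0.9, 0.5, 0.4))), 0.7)
  expect_error(psf(0.3), "offsets")
  # invariant to offset reordering
  set.seed(12)
  x <- runif(16)
  expect_equal(psf(x), psf(sample(x)))
})

test_that("PA and its variants reproduce the worked arithmetic", {
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 0.8
  M[2, 3] <- M[3, 2] <- 0.5
  p <- c(1, 2, 3)
  expect_equal(pa(p, M), 0.4)
  expect_equal(pa_min(p, M), 0.5)
  expect_lte(pa(p, M), min(0.8, 0.5))
  M0 <- M; M0[2, 3] <- M0[3, 2] <- 0
  expect_equal(pa(p, M0), 0)
  # single-edge path: both variants give that edge's coherence
  expect_equal(pa(c(1, 2), M), 0.8)
  expect_equal(pa_min(c(1, 2), M), pa(c(1, 2), M))
  # uniform strengths 0.1 scale pa by 0.1
  C <- matrix(0.1, 3, 3) - diag(0.1, 3)
  expect_equal(pa_weighted(p, M, C), 0.04)
})

test_that("PPS is the PA range and bounded by the PA maximum", {
  expect_equal(pps(c(0.3, 0.3, 0.3)), 0)
  expect_equal(pps(c(0.1, 0.6)), 0.5)
  set.seed(13)
  for (rep in 1:20) {
    crv <- runif(8)
    expect_gte(pps(crv), 0)
    expect_lte(pps(crv), max(crv))
    expect_lte(pps(crv), 1)
  }
})

test_that("PSI detects mutual dominance and normalizes by square root", {
  pa1 <- c(0.8, 0.2); pa2 <- c(0.3, 0.6)
  expect_equal(psi(pa1, pa2), 0.5 * 0.4)
  expect_equal(psi_normalized(psi(pa1, pa2)), sqrt(0.2))
  # dominance of one path at every offset gives psi <= 0
  expect_lte(psi(c(0.9, 0.8), c(0.5, 0.5)), 0)
  expect_equal(psi(c(0.4, 0.4), c(0.4, 0.4)), 0)
  # symmetric under path exchange
  expect_equal(psi(pa1, pa2), psi(pa2, pa1))
  expect_equal(psi_normalized(-0.04), -0.2)
  expect_error(psi(c(1, 2), c(1, 2, 3)), "offsets")
})

test_that("metric bounds hold on fuzzed coherence inputs", {
  set.seed(14)
  for (rep in 1:50) {
    k <- sample(2:16, 1)
    curve <- runif(k)
    expect_true(psf(curve) >= 0 && psf(curve) <= 1)
    M <- matrix(runif(16), 4, 4)
    M <- (M + t(M)) / 2; diag(M) <- 1
    p <- sample(4)
    expect_true(pa(p, M) >= 0 && pa(p, M) <= 1)
    expect_true(pa_min(p, M) >= 0 && pa_min(p, M) <= 1)
    a1 <- runif(k); a2 <- runif(k)
    expect_gte(psi_normalized(psi(a1, a2)), -1)
    expect_lte(psi_normalized(psi(a1, a2)), 1)
  }
})

test_that("select_top_paths picks P1, an edge-disjoint P2, lexicographic ties", {
  paths <- list(c(1L, 2L, 4L), c(1L, 3L, 4L), c(1L, 4L))
  curves <- list(c(0.5, 0.5), c(0.3, 0.3), c(0.2, 0.2))
  top <- select_top_paths(paths, curves)
  expect_equal(top$p1, 1L)
  expect_equal(top$p2, 2L)  # 1>3>4 disjoint from 1>2>4; 1>4 also disjoint but weaker
  # single path: P2 absent
  top1 <- select_top_paths(paths[1], curves[1])
  expect_true(is.na(top1$p2))
  # exact tie: lexicographically smaller (earlier in enumeration order) wins
  top2 <- select_top_paths(paths, list(c(0.4, 0.4), c(0.4, 0.4), c(0.1, 0.1)))
  expect_equal(top2$p1, 1L)
  # no edge-disjoint candidate
  top3 <- select_top_paths(list(c(1L, 2L), c(2L, 1L)),
                           list(c(0.5, 0.5), c(0.4, 0.4)))
  expect_true(is.na(top3$p2))
})

test_that("phase alignment wraps into (-pi, pi] and is shift-invariant", {
  pr <- mk_probe(c(0.9, 0.2, 0.3, 0.4))  # pair coherence peaks at offset 0
  # PA curve peaking at the same offset: difference 0
  al <- phase_alignment(pr, pa_vals = c(0.8, 0.1, 0.1, 0.1))
  expect_equal(al$diff, 0)
  expect_false(al$flat)
  # argmaxes at 0 and pi: wrapped difference is +pi (not -pi)
  al2 <- phase_alignment(pr, pa_vals = c(0.1, 0.1, 0.8, 0.1))
  expect_equal(al2$diff, pi)
  # shifting both curves by the same offset leaves the difference unchanged
  pr3 <- mk_probe(c(0.4, 0.9, 0.2, 0.3))
  al3 <- phase_alignment(pr3, pa_vals = c(0.1, 0.8, 0.1, 0.1))
  expect_equal(al3$diff, al$diff)
  # flat curves are flagged
  al4 <- phase_alignment(pr, pa_vals = c(0.2, 0.2, 0.2, 0.2))
  expect_true(al4$flat)
})

test_that("probe_result validates offsets and pair_metrics assembles", {
  expect_error(probe_result(c(1, 1), 0, list(diag(2))))
  expect_error(probe_result(c(1, 2), c(0.5, 0.2), list(diag(2), diag(2))))
  con <- make_motif("chain_3node", 100)
  pr <- mk_probe(c(0.8, 0.3, 0.5, 0.6), n = 3, pair = c(1, 3), fill = 0.7)
  m <- pair_metrics(pr, con)
  expect_s3_class(m, "pair_metrics")
  expect_equal(m$psf, 0.5)
  expect_equal(m$n_paths, 1L)         # only 1>2>3 exists
  expect_equal(m$p1, c(1L, 2L, 3L))
  expect_null(m$p2)                   # nothing edge-disjoint
  expect_true(is.na(m$psi))
  expect_equal(m$pps1, 0)             # fill coherence constant across offsets
})

test_that("classification separates flat, selective and switching pairs", {
  mk <- function(pps1, psi, p1 = 1:2) {
    structure(list(pair = c(1L, 2L), psf = 0.1, n_paths = 2L, p1 = p1,
                   pps1 = pps1, psi = psi), class = "pair_metrics")
  }
  cls <- classify_pairs(list(mk(0.02, -0.1), mk(0.5, -0.2), mk(0.5, 0.3),
                             mk(0.02, NA)))
  expect_equal(as.character(cls), c("flat", "selective", "switching", "flat"))
})
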