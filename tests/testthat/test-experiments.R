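# desk-scale settings keep these runs to seconds; physics-level assertions
# live in test-acceptance.R
short_cfg <- function(seed = 1) sim_config(duration = 25, transient = 5,
                                           seed = seed)

test_that("pair_probe returns one coherence matrix per offset, seeds matched", {
  con <- make_motif("bi_2node", 100)
  pr <- pair_probe(con, c(1, 2), offsets = 0, cfg = short_cfg())
  expect_s3_class(pr, "probe_result")
  expect_length(pr$coh_list, 1)
  expect_equal(dim(pr$coh_list[[1]]), c(2, 2))
  # rerunning reproduces bit-exactly (matched noise seeds across offsets)
  pr2 <- pair_probe(con, c(1, 2), offsets = 0, cfg = short_cfg())
  expect_identical(pr$coh_list, pr2$coh_list)
  expect_error(pair_probe(con, c(2, 2)))
})

test_that("all_pairs_probe probes each pair once and tabulates", {
  con <- make_motif("chain_3node", 90)
  res <- all_pairs_probe(con, offsets = c(0, pi), cfg = short_cfg(),
                         c_ext = 0.1)
  expect_equal(nrow(res$table), 3)  # 3 unordered pairs
  expect_setequal(paste(res$table$i, res$table$j),
                  c("1 2", "1 3", "2 3"))
  expect_true(all(res$table$psf >= 0 & res$table$psf <= 1))
  # explicit pair subset restricts rows
  res1 <- all_pairs_probe(con, pairs = rbind(c(1L, 3L)),
                          offsets = c(0, pi), cfg = short_cfg(), c_ext = 0.1)
  expect_equal(nrow(res1$table), 1)
  expect_equal(res1$table$p1, "1>2>3")
})

test_that("single-driver sweep separates driven node from chance level", {
  con <- synth_connectome(5, 0.5, seed = 7)
  sw <- single_driver_sweep(con, freqs = 11, strengths = c(0, 4),
                            placements = c(1, 3), cfg = short_cfg(),
                            center_on_driver = TRUE)
  expect_equal(nrow(sw), 2)
  z <- sw[sw$strength == 0, ]
  s <- sw[sw$strength == 4, ]
  # zero-strength driver: coherence to the network at chance level
  expect_lt(z$coh_network, 0.4)
  # strong on-frequency driver: driven node exceeds the network average
  expect_gt(s$coh_stimulated, s$coh_network)
  expect_gt(s$coh_stimulated, 0.8)
  expect_true(all(sw$kuramoto >= 0 & sw$kuramoto <= 1))
})

test_that("driver at a node with no connections flags the neighbor average", {
  C <- matrix(0, 3, 3); C[1, 2] <- C[2, 1] <- 0.1
  L <- matrix(0, 3, 3); L[1, 2] <- L[2, 1] <- 50; L[1, 3] <- L[3, 1] <- 50
  L[2, 3] <- L[3, 2] <- 50
  con <- connectome(C, L)
  sw <- single_driver_sweep(con, freqs = 11, strengths = 1, placements = 3,
                            cfg = short_cfg())
  expect_true(is.nan(sw$coh_neighbors) || is.na(sw$coh_neighbors))
})

test_that("fc_fit recovers r = 1 when the reference is the model's own FC", {
  con <- synth_connectome(5, 0.5, seed = 7)
  cfg <- short_cfg(seed = 21)
  ref_ts <- simulate(con, global_coupling(14, 2.6), noise = noise_spec(),
                     cfg = cfg)
  ref <- coherence_matrix(bandpass_analytic(ref_ts))
  fit <- fc_fit(con, ref, c_net_grid = c(7, 14), v_grid = 2.6, cfg = cfg)
  expect_equal(fit$best$c_net, 14)
  expect_equal(fit$best$r, 1)
  # permuted reference decorrelates
  set.seed(3)
  perm <- sample(5)
  fitp <- fc_fit(con, ref[perm, perm], c_net_grid = 14, v_grid = 2.6,
                 cfg = cfg)
  expect_lt(fitp$surface$r, 0.9)
  expect_error(fc_fit(con, matrix(0.5, 5, 5), c_net_grid = 14, v_grid = 2.6,
                      cfg = cfg), "degenerate")
})

test_that("structure summary computes the stated Pearson correlations", {
  con <- make_motif("chain_3node", 90)
  tab <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                    psf = c(0.4, 0.1, 0.3))
  s <- psf_structure_summary(tab, con)
  expect_equal(s$table$hops, c(1, 2, 1))
  expect_equal(s$table$length_mm, c(22.5, 90, 67.5))
  expect_equal(s$table$dijkstra, c(10, 20, 10))
  # hand-computed Pearson r between hops and log(psf)
  expect_equal(unname(s$correlations["hops"]),
               cor(c(1, 2, 1), log(c(0.4, 0.1, 0.3))))
  # adding a constant to all distances leaves r unchanged (cor invariance)
  expect_equal(unname(s$correlations["length_mm"]),
               cor(c(22.5, 90, 67.5) + 5, log(c(0.4, 0.1, 0.3))))
  # zero-variance cases reported as NA
  s2 <- psf_structure_summary(tab[c(1, 3), ], con)
  expect_true(is.na(s2$correlations["hops"]))
  # PSF = 0 rows excluded from the log with a count
  tab$psf[2] <- 0
  s3 <- psf_structure_summary(tab, con)
  expect_equal(s3$n_excluded, 1L)
})

test_that("metric tables and summaries round-trip through CSV/JSON", {
  con <- make_motif("chain_3node", 90)
  res <- all_pairs_probe(con, offsets = c(0, pi), cfg = short_cfg(),
                         c_ext = 0.1)
  stem <- file.path(tempdir(), "probe_out")
  write_metrics(res, stem)
  write_pa_curves(res, stem)
  tab <- read.csv(paste0(stem, "_pairs.csv"))
  expect_equal(nrow(tab), 3)
  expect_true(all(c("psf", "pps1", "psi_norm", "class") %in% names(tab)))
  smry <- jsonlite::read_json(paste0(stem, "_summary.json"))
  expect_equal(smry$n_pairs, 3)
  crv <- read.csv(paste0(stem, "_pa_curves.csv"))
  expect_equal(sort(unique(crv$offset)), c(0, pi))
  expect_true(all(crv$rank %in% 1:2))
})
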