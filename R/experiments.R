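# Protocol orchestration: single-driver sweeps, pairwise phase probing,
# functional-connectivity grid fitting, and structural summaries of the
# facilitation effect.

#' Probe one node pair over stimulation phase offsets
#'
#' Runs one simulation per phase offset with two 11 Hz drivers on the pair,
#' the first at phase 0 and the second at the offset, and computes the full
#' coherence matrix per offset.  The noise seed is identical across offsets
#' so that the offset is the only varied factor.
#'
#' @param connectome A [connectome()].
#' @param pair Integer length-2 node indices.
#' @param offsets Phase offsets (rad), default 16 equally spaced in
#'   `[0, 2 pi)`.
#' @param cfg A [sim_config()]; `cfg$seed` is reused for every offset.
#' @param coupling,noise,params Passed to [simulate()].
#' @param f_ext,c_ext Driver frequency (Hz) and amplitude (mV).
#' @param center,halfwidth Analysis band (Hz), see [bandpass_analytic()].
#' @param weighted Amplitude-weighted coherence estimator flag.
#' @return A [probe_result()].
#' @export
pair_probe <- function(connectome, pair,
                       offsets = seq(0, 2 * pi, length.out = 17)[-17],
                       cfg = sim_config(seed = 1),
                       coupling = global_coupling(), noise = noise_spec(),
                       params = jr_params(), f_ext = 11, c_ext = 0.5,
                       center = 10, halfwidth = 2, weighted = FALSE) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  coh_list <- lapply(offsets, function(dphi) {
    stim <- stimulus_spec(targets = pair, f_ext = f_ext, c_ext = c_ext,
                          phases = c(0, dphi))
    ts <- simulate(connectome, coupling, stim, noise, cfg, params)
    coherence_matrix(bandpass_analytic(ts, center, halfwidth),
                     weighted = weighted)
  })
  probe_result(pair, offsets, coh_list)
}

#' Probe all (or a subset of) node pairs and tabulate pathway metrics
#'
#' Runs [pair_probe()] for every pair and [pair_metrics()] on each result.
#' Per-pair failures are caught, flagged and skipped.
#'
#' @inheritParams pair_probe
#' @param pairs Optional 2-column matrix of node-index pairs; defaults to
#'   all unordered pairs.
#' @param max_edges Pathway edge cap for PA evaluation.
#' @param progress Print one line per pair.
#' @param ... Further arguments to [pair_probe()].
#' @return List with `metrics` (list of `pair_metrics`), `table` (one row
#'   per pair: psf, n_paths, pps1, psi, psi_norm, alignment1, class, p1,
#'   p2), and `probes` (the probe results).
#' @export
all_pairs_probe <- function(connectome, pairs = NULL,
                            offsets = seq(0, 2 * pi, length.out = 17)[-17],
                            cfg = sim_config(seed = 1), max_edges = 4,
                            progress = FALSE, ...) {
  if (is.null(pairs))
    pairs <- t(utils::combn(connectome$n, 2))
  metrics <- vector("list", nrow(pairs))
  probes <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pr <- tryCatch(
      pair_probe(connectome, pairs[k, ], offsets = offsets, cfg = cfg, ...),
      error = function(e) e)
    if (inherits(pr, "error")) {
      warning(sprintf("pair (%d, %d) failed: %s", pairs[k, 1], pairs[k, 2],
                      conditionMessage(pr)))
      next
    }
    probes[[k]] <- pr
    metrics[[k]] <- pair_metrics(pr, connectome, max_edges = max_edges)
    if (progress)
      message(sprintf("pair %d/%d (%d, %d): PSF = %.3f", k, nrow(pairs),
                      pairs[k, 1], pairs[k, 2], metrics[[k]]$psf))
  }
  ok <- !vapply(metrics, is.null, logical(1))
  metrics <- metrics[ok]; probes <- probes[ok]
  tab <- metrics_table(metrics)
  list(metrics = metrics, table = tab, probes = probes)
}

#' Flatten pair metrics into a data.frame
#'
#' @param metrics_list List of `pair_metrics` from [pair_metrics()].
#' @param labels Optional node labels for naming paths.
#' @return One row per pair.
#' @export
metrics_table <- function(metrics_list, labels = NULL) {
  fmt_path <- function(p) {
    if (is.null(p)) return(NA_character_)
    if (!is.null(labels)) p <- labels[p]
    paste(p, collapse = ">")
  }
  df <- data.frame(
    i = vapply(metrics_list, function(m) m$pair[1], integer(1)),
    j = vapply(metrics_list, function(m) m$pair[2], integer(1)),
    psf = vapply(metrics_list, function(m) m$psf, numeric(1)),
    n_paths = vapply(metrics_list, function(m) m$n_paths, integer(1)),
    pps1 = vapply(metrics_list, function(m) m$pps1, numeric(1)),
    psi = vapply(metrics_list, function(m) m$psi, numeric(1)),
    psi_norm = vapply(metrics_list, function(m) m$psi_norm, numeric(1)),
    alignment1 = vapply(metrics_list, function(m) m$alignment1, numeric(1)),
    p1 = vapply(metrics_list, function(m) fmt_path(m$p1), character(1)),
    p2 = vapply(metrics_list, function(m) fmt_path(m$p2), character(1)),
    stringsAsFactors = FALSE)
  df$class <- as.character(classify_pairs(metrics_list))
  df
}

#' Single-driver frequency-by-strength sweep
#'
#' For each grid cell one node is driven by a single sinusoid and the
#' coherence of the driver (as a virtual node) to (a) the whole network,
#' (b) the direct neighbors of the driven node, and (c) the driven node
#' itself is measured, along with the network Kuramoto order parameter.
#' Results are averaged over the given stimulus placements.
#'
#' @param connectome A [connectome()].
#' @param freqs Driver frequencies (Hz).
#' @param strengths Driver amplitudes (mV).
#' @param placements Nodes to drive (averaged over); defaults to all nodes.
#' @param cfg,coupling,noise,params As in [simulate()].
#' @param center_on_driver Band-pass around the driver frequency (TRUE) or
#'   the fixed 10 Hz band (FALSE).
#' @param halfwidth Analysis half-band (Hz).
#' @return data.frame: one row per (freq, strength) with columns
#'   `coh_network`, `coh_neighbors`, `coh_stimulated`, `kuramoto`.
#' @export
single_driver_sweep <- function(connectome, freqs = c(6, 11, 16),
                                strengths = c(0.25, 1, 4),
                                placements = seq_len(connectome$n),
                                cfg = sim_config(seed = 1),
                                coupling = global_coupling(),
                                noise = noise_spec(), params = jr_params(),
                                center_on_driver = TRUE, halfwidth = 2) {
  und <- (connectome$C > 0) | t(connectome$C > 0)
  grid <- expand.grid(freq = freqs, strength = strengths)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    f <- grid$freq[g]; a <- grid$strength[g]
    acc <- matrix(NA_real_, length(placements), 4)
    for (pi_ in seq_along(placements)) {
      node <- placements[pi_]
      stim <- stimulus_spec(targets = node, f_ext = f, c_ext = a)
      ts <- simulate(connectome, coupling, stim, noise, cfg, params,
                     store_drivers = TRUE)
      ctr <- if (center_on_driver) f else 10
      an <- bandpass_analytic(ts, center = ctr, halfwidth = halfwidth,
                              include_drivers = TRUE)
      M <- coherence_matrix(an)
      dcol <- connectome$n + 1L  # virtual driver column
      nb <- which(und[node, ])
      acc[pi_, ] <- c(mean(M[dcol, seq_len(connectome$n)]),
                      if (length(nb)) mean(M[dcol, nb]) else NA_real_,
                      M[dcol, node],
                      kuramoto_order(an$phase[, seq_len(connectome$n)]))
    }
    colMeans(acc, na.rm = TRUE)
  })
  out <- do.call(rbind, out)
  data.frame(grid, coh_network = out[, 1], coh_neighbors = out[, 2],
             coh_stimulated = out[, 3], kuramoto = out[, 4])
}

#' Grid-search fit of global coupling and velocity to a reference FC
#'
#' For each `(c_net, v)` cell an unstimulated simulation is run, the
#' band-limited coherence (functional connectivity) matrix computed, and
#' its off-diagonal upper triangle correlated (Pearson) with the reference
#' FC.  Returns the full correlation surface and the argmax cell.
#'
#' @param connectome A [connectome()].
#' @param reference Symmetric reference FC matrix in [0, 1].
#' @param c_net_grid,v_grid Parameter grids.
#' @param cfg,noise,params As in [simulate()].
#' @param center,halfwidth Analysis band (Hz).
#' @return List with `surface` (data.frame c_net, v, r), `best`
#'   (row of `surface`), and `fc_best` (FC matrix at the argmax).
#' @export
fc_fit <- function(connectome, reference, c_net_grid = c(10, 14, 18),
                   v_grid = c(2, 2.6, 3.4), cfg = sim_config(seed = 1),
                   noise = noise_spec(), params = jr_params(),
                   center = 10, halfwidth = 2) {
  ut <- upper.tri(reference)
  if (stats::sd(reference[ut]) == 0)
    stop("reference FC is degenerate (zero variance off-diagonal)")
  grid <- expand.grid(c_net = c_net_grid, v = v_grid)
  fcs <- vector("list", nrow(grid))
  r <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ts <- simulate(connectome, global_coupling(grid$c_net[g], grid$v[g]),
                   stim = NULL, noise = noise, cfg = cfg, params = params)
    fcs[[g]] <- coherence_matrix(bandpass_analytic(ts, center, halfwidth))
    r[g] <- stats::cor(fcs[[g]][ut], reference[ut])
  }
  surface <- data.frame(grid, r = r)
  k <- which.max(r)
  list(surface = surface, best = surface[k, ], fc_best = fcs[[k]])
}

#' Relate the facilitation effect to graph structure
#'
#' Per probed pair: shortest-path hop count, shortest-path metric length
#' (mm), Dijkstra distance on inverted strengths, and (pooled) path count;
#' Pearson correlations of each with `log(PSF)`; group means of `log(PSF)`
#' by hop count and by pooled path count.
#'
#' @param table Metrics table from [all_pairs_probe()] (columns i, j, psf).
#' @param connectome The [connectome()] probed.
#' @param max_edges_count Edge cap for the path-count statistic.
#' @param pool_above Path-count pooling threshold.
#' @return List with `table` (input plus structure columns),
#'   `correlations` (named vector of Pearson r against log PSF; NA where
#'   undefined), `by_hops` and `by_npaths` (group summaries), and
#'   `n_excluded` (pairs with PSF = 0, excluded from the log).
#' @export
psf_structure_summary <- function(table, connectome, max_edges_count = 5,
                                  pool_above = 5) {
  st <- lapply(seq_len(nrow(table)), function(k) {
    i <- table$i[k]; j <- table$j[k]
    sp <- shortest_path_stats(connectome, i, j)
    dk <- dijkstra_inverse_strength(connectome, i, j)
    c(hops = sp$edges, length_mm = sp$length_mm, dijkstra = dk$distance,
      n_paths_capped = count_paths(connectome, i, j,
                                   max_edges = max_edges_count,
                                   pool_above = pool_above))
  })
  st <- as.data.frame(do.call(rbind, st))
  tab <- cbind(table, st)
  ok <- tab$psf > 0
  lp <- log(tab$psf[ok])
  safe_cor <- function(x) {
    x <- x[ok]
    if (length(unique(x)) < 2 || stats::sd(lp) == 0) return(NA_real_)
    stats::cor(x, lp)
  }
  correlations <- c(hops = safe_cor(st$hops),
                    length_mm = safe_cor(st$length_mm),
                    dijkstra = safe_cor(st$dijkstra),
                    n_paths = safe_cor(st$n_paths_capped))
  grp <- function(f) {
    s <- split(lp, f[ok])
    data.frame(level = names(s),
               mean_log_psf = vapply(s, mean, numeric(1)),
               sd_log_psf = vapply(s, stats::sd, numeric(1)),
               n = vapply(s, length, integer(1)), row.names = NULL)
  }
  list(table = tab, correlations = correlations,
       by_hops = grp(st$hops), by_npaths = grp(st$n_paths_capped),
       n_excluded = sum(!ok))
}

#' Write probe metrics to CSV / JSON
#'
#' `write_metrics` writes the per-pair table as CSV plus a JSON summary
#' with PPS / normalized-PSI / alignment histograms; `write_pa_curves`
#' writes one row per (pair, path, offset).
#'
#' @param result Result of [all_pairs_probe()].
#' @param stem Output path stem.
#' @param n_bins Histogram bin count (matches the 16 probed offsets by
#'   default).
#' @return `stem`, invisibly.
#' @export
write_metrics <- function(result, stem, n_bins = 16) {
  utils::write.csv(result$table, paste0(stem, "_pairs.csv"),
                   row.names = FALSE)
  tab <- result$table
  hist_of <- function(x, breaks) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NULL)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  summary <- list(
    n_pairs = nrow(tab),
    psf_mean = mean(tab$psf),
    class_counts = as.list(table(factor(tab$class,
      levels = c("flat", "selective", "switching")))),
    switching_fraction = mean(tab$psi > 0, na.rm = TRUE),
    pps_hist = hist_of(tab$pps1, seq(0, 1, length.out = n_bins + 1)),
    psi_norm_hist = hist_of(tab$psi_norm,
                            seq(-1, 1, length.out = 2 * n_bins + 1)),
    alignment_hist = hist_of(tab$alignment1,
                             seq(-pi, pi, length.out = n_bins + 1)))
  jsonlite::write_json(summary, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_metrics
#' @export
write_pa_curves <- function(result, stem) {
  rows <- list()
  for (k in seq_along(result$metrics)) {
    m <- result$metrics[[k]]
    pr <- result$probes[[k]]
    for (which_p in c("p1", "p2")) {
      p <- m[[which_p]]
      crv <- m[[if (which_p == "p1") "pa1" else "pa2"]]
      if (is.null(p)) next
      rows[[length(rows) + 1]] <- data.frame(
        i = m$pair[1], j = m$pair[2], path = paste(p, collapse = ">"),
        rank = if (which_p == "p1") 1L else 2L,
        offset = pr$offsets, pa = crv)
    }
  }
  utils::write.csv(do.call(rbind, rows), paste0(stem, "_pa_curves.csv"),
                   row.names = FALSE)
  invisible(stem)
}
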