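# Phase-probing metrics for a stimulated node pair.  All operate on
# coherence values measured at a set of stimulation phase offsets
# (a probe_result): PSF on the pair coherence curve, PA/PPS on pathway
# coherence products, PSI on competing pathway PA curves.

#' Probe-result container
#'
#' One stimulated node pair probed at a set of phase offsets, with a full
#' coherence matrix per offset.
#'
#' @param pair Integer length-2: the stimulated nodes (i, j).
#' @param offsets Strictly increasing phase offsets in `[0, 2 pi)` (rad).
#' @param coh_list One coherence matrix (see [coherence_matrix()]) per
#'   offset.
#' @return An object of class `probe_result`.
#' @export
probe_result <- function(pair, offsets, coh_list) {
  stopifnot(length(pair) == 2, pair[1] != pair[2],
            length(offsets) == length(coh_list), length(offsets) >= 1,
            all(diff(offsets) > 0), all(offsets >= 0), all(offsets < 2 * pi))
  structure(list(pair = as.integer(pair), offsets = offsets,
                 coh_list = coh_list), class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("probe_result: pair (%d, %d), %d phase offsets, %d-node coherence\n",
              x$pair[1], x$pair[2], length(x$offsets), nrow(x$coh_list[[1]])))
  invisible(x)
}

#' Pair coherence curve of a probe
#'
#' @param probe A [probe_result()].
#' @return Numeric vector: coherence of the stimulated pair at each offset.
#' @export
pair_coherence_curve <- function(probe) {
  vapply(probe$coh_list, function(M) M[probe$pair[1], probe$pair[2]],
         numeric(1))
}

#' Pathway synchronization facilitation (PSF)
#'
#' Max-minus-min of a stimulated pair's coherence over stimulation phase
#' offsets.  The minimum serves as the baseline of externally induced
#' trivial coherence; any excess at some other offset indicates
#' phase-dependent interaction through the network.
#'
#' @param coh Numeric coherence curve over offsets (>= 2 values), or a
#'   [probe_result()].
#' @return Scalar in [0, 1].
#' @export
psf <- function(coh) {
  if (inherits(coh, "probe_result")) coh <- pair_coherence_curve(coh)
  if (length(coh) < 2) stop("need coherence at >= 2 phase offsets")
  max(coh) - min(coh)
}

#' Pathway activation (PA) and variants
#'
#' `pa` is the product of the pairwise coherences between consecutive
#' pathway nodes at one offset: a chain is only as active as all of its
#' segments, and longer chains are penalized since every factor is <= 1.
#' `pa_min` replaces the product with the minimum segment coherence
#' (bottleneck-only variant); `pa_weighted` multiplies `pa` by the mean
#' structural connection strength over the path's edges.
#'
#' @param path Integer node sequence (>= 2 nodes).
#' @param coh Coherence matrix over the nodes.
#' @param C Structural weight matrix (for `pa_weighted`); asymmetric
#'   entries are resolved as `max(C[m,j], C[j,m])`.
#' @return Scalar in [0, 1] (`pa_weighted` in [0, max C]).
#' @export
pa <- function(path, coh) {
  stopifnot(length(path) >= 2, max(path) <= nrow(coh))
  prod(coh[cbind(path[-length(path)], path[-1])])
}

#' @rdname pa
#' @export
pa_min <- function(path, coh) {
  stopifnot(length(path) >= 2, max(path) <= nrow(coh))
  min(coh[cbind(path[-length(path)], path[-1])])
}

#' @rdname pa
#' @export
pa_weighted <- function(path, coh, C) {
  a <- path[-length(path)]; b <- path[-1]
  w <- pmax(C[cbind(a, b)], C[cbind(b, a)])
  pa(path, coh) * mean(w)
}

#' PA curve of a pathway over a probe's offsets
#'
#' @param probe A [probe_result()].
#' @param path Integer node sequence.
#' @param variant `"product"`, `"min"` or `"weighted"`.
#' @param C Required for `variant = "weighted"`.
#' @return Numeric vector, one PA value per offset.
#' @export
pa_curve <- function(probe, path, variant = c("product", "min", "weighted"),
                     C = NULL) {
  variant <- match.arg(variant)
  f <- switch(variant,
              product = function(M) pa(path, M),
              min = function(M) pa_min(path, M),
              weighted = function(M) pa_weighted(path, M, C))
  vapply(probe$coh_list, f, numeric(1))
}

#' Pathway phase selectivity (PPS)
#'
#' Max-minus-min of a pathway's PA over stimulation phase offsets: 0 for a
#' pathway insensitive to the phase relationship of the stimulated pair,
#' approaching 1 for one that can be switched on and off.
#'
#' @param pa_vals PA curve over offsets (>= 2 values).
#' @return Scalar in [0, 1].
#' @export
pps <- function(pa_vals) {
  if (length(pa_vals) < 2) stop("need PA at >= 2 phase offsets")
  max(pa_vals) - min(pa_vals)
}

#' Pathway switching index (PSI)
#'
#' `psi = max_offset(PA1 - PA2) * max_offset(PA2 - PA1)`: positive iff each
#' pathway dominates the other at some offset, i.e. the pair can switch its
#' communication route by changing the phase relationship.
#' `psi_normalized` maps back from the space of coherence products:
#' `sign(psi) sqrt(|psi|)`.
#'
#' @param pa1,pa2 PA curves on identical offsets.
#' @return Scalar in [-1, 1].
#' @export
psi <- function(pa1, pa2) {
  if (length(pa1) != length(pa2)) stop("PA curves must share their offsets")
  max(pa1 - pa2) * max(pa2 - pa1)
}

#' @rdname psi
#' @param value A PSI value.
#' @export
psi_normalized <- function(value) sign(value) * sqrt(abs(value))

#' Select the strongest and second-strongest disjoint pathway
#'
#' P1 maximizes the offset-averaged PA; P2 maximizes it among pathways
#' edge-disjoint from P1.  Ties break to the lexicographically smaller node
#' sequence (enumeration order).
#'
#' @param paths List of pathways in lexicographic order (see
#'   [enumerate_paths()]).
#' @param pa_curves List of PA curves, parallel to `paths`.
#' @return List with `p1`, `p2` (indices into `paths`; `p2` may be NA),
#'   `pa1`, `pa2` (curves; `pa2` NULL when absent).
#' @export
select_top_paths <- function(paths, pa_curves) {
  stopifnot(length(paths) >= 1, length(paths) == length(pa_curves))
  means <- vapply(pa_curves, mean, numeric(1))
  i1 <- which.max(means)  # first max = lexicographically smallest on ties
  disj <- which(vapply(paths, edge_disjoint, logical(1), p2 = paths[[i1]]))
  if (length(disj) == 0)
    return(list(p1 = i1, p2 = NA_integer_, pa1 = pa_curves[[i1]], pa2 = NULL))
  i2 <- disj[which.max(means[disj])]
  list(p1 = i1, p2 = i2, pa1 = pa_curves[[i1]], pa2 = pa_curves[[i2]])
}

#' Phase-preference alignment of a pathway with its pair
#'
#' Wrapped difference (in `(-pi, pi]`) between the offset at which the
#' pathway's PA peaks and the offset at which the stimulated pair's
#' coherence peaks.  Flat curves fall back to the first argmax and set the
#' `flat` flag.
#'
#' @param probe A [probe_result()].
#' @param path Integer node sequence (or a PA curve via `pa_vals`).
#' @param pa_vals Optional precomputed PA curve.
#' @return List with `diff` (rad) and `flat` (logical).
#' @export
phase_alignment <- function(probe, path = NULL, pa_vals = NULL) {
  if (is.null(pa_vals)) pa_vals <- pa_curve(probe, path)
  coh <- pair_coherence_curve(probe)
  flat <- (max(pa_vals) == min(pa_vals)) || (max(coh) == min(coh))
  d <- probe$offsets[which.max(pa_vals)] - probe$offsets[which.max(coh)]
  d <- (d + pi) %% (2 * pi) - pi
  if (d == -pi) d <- pi  # wrap convention: difference lies in (-pi, pi]
  list(diff = d, flat = flat)
}

#' All pathway metrics for one probed pair
#'
#' Enumerates pathways between the stimulated pair (default cap 4 edges,
#' i.e. up to 5 nodes), computes PA curves, selects the strongest (P1) and
#' the strongest edge-disjoint competitor (P2), and derives PSF, PPS(P1),
#' PSI(P1, P2) and the phase alignment of P1.
#'
#' @param probe A [probe_result()].
#' @param connectome The [connectome()] the probe was run on.
#' @param max_edges Pathway edge cap for PA evaluation.
#' @param variant PA variant, see [pa_curve()].
#' @return A `pair_metrics` list: `pair`, `psf`, `n_paths`, `p1`, `p2`
#'   (node sequences; `p2` may be NULL), `pa1`, `pa2`, `pps1`, `psi`,
#'   `psi_norm`, `alignment1`, plus flags.
#' @export
pair_metrics <- function(probe, connectome, max_edges = 4,
                         variant = "product") {
  i <- probe$pair[1]; j <- probe$pair[2]
  paths <- enumerate_paths(connectome, i, j, max_edges = max_edges)
  res <- list(pair = probe$pair, psf = psf(probe), n_paths = length(paths))
  if (length(paths) == 0) {
    res <- c(res, list(p1 = NULL, p2 = NULL, pa1 = NULL, pa2 = NULL,
                       pps1 = NA_real_, psi = NA_real_, psi_norm = NA_real_,
                       alignment1 = NA_real_, flat = NA))
    class(res) <- "pair_metrics"
    return(res)
  }
  curves <- lapply(paths, function(p)
    pa_curve(probe, p, variant = variant, C = connectome$C))
  top <- select_top_paths(paths, curves)
  al <- phase_alignment(probe, pa_vals = top$pa1)
  res$p1 <- paths[[top$p1]]
  res$p2 <- if (is.na(top$p2)) NULL else paths[[top$p2]]
  res$pa1 <- top$pa1
  res$pa2 <- top$pa2
  res$pps1 <- pps(top$pa1)
  res$psi <- if (is.null(top$pa2)) NA_real_ else psi(top$pa1, top$pa2)
  res$psi_norm <- psi_normalized(res$psi)
  res$alignment1 <- al$diff
  res$flat <- al$flat
  class(res) <- "pair_metrics"
  res
}

#' @export
print.pair_metrics <- function(x, ...) {
  cat(sprintf("pair (%d, %d): PSF = %.3f, %d paths", x$pair[1], x$pair[2],
              x$psf, x$n_paths))
  if (!is.null(x$p1))
    cat(sprintf(", PPS(P1) = %.3f, PSI = %s", x$pps1,
                if (is.na(x$psi)) "NA (no disjoint P2)" else sprintf("%.4f", x$psi)))
  cat("\n")
  invisible(x)
}

#' Classify probed pairs by their routing behavior
#'
#' Three qualitative classes of stimulated pairs: `"flat"` (the strongest
#' pathway shows little phase selectivity, PPS < `pps_threshold`),
#' `"selective"` (phase-selective but non-switching), and `"switching"`
#' (positive PSI between the strongest and the strongest edge-disjoint
#' pathway).
#'
#' @param metrics_list List of `pair_metrics`.
#' @param pps_threshold PPS below which the strongest path counts as flat.
#' @return Factor of classes, parallel to `metrics_list` (NA where no
#'   pathway exists).
#' @export
classify_pairs <- function(metrics_list, pps_threshold = 0.1) {
  cls <- vapply(metrics_list, function(m) {
    if (is.null(m$p1)) return(NA_character_)
    if (!is.na(m$psi) && m$psi > 0) return("switching")
    if (m$pps1 < pps_threshold) return("flat")
    "selective"
  }, character(1))
  factor(cls, levels = c("flat", "selective", "switching"))
}
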