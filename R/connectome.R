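#' Structural connectome container
#'
#' Bundles a directed weight matrix `C` and a symmetric fiber-length matrix
#' `L` (mm).  Orientation convention: `C[m, j]` is the strength of the
#' connection from source `m` to target `j`, so the incoming weights of
#' target `j` are the column `C[, j]`.  Preprocessed matrices (see
#' [preprocess_sc()]) have incoming weights summing to 1 for every target
#' with any input.
#'
#' @param C Square non-negative weight matrix with zero diagonal.
#' @param L Square symmetric non-negative fiber-length matrix (mm), zero
#'   diagonal.
#' @param labels Optional node names; defaults to `n1..nN`.
#' @return An object of class `connectome`.
#' @export
connectome <- function(C, L, labels = NULL) {
  C <- as.matrix(C); L <- as.matrix(L)
  n <- nrow(C)
  stopifnot(ncol(C) == n, nrow(L) == n, ncol(L) == n)
  if (any(C < 0) || any(L < 0)) stop("C and L must be non-negative")
  if (any(diag(C) != 0) || any(diag(L) != 0)) stop("C and L must have zero diagonals")
  if (max(abs(L - t(L))) > 1e-9) stop("L must be symmetric")
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  stopifnot(length(labels) == n)
  dimnames(C) <- dimnames(L) <- list(labels, labels)
  structure(list(n = n, C = C, L = L, labels = labels), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d nodes, %d directed edges, distances %.0f-%.0f mm\n",
              x$n, sum(x$C > 0),
              if (any(x$C > 0)) min(x$L[x$C > 0]) else 0,
              if (any(x$C > 0)) max(x$L[x$C > 0]) else 0))
  invisible(x)
}

#' Global network coupling parameters
#'
#' @param c_net Dimensionless global scaling of connection strengths.
#' @param v Conduction velocity (m/s) converting fiber length to delay.
#' @return An object of class `global_coupling`.
#' @export
global_coupling <- function(c_net = 14, v = 2.6) {
  stopifnot(c_net > 0, v > 0)
  structure(list(c_net = c_net, v = v), class = "global_coupling")
}

#' Preprocess a raw structural connectivity matrix
#'
#' Applies, in order: (1) normalize the incoming weights of each target to
#' sum 1; (2) zero all entries below `threshold`; (3) re-normalize incoming
#' weights to sum 1.  Targets that lose all inputs at step (2) stay
#' all-zero, with a warning.  Idempotent.
#'
#' @param C_raw Non-negative square matrix, zero diagonal, oriented
#'   (source, target).
#' @param threshold Strength cutoff applied after the first normalization.
#' @param normalize If `FALSE`, only thresholding is applied.
#' @return Weight matrix of the same shape satisfying the connectome
#'   invariants.
#' @export
preprocess_sc <- function(C_raw, threshold = 0.1, normalize = TRUE) {
  C <- as.matrix(C_raw)
  if (any(C < 0)) stop("raw weights must be non-negative")
  norm_in <- function(M) {
    s <- colSums(M)
    keep <- s > 0
    M[, keep] <- sweep(M[, keep, drop = FALSE], 2, s[keep], "/")
    M
  }
  if (normalize) C <- norm_in(C)
  C[C < threshold] <- 0
  lost <- colSums(as.matrix(C_raw)) > 0 & colSums(C) == 0
  if (any(lost))
    warning(sprintf("%d target(s) lost all incoming connections at threshold %g",
                    sum(lost), threshold))
  if (normalize) C <- norm_in(C)
  C
}

#' Convert fiber lengths to integer signal-transmission delays
#'
#' `delay = round((L/1000) / v / dt)` steps, floored at 1 step for every
#' existing edge (a zero-delay edge would change the integrator structure).
#'
#' @param L Fiber-length matrix (mm).
#' @param v Conduction velocity (m/s).
#' @param dt Integration step (s).
#' @param mask Logical matrix of existing edges; delays are 0 (absent)
#'   elsewhere.  Defaults to all off-diagonal entries.
#' @return Integer matrix of delays in steps.
#' @export
delays_in_steps <- function(L, v, dt, mask = NULL) {
  stopifnot(v > 0, dt > 0)
  L <- as.matrix(L)
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(L), ncol(L)); diag(mask) <- FALSE
  }
  d <- matrix(0L, nrow(L), ncol(L))
  d[mask] <- pmax(1L, as.integer(round((L[mask] / 1000) / v / dt)))
  d
}

#' Toy connectivity motifs
#'
#' Two- and three-node motifs used to study how the phase preference of a
#' stimulated pair depends on transmission delay: a uni-directional pair, a
#' bi-directional pair, and a bi-directional chain where a relay node sits
#' at `relay_fraction` of the total end-to-end distance (no direct
#' end-to-end edge).  All existing edges have weight 0.1.
#'
#' @param kind `"uni_2node"`, `"bi_2node"` or `"chain_3node"`.
#' @param total_distance End-to-end distance (mm).
#' @param relay_fraction Position of the relay on the chain, in (0, 1).
#' @return A [connectome()].
#' @export
make_motif <- function(kind = c("uni_2node", "bi_2node", "chain_3node"),
                       total_distance = 100, relay_fraction = 0.25) {
  kind <- match.arg(kind)
  stopifnot(total_distance > 0)
  w <- 0.1
  if (kind == "uni_2node") {
    C <- matrix(0, 2, 2); C[1, 2] <- w
    L <- matrix(0, 2, 2); L[1, 2] <- L[2, 1] <- total_distance
    connectome(C, L, c("a", "b"))
  } else if (kind == "bi_2node") {
    C <- matrix(c(0, w, w, 0), 2, 2)
    L <- matrix(c(0, 1, 1, 0), 2, 2) * total_distance
    connectome(C, L, c("a", "b"))
  } else {
    stopifnot(relay_fraction > 0, relay_fraction < 1)
    d1 <- relay_fraction * total_distance
    d2 <- (1 - relay_fraction) * total_distance
    C <- matrix(0, 3, 3)
    C[1, 2] <- C[2, 1] <- C[2, 3] <- C[3, 2] <- w
    L <- matrix(0, 3, 3)
    L[1, 2] <- L[2, 1] <- d1
    L[2, 3] <- L[3, 2] <- d2
    connectome(C, L, c("a", "relay", "b"))
  }
}

#' Synthetic connectome generator
#'
#' Stands in for diffusion-imaging derived structural matrices, which are
#' not redistributable: sparse directed edges (Bernoulli `density`) with
#' heavy-tailed log-normal raw weights, symmetric uniform inter-node
#' distances, then passed through [preprocess_sc()].  A random spanning tree
#' is inserted first (bi-directionally) so the undirected support is always
#' connected.  Reproducible for a fixed `seed`.
#'
#' @param n Number of nodes (>= 2).
#' @param density Probability of each directed off-diagonal edge.
#' @param distance_range Length-2 range of inter-node distances (mm).
#' @param seed Integer seed.
#' @param threshold Passed to [preprocess_sc()].
#' @param sdlog Log-normal spread of raw weights.
#' @return A [connectome()].
#' @export
synth_connectome <- function(n = 33, density = 0.3,
                             distance_range = c(10, 160), seed = 1,
                             threshold = 0.1, sdlog = 1) {
  stopifnot(n >= 2, density > 0, density <= 1)
  set.seed(seed)
  A <- matrix(stats::runif(n * n) < density, n, n)
  diag(A) <- FALSE
  # spanning tree over a random node order guarantees weak connectivity
  ord <- sample(n)
  for (k in 2:n) {
    parent <- ord[sample.int(k - 1, 1)]
    A[parent, ord[k]] <- TRUE
    A[ord[k], parent] <- TRUE
  }
  W <- matrix(0, n, n)
  W[A] <- stats::rlnorm(sum(A), meanlog = 0, sdlog = sdlog)
  Lv <- matrix(stats::runif(n * n, distance_range[1], distance_range[2]), n, n)
  L <- (Lv + t(Lv)) / 2
  diag(L) <- 0
  C <- suppressWarnings(preprocess_sc(W, threshold = threshold))
  connectome(C, L)
}

#' Read / write connectome matrices as delimited text
#'
#' `C` and `L` are stored as CSV with a header row and row names of node
#' labels, plus a JSON sidecar (`<stem>.json`) recording the orientation
#' convention (rows = sources, columns = targets) and distance units (mm).
#'
#' @param con A [connectome()].
#' @param stem Path stem; writes `<stem>_C.csv`, `<stem>_L.csv`,
#'   `<stem>.json`.
#' @return `write_connectome` returns `stem` invisibly; `read_connectome`
#'   returns a [connectome()].
#' @export
write_connectome <- function(con, stem) {
  utils::write.csv(con$C, paste0(stem, "_C.csv"))
  utils::write.csv(con$L, paste0(stem, "_L.csv"))
  jsonlite::write_json(
    list(orientation = "rows are sources, columns are targets",
         units = list(L = "mm"), n = con$n, labels = con$labels),
    paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(stem)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(stem) {
  C <- as.matrix(utils::read.csv(paste0(stem, "_C.csv"), row.names = 1,
                                 check.names = FALSE))
  L <- as.matrix(utils::read.csv(paste0(stem, "_L.csv"), row.names = 1,
                                 check.names = FALSE))
  connectome(C, L, labels = rownames(C))
}
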