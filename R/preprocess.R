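#' Background (mean-trace) removal
#'
#' Subtracts from every trace the mean trace of the record,
#' `x'_ij = x_ij - mean_j(x_ij)`, which removes the laterally invariant
#' direct-wave energy from a B-scan.
#'
#' @param x A [bscan()] or plain matrix, time sample x trace (>= 2 traces).
#' @return Same shape as `x`; every time-row of the output has zero mean.
#' @export
remove_background <- function(x) {
  if (ncol(x) < 2)
    stop("background removal needs at least 2 traces", call. = FALSE)
  out <- x - rowMeans(x)
  attributes(out) <- attributes(x)
  out
}

#' Exponential time gain
#'
#' Compensates geometric spreading and attenuation with the fixed gain
#' `exp(2e7 * i * dt)^5 = exp(1e8 * i * dt)` applied to time-step `i`
#' (0-based) of every trace.
#'
#' @param x Matrix, time sample x trace.
#' @param dt Sampling interval of the record, s.
#' @return Gained matrix, same shape.
#' @export
apply_gain <- function(x, dt = attr(x, "dt")) {
  stopifnot(!is.null(dt), dt > 0)
  g <- exp(1e8 * (seq_len(nrow(x)) - 1) * dt)
  out <- x * g
  attributes(out) <- attributes(x)
  out
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; errors on constant input.
#'
#' @param x Numeric array.
#' @return Same shape, minimum exactly 0 and maximum exactly 1.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (r[1] == r[2])
    stop("degenerate input: constant array cannot be min-max normalized",
         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Nearest-neighbour resize
#'
#' Each output cell copies the input cell containing the output cell's
#' center under the half-open cell mapping; when the center falls exactly
#' on a cell boundary the smaller index wins.  Output values are always a
#' subset of input values, so binary maps stay binary.
#'
#' @param x Numeric matrix.
#' @param nrow_out,ncol_out Target size (default 128 x 128).
#' @return `nrow_out` x `ncol_out` matrix.
#' @export
resize_nearest <- function(x, nrow_out = 128, ncol_out = 128) {
  stopifnot(nrow(x) >= 1, ncol(x) >= 1)
  ri <- .nn_index(nrow(x), nrow_out)
  ci <- .nn_index(ncol(x), ncol_out)
  x[ri, ci, drop = FALSE]
}

# 1-based source indices for nearest-neighbour resampling n_src -> n_dst;
# boundary ties resolve toward the smaller index
.nn_index <- function(n_src, n_dst) {
  pos <- (seq_len(n_dst) - 0.5) * n_src / n_dst
  idx <- floor(pos) + 1L          # containing cell, half-open intervals
  tie <- abs(pos - round(pos)) < 1e-12 & round(pos) > 0
  idx[tie] <- round(pos[tie])     # boundary point: smaller index wins
  as.integer(pmin(pmax(idx, 1L), n_src))
}

#' Build the permittivity and edge training labels
#'
#' The permittivity label is the map under the fixed global scale
#' `(eps' - 1) / (eps_max - 1)` clipped to `[0, 1]` (so a scatterer at the
#' maximum permittivity 32 maps to exactly 1), resized to the label size.
#' The edge label marks, with a single-cell-wide contour, every cell of
#' the resized label whose forward difference to its right or lower
#' neighbour exceeds `edge_threshold`.
#'
#' @param perm_map A [permittivity_map()] or numeric matrix of `eps'`.
#' @param size Output label size (square).
#' @param eps_max Upper end of the global permittivity scale.
#' @param edge_threshold Normalized-jump threshold for the edge label.
#' @return List with `perm_label` (in `[0, 1]`) and `edge_label` (binary),
#'   both `size` x `size`, plus the normalization constants.
#' @export
make_labels <- function(perm_map, size = 128, eps_max = 32,
                        edge_threshold = 0.02) {
  g <- pmin(pmax((unclass(perm_map) - 1) / (eps_max - 1), 0), 1)
  perm_label <- resize_nearest(g, size, size)
  dz <- abs(perm_label[-1, ] - perm_label[-nrow(perm_label), ])
  dxl <- abs(perm_label[, -1] - perm_label[, -ncol(perm_label)])
  edge <- matrix(0L, size, size)
  edge[-size, ][dz > edge_threshold] <- 1L
  edge[, -size][dxl > edge_threshold] <- 1L
  list(perm_label = perm_label, edge_label = edge,
       eps_min = 1, eps_max = eps_max, edge_threshold = edge_threshold)
}

#' Preprocess one simulated (B-scan, permittivity map) pair
#'
#' Applies, in order, background removal, time gain at the record's
#' native sampling interval, min-max normalization and nearest-neighbour
#' resizing to the network input size, and builds the two training labels
#' from the permittivity map.
#'
#' @param bscan A [bscan()] (carries its `dt`).
#' @param perm_map A [permittivity_map()].
#' @param size Network input / label size.
#' @param eps_max,edge_threshold Label parameters, see [make_labels()].
#' @param meta Optional provenance list stored with the sample.
#' @return A `processed_sample`: list with `input`, `perm_label`,
#'   `edge_label` (all `size` x `size`) and `meta`.
#' @export
process_sample <- function(bscan, perm_map, size = 128, eps_max = 32,
                           edge_threshold = 0.02, meta = list()) {
  inp <- resize_nearest(
    minmax_normalize(apply_gain(remove_background(bscan))), size, size)
  lab <- make_labels(perm_map, size, eps_max, edge_threshold)
  meta$dt <- attr(bscan, "dt")
  meta$eps_max <- eps_max
  meta$edge_threshold <- edge_threshold
  structure(list(input = unclass(inp),
                 perm_label = lab$perm_label,
                 edge_label = lab$edge_label, meta = meta),
            class = "processed_sample")
}
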