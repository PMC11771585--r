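#' Radial density-compensation weights
#'
#' Ramp (`|k|`) weights for radial spokes with a small DC regularisation:
#' sample `t` receives area `max(|t|, dk/4) * dk * pi / n_spokes`, the
#' polar-cell area its location represents when spokes (diameters) cover
#' the half-circle of angles.
#'
#' @param kspace A `radial_kspace`.
#' @return Numeric vector of weights, one per spoke sample.
#' @export
density_compensation <- function(kspace) {
  dk <- 2 * pi / kspace$matrix
  pmax(abs(kspace$tvals), dk / 4) * dk * pi / nrow(kspace$spokes)
}

#' Subspace (temporal-basis) adjoint reconstruction
#'
#' Projects the spoke time series onto the temporal SVD basis in k-space
#' and grids each of the rank coefficient channels to an image by adjoint
#' non-uniform Fourier transform with radial density compensation: channel
#' `r` is the adjoint NUDFT of `w_k * s_k * basis[t(k), r]`, the
#' subspace coefficient of the measured series at each k-point.
#'
#' @param kspace A `radial_kspace`.
#' @param basis Temporal basis, readouts x rank complex matrix with
#'   orthonormal columns (see [compress_svd()]).
#' @return Complex array `matrix x matrix x rank` of coefficient images
#'   with attribute `"pixel_mm"`.
#' @export
reconstruct_subspace_images <- function(kspace, basis) {
  basis <- as.matrix(basis)
  if (nrow(basis) != nrow(kspace$spokes))
    stop("basis rows must equal the readout count")
  ns <- nrow(kspace$spokes)
  nt <- length(kspace$tvals)
  w <- density_compensation(kspace)
  kx <- as.vector(outer(cos(kspace$angles), kspace$tvals))  # spoke-major
  ky <- as.vector(outer(sin(kspace$angles), kspace$tvals))
  wdata <- kspace$spokes * matrix(w, ns, nt, byrow = TRUE)
  data <- matrix(0 + 0i, ns * nt, ncol(basis))
  for (r in seq_len(ncol(basis)))
    data[, r] <- as.vector(wdata * basis[, r])
  img <- spoke_adjoint_cpp(data, kx, ky, kspace$matrix) / (2 * pi)^2
  img <- array(img, dim = c(kspace$matrix, kspace$matrix, ncol(basis)))
  attr(img, "pixel_mm") <- kspace$pixel_mm
  img
}

#' Matched-filter coil combination
#'
#' Combines per-coil coefficient images with the matched filter
#' `sum_c conj(S_c) I_c / sum_c |S_c|^2`; with a single uniform coil this
#' reduces to the identity.
#'
#' @param coil_images List over coils of `n x n x rank` arrays.
#' @param sens `n x n x n_coils` complex sensitivity array.
#' @return Combined `n x n x rank` array.
#' @export
matched_filter_combine <- function(coil_images, sens) {
  nc <- length(coil_images)
  stopifnot(dim(sens)[3] == nc)
  norm <- matrix(0, dim(sens)[1], dim(sens)[2])
  for (c in seq_len(nc)) norm <- norm + Mod(sens[, , c])^2
  norm[norm == 0] <- 1
  out <- array(0 + 0i, dim = dim(coil_images[[1]]))
  for (c in seq_len(nc))
    for (r in seq_len(dim(out)[3]))
      out[, , r] <- out[, , r] +
        Conj(sens[, , c]) * coil_images[[c]][, , r] / norm
  out
}

#' Voxel-wise dictionary matching
#'
#' Searches the compressed dictionary for the highest-magnitude normalised
#' inner product per voxel and writes the grid parameter values, the
#' correlation and the projection amplitude (rho). Voxels with zero signal
#' are flagged unmatched (correlation 0, parameters `NA`).
#'
#' @param images Coefficient images from [reconstruct_subspace_images()]
#'   (rank must equal the dictionary's).
#' @param dict An SVD-compressed `mrf_dictionary`.
#' @return A `parameter_maps` object: `t1_map`, `t2_map`, `b1_map`
#'   (degrees), `rho_map` (complex), `correlation_map`, `matched`.
#' @export
match_maps <- function(images, dict) {
  if (is.null(dict$compressed)) stop("dictionary is not compressed")
  d <- dim(images)
  if (d[3] != dict$rank) stop("image rank must equal the dictionary rank")
  if (!nrow(dict$compressed)) stop("dictionary is empty")
  n <- d[1]
  X <- matrix(images, nrow = n * d[2], ncol = d[3])      # voxels x rank
  C <- dict$compressed
  cn <- sqrt(rowSums(Mod(C)^2))
  xn <- sqrt(rowSums(Mod(X)^2))
  M <- Conj(C / cn) %*% t(X)                             # entries x voxels
  corr_all <- Mod(M)
  best <- max.col(t(corr_all), ties.method = "first")
  ok <- xn > 0
  corr <- numeric(length(best))
  corr[ok] <- corr_all[cbind(best[ok], which(ok))] / xn[ok]
  proj <- M[cbind(best, seq_along(best))] / cn[best]     # <d,x>/|d|^2
  ent <- dict$grid$entries
  pick <- function(v) { out <- v[best]; out[!ok] <- NA; matrix(out, n) }
  rho <- proj
  rho[!ok] <- NA
  structure(list(t1_map = pick(ent$t1), t2_map = pick(ent$t2),
                 b1_map = pick(ent$b1), rho_map = matrix(rho, n),
                 correlation_map = matrix(pmin(corr, 1), n),
                 matched = matrix(ok, n),
                 pixel_mm = attr(images, "pixel_mm")),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps> %dx%d px, %d matched voxels\n",
              nrow(x$t1_map), ncol(x$t1_map), sum(x$matched)))
  invisible(x)
}

#' Region-of-interest statistics of parameter maps
#'
#' @param maps A `parameter_maps` object.
#' @param masks Integer label image (0 = outside all ROIs) or a named list
#'   of logical masks.
#' @return Tibble with one row per ROI and map: mean, SD, median, n.
#' @export
roi_statistics <- function(maps, masks) {
  if (is.list(masks)) {
    lab <- matrix(0L, nrow(maps$t1_map), ncol(maps$t1_map))
    for (i in seq_along(masks)) lab[masks[[i]]] <- i
    roi_names <- names(masks)
    if (is.null(roi_names)) roi_names <- paste0("roi", seq_along(masks))
  } else {
    lab <- masks
    roi_names <- as.character(sort(unique(lab[lab > 0])))
  }
  layers <- list(t1 = maps$t1_map, t2 = maps$t2_map, b1 = maps$b1_map,
                 rho = Mod(maps$rho_map),
                 correlation = maps$correlation_map)
  rows <- list()
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) stop("no non-empty ROI in the label image")
  for (k in seq_along(ids)) {
    sel <- lab == ids[k]
    for (nm in names(layers)) {
      v <- layers[[nm]][sel]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        roi = roi_names[k], map = nm,
        mean = mean(v), sd = stats::sd(v), median = stats::median(v),
        n = length(v))
    }
  }
  do.call(rbind, rows)
}

#' Relative difference between two ROI-statistics tables
#'
#' Joins two [roi_statistics()] tables on ROI and map and reports the
#' relative difference of the means, `(a - b) / b`. The difference of a
#' table with itself is zero everywhere.
#'
#' @param stats_a,stats_b Tibbles from [roi_statistics()].
#' @return Tibble with `roi`, `map`, `mean_a`, `mean_b`, `rel_diff`.
#' @export
relative_difference <- function(stats_a, stats_b) {
  m <- merge(as.data.frame(stats_a)[, c("roi", "map", "mean")],
             as.data.frame(stats_b)[, c("roi", "map", "mean")],
             by = c("roi", "map"), suffixes = c("_a", "_b"))
  tibble::tibble(roi = m$roi, map = m$map, mean_a = m$mean_a,
                 mean_b = m$mean_b,
                 rel_diff = (m$mean_a - m$mean_b) / m$mean_b)
}
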