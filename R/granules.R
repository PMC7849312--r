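#' Label connected components in a binary mask
#'
#' Connected-component labeling with 8-connectivity by default (the ImageJ
#' convention; 4-connectivity available). Implemented by iterative label
#' propagation: each foreground pixel starts with a unique label and
#' repeatedly takes the minimum label over its neighborhood until stable, so
#' the result is deterministic and independent of scan order.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape: 0 background, 1..k component
#'   labels (relabeled contiguously in first-pixel order).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) return(lab)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  repeat {
    new <- lab
    for (o in offs) {
      nb <- shift(lab, o[1], o[2])
      take <- mask & nb > 0L & (nb < new | new == 0L)
      new[take] <- nb[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # propagate label equivalences that min-propagation resolves in stages
  ids <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], sort(ids))
  lab
}

#' Segment granules in one image channel
#'
#' Thresholds the channel (Otsu's method when \code{threshold = "auto"}),
#' labels connected components (8-connectivity by default) and keeps objects
#' whose pixel count lies within \code{size_range} — inclusive bounds, with
#' the 1 to 2,000 px default — reporting per-object unweighted pixel
#' centroids, areas and mean intensities in both pixel and micrometre units.
#'
#' @param img Numeric matrix (2D intensity image, rows = y, columns = x).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param threshold Numeric cutoff (mask = intensity > threshold) or
#'   \code{"auto"} for Otsu.
#' @param size_range Inclusive \[min, max\] object size in pixels (default
#'   c(1, 2000)).
#' @param connectivity Component connectivity, 8 (default) or 4.
#' @return Data frame, one row per kept object: \code{label}, \code{x_px},
#'   \code{y_px} (centroid, 1-based pixel centers; x = column, y = row),
#'   \code{x_um}, \code{y_um}, \code{area_px}, \code{area_um2},
#'   \code{mean_intensity}. Attribute \code{threshold} records the cutoff
#'   used.
#' @export
segment_channel <- function(img, pixel_size_um, threshold = "auto",
                            size_range = c(1, 2000), connectivity = 8) {
  if (missing(pixel_size_um) || is.null(pixel_size_um)) {
    stop("pixel size (um/px) is required")
  }
  if (identical(threshold, "auto")) {
    rng <- range(img)
    threshold <- if (rng[1] == rng[2]) rng[2] else
      EBImage::otsu(img, range = rng)
  }
  mask <- img > threshold
  lab <- label_components(mask, connectivity)
  empty <- data.frame(label = integer(0), x_px = numeric(0),
                      y_px = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  attr(empty, "threshold") <- threshold
  if (max(lab) == 0) return(empty)
  idx <- which(lab > 0L)
  lv <- lab[idx]
  rows <- (idx - 1L) %% nrow(img) + 1L
  cols <- (idx - 1L) %/% nrow(img) + 1L
  area <- tabulate(lv)
  keep <- which(area >= size_range[1] & area <= size_range[2])
  if (length(keep) == 0) {
    out <- empty
  } else {
    xc <- vapply(keep, function(k) mean(cols[lv == k]), numeric(1))
    yc <- vapply(keep, function(k) mean(rows[lv == k]), numeric(1))
    mi <- vapply(keep, function(k) mean(img[idx[lv == k]]), numeric(1))
    out <- data.frame(
      label = seq_along(keep), x_px = xc, y_px = yc,
      x_um = xc * pixel_size_um, y_um = yc * pixel_size_um,
      area_px = area[keep], area_um2 = area[keep] * pixel_size_um^2,
      mean_intensity = mi
    )
  }
  attr(out, "threshold") <- threshold
  out
}

#' Nearest-center distances between two channels
#'
#' For every object in channel A, the Euclidean center-to-center distance (in
#' micrometres) to its nearest channel-B object — the center-distance measure
#' of colocalization. Note the pairing is directional: swapping channels can
#' change the pair list.
#'
#' @param objs_a,objs_b [segment_channel()] outputs from co-registered
#'   channels.
#' @param pixel_size_um Pixel size; required when the object tables lack
#'   micrometre columns.
#' @return Data frame \code{label_a}, \code{label_b}, \code{distance_um};
#'   zero rows (with attribute \code{empty_b = TRUE}) when channel B has no
#'   objects.
#' @export
pair_distances <- function(objs_a, objs_b, pixel_size_um = NULL) {
  get_um <- function(df) {
    if (all(c("x_um", "y_um") %in% names(df))) {
      cbind(df$x_um, df$y_um)
    } else {
      if (is.null(pixel_size_um)) stop("pixel size (um/px) is required")
      cbind(df$x_px, df$y_px) * pixel_size_um
    }
  }
  out <- data.frame(label_a = integer(0), label_b = integer(0),
                    distance_um = numeric(0))
  if (nrow(objs_a) == 0) return(out)
  if (nrow(objs_b) == 0) {
    attr(out, "empty_b") <- TRUE
    return(out)
  }
  A <- get_um(objs_a); B <- get_um(objs_b)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  j <- apply(d2, 1, which.min)
  data.frame(
    label_a = objs_a$label,
    label_b = objs_b$label[j],
    distance_um = sqrt(d2[cbind(seq_len(nrow(A)), j)])
  )
}

#' Z/P granule count-ratio comparison across genotypes
#'
#' Pools Z- and P-granule counts per genotype and compares each genotype to
#' the reference with a pooled two-proportion z-test on the proportion
#' Z/(Z+P), adjusting the two-sided p-values across genotypes with the Holm
#' method. The figure-style ratio Z/P is reported alongside the tested
#' proportion.
#'
#' @param counts Data frame with columns \code{genotype}, \code{n_z},
#'   \code{n_p} (already pooled over gonads).
#' @param reference Reference genotype.
#' @return Data frame \code{genotype}, \code{n_z}, \code{n_p}, \code{ratio}
#'   (Z/P; \code{NA} when n_p = 0), \code{prop_z}, \code{z}, \code{p},
#'   \code{p_adj} (reference row has NA statistics). Genotypes with zero
#'   total granules are dropped with a warning.
#' @export
zp_ratio_test <- function(counts, reference) {
  stopifnot(all(c("genotype", "n_z", "n_p") %in% names(counts)))
  tot <- counts$n_z + counts$n_p
  if (any(tot == 0)) {
    warning("dropping genotype(s) with zero granules: ",
            paste(counts$genotype[tot == 0], collapse = ", "))
    counts <- counts[tot > 0, , drop = FALSE]
  }
  if (!(reference %in% counts$genotype)) stop("reference genotype missing")
  ref <- counts[counts$genotype == reference, ]
  out <- data.frame(
    genotype = counts$genotype, n_z = counts$n_z, n_p = counts$n_p,
    ratio = ifelse(counts$n_p > 0, counts$n_z / counts$n_p, NA_real_),
    prop_z = counts$n_z / (counts$n_z + counts$n_p),
    z = NA_real_, p = NA_real_, p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  others <- which(out$genotype != reference)
  for (i in others) {
    ht <- two_prop_z(out$n_z[i], out$n_z[i] + out$n_p[i],
                     ref$n_z, ref$n_z + ref$n_p)
    out$z[i] <- ht$z; out$p[i] <- ht$p
  }
  out$p_adj[others] <- adjust_pvalues(out$p[others], "Holm")
  out
}

#' Compare granule area distributions across genotypes
#'
#' Box-plot summaries (median, IQR, whiskers at the quartiles extended by
#' 1.5 IQR, clipped to the data) per genotype plus pairwise two-tailed
#' unpaired t-tests on the areas.
#'
#' @param areas Named list: genotype -> numeric vector of object areas
#'   (µm²), each of length >= 2.
#' @return List with \code{summary} (per-genotype box stats) and
#'   \code{pairwise} (data.frame \code{genotype_a}, \code{genotype_b},
#'   \code{t}, \code{p}; \code{NA} p when both groups are degenerate).
#' @export
area_compare <- function(areas) {
  stopifnot(length(areas) >= 1, all(vapply(areas, length, 1L) >= 2))
  summ <- do.call(rbind, lapply(names(areas), function(g) {
    x <- areas[[g]]
    qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    data.frame(genotype = g, n = length(x), median = qs[2],
               q1 = qs[1], q3 = qs[3],
               whisker_lo = min(x[x >= qs[1] - 1.5 * iqr]),
               whisker_hi = max(x[x <= qs[3] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  }))
  if (length(areas) < 2) {
    return(list(summary = summ,
                pairwise = data.frame(genotype_a = character(0),
                                      genotype_b = character(0),
                                      t = numeric(0), p = numeric(0))))
  }
  pairs <- t(utils::combn(names(areas), 2))
  pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    x <- areas[[pairs[i, 1]]]; y <- areas[[pairs[i, 2]]]
    ht <- if (sd(x) == 0 && sd(y) == 0 && mean(x) != mean(y)) {
      list(t = NA_real_, p = NA_real_)
    } else {
      t_test2(x, y)
    }
    data.frame(genotype_a = pairs[i, 1], genotype_b = pairs[i, 2],
               t = ht$t, p = ht$p, stringsAsFactors = FALSE)
  }))
  list(summary = summ, pairwise = pw)
}
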