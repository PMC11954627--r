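#' Parameters for automatic boundary detection
#'
#' @param smoothing_sigma_um Gaussian pre-smoothing width, micrometers;
#'   suppresses per-nucleus texture while keeping the tissue edge.
#' @param min_tissue_area_um2 components smaller than this are discarded.
#' @param closing_radius_um radius of the morphological closing applied to
#'   the thresholded tissue mask.
#' @return object of class `boundary_params`.
#' @export
boundary_params <- function(smoothing_sigma_um = 2,
                            min_tissue_area_um2 = 100,
                            closing_radius_um = 1) {
  if (smoothing_sigma_um < 0) stop_field("smoothing_sigma_um", "must be >= 0")
  if (min_tissue_area_um2 <= 0) {
    stop_field("min_tissue_area_um2", "must be > 0")
  }
  structure(list(smoothing_sigma_um = smoothing_sigma_um,
                 min_tissue_area_um2 = min_tissue_area_um2,
                 closing_radius_um = closing_radius_um),
            class = "boundary_params")
}

new_epithelial_boundary <- function(tissue_mask, coords,
                                    provenance = "automatic",
                                    pixel_size = NA_real_,
                                    luminal_side = "unoriented") {
  structure(list(tissue_mask = tissue_mask, coords = coords,
                 provenance = provenance, pixel_size = pixel_size,
                 luminal_side = luminal_side),
            class = "epithelial_boundary")
}

#' @export
print.epithelial_boundary <- function(x, ...) {
  cat(sprintf("<epithelial_boundary> %d boundary px, tissue %.1f%% of frame, %s, luminal side: %s\n",
              nrow(x$coords), 100 * mean(x$tissue_mask), x$provenance,
              x$luminal_side))
  invisible(x)
}

# Extract the ordered lumen-facing edge of a tissue mask.  Only the edge
# adjacent to the largest non-tissue component (the lumen) is kept, so
# internal holes or image borders do not contribute boundary pixels.
extract_luminal_edge <- function(tissue_mask) {
  lumen_lab <- as_mat(EBImage::bwlabel(!tissue_mask))
  if (max(lumen_lab) == 0) stop("no lumen detected", call. = FALSE)
  sizes <- tabulate(lumen_lab[lumen_lab > 0])
  lumen <- lumen_lab == which.max(sizes)
  edge <- edge_of_mask(!lumen) & tissue_mask
  coords <- which(edge, arr.ind = TRUE)
  if (!nrow(coords)) stop("no lumen detected", call. = FALSE)
  coords <- order_chain(coords)
  colnames(coords) <- c("row", "col")
  coords
}

#' Detect the epithelial boundary from the DAPI channel
#'
#' Locates the lumen-facing edge of the tissue at the spatial-gradient
#' transition of the DAPI signal: the channel is Gaussian-smoothed to
#' suppress per-nucleus texture, an automatic (Otsu) threshold selects the
#' tissue iso-contour - which, for the smoothed step edge between the
#' nucleus-dense tissue band and the dim lumen, lies on the ridge of the
#' DAPI gradient magnitude - and the mask is hole-filled, morphologically
#' closed, and reduced to its largest connected component.  The boundary
#' is the ordered chain of tissue pixels facing the largest non-tissue
#' region.
#'
#' @param dapi 2-D numeric matrix, the DAPI channel.
#' @param params a [boundary_params()].
#' @param pixel_size micrometers per pixel, > 0.
#' @return an `epithelial_boundary`: `tissue_mask` (logical matrix),
#'   `coords` (ordered row/col matrix of the lumen-facing edge),
#'   `provenance = "automatic"`, and `luminal_side` (set to `"complement"`:
#'   the lumen is the non-tissue side; see [orient_luminal_side()] to
#'   verify or flip the orientation against the image).
#' @examples
#' dapi <- matrix(0, 64, 64); dapi[33:64, ] <- 100
#' b <- detect_boundary(dapi, pixel_size = 0.5)
#' range(b$coords[, "row"])
#' @export
detect_boundary <- function(dapi, params = boundary_params(),
                            pixel_size = 1) {
  check_matrix2d(dapi, "dapi")
  if (any(dim(dapi) < 8)) {
    stop("dapi must be an image of at least 8x8 pixels", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop_field("pixel_size", "must be > 0")
  }
  if (diff(range(dapi)) < .Machine$double.eps) {
    stop("no tissue detected: DAPI channel is constant", call. = FALSE)
  }
  sm <- smooth_gaussian(dapi, params$smoothing_sigma_um / pixel_size)
  level <- otsu_threshold(sm)
  if (is.na(level)) stop("no tissue detected: flat DAPI", call. = FALSE)
  # The smoothed DAPI signal falls monotonically across the tissue edge,
  # so its Otsu iso-contour lies on the ridge of the spatial gradient
  # magnitude; thresholding the smoothed intensity therefore places the
  # boundary at the DAPI gradient transition while staying robust to
  # per-nucleus texture inside the tissue band.
  mask <- sm >= level
  mask <- as_mat(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  cl_px <- max(1, round(params$closing_radius_um / pixel_size))
  brush <- EBImage::makeBrush(2 * cl_px + 1, shape = "disc")
  mask <- as_mat(EBImage::closing(EBImage::Image(mask * 1), brush)) > 0
  lab <- as_mat(EBImage::bwlabel(mask))
  if (max(lab) == 0) stop("no tissue detected", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) * pixel_size^2 < params$min_tissue_area_um2) {
    stop("no tissue detected: largest component below min_tissue_area",
         call. = FALSE)
  }
  tissue <- lab == which.max(sizes)
  if (all(tissue)) stop("no lumen detected", call. = FALSE)
  coords <- extract_luminal_edge(tissue)
  new_epithelial_boundary(tissue, coords, provenance = "automatic",
                          pixel_size = pixel_size,
                          luminal_side = "complement")
}

# Bresenham rasterization of one segment; returns row/col matrix.
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) return(out[seq_len(i), , drop = FALSE])
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Build an epithelial boundary from a user-supplied polyline
#'
#' Headless counterpart of manual boundary tracing: the polyline (physical
#' coordinates, micrometers) is rasterized to an 8-connected pixel chain
#' and the tissue mask is the side opposite the stated luminal side.  The
#' polyline must span the full image along one axis so that it separates
#' the frame into two sides.
#'
#' @param polyline numeric matrix or data.frame with columns `x_um`, `y_um`
#'   (x along columns, y along rows, y increasing downward), >= 2 vertices.
#' @param image_shape integer `(rows, cols)`.
#' @param pixel_size micrometers per pixel.
#' @param luminal_side one of `"above"`, `"below"`, `"left"`, `"right"`.
#' @return an `epithelial_boundary` with `provenance = "manual"`.
#' @examples
#' pl <- cbind(x_um = c(0, 32), y_um = c(25, 25))
#' b <- manual_boundary(pl, c(64, 64), 0.5, "below")
#' sum(b$tissue_mask[1, ]) # top row is tissue
#' @export
manual_boundary <- function(polyline, image_shape, pixel_size,
                            luminal_side = c("below", "above", "left",
                                             "right")) {
  luminal_side <- match.arg(luminal_side)
  polyline <- as.matrix(as.data.frame(polyline)[, c("x_um", "y_um")])
  if (nrow(polyline) < 2) {
    stop("polyline must have at least 2 vertices", call. = FALSE)
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  if (any(polyline[, "x_um"] < 0 | polyline[, "x_um"] > nc * pixel_size |
            polyline[, "y_um"] < 0 | polyline[, "y_um"] > nr * pixel_size)) {
    stop("polyline vertices must lie inside the image frame", call. = FALSE)
  }
  nseg <- nrow(polyline) - 1
  if (nseg >= 3) {
    for (i in 1:(nseg - 2)) for (j in (i + 2):nseg) {
      if (segments_intersect(polyline[i, ], polyline[i + 1, ],
                             polyline[j, ], polyline[j + 1, ])) {
        stop("polyline is self-intersecting", call. = FALSE)
      }
    }
  }
  px <- cbind(row = pmin(pmax(floor(polyline[, "y_um"] / pixel_size + 0.5),
                              1), nr),
              col = pmin(pmax(floor(polyline[, "x_um"] / pixel_size + 0.5),
                              1), nc))
  chain <- px[1, , drop = FALSE]
  for (i in seq_len(nseg)) {
    seg <- bresenham(px[i, 1], px[i, 2], px[i + 1, 1], px[i + 1, 2])
    chain <- rbind(chain, seg[-1, , drop = FALSE])
  }
  chain <- chain[!duplicated(chain), , drop = FALSE]
  horizontal <- luminal_side %in% c("above", "below")
  span_cols <- min(chain[, "col"]) == 1 && max(chain[, "col"]) == nc
  span_rows <- min(chain[, "row"]) == 1 && max(chain[, "row"]) == nr
  if ((horizontal && !span_cols) || (!horizontal && !span_rows)) {
    stop("polyline does not span the image frame along the required axis",
         call. = FALSE)
  }
  tissue <- matrix(FALSE, nr, nc)
  if (horizontal) {
    for (cc in seq_len(nc)) {
      rows <- chain[chain[, "col"] == cc, "row"]
      if (!length(rows)) next
      if (luminal_side == "below") {
        tissue[1:min(rows), cc] <- TRUE
      } else {
        tissue[max(rows):nr, cc] <- TRUE
      }
    }
  } else {
    for (rr in seq_len(nr)) {
      cols <- chain[chain[, "row"] == rr, "col"]
      if (!length(cols)) next
      if (luminal_side == "right") {
        tissue[rr, 1:min(cols)] <- TRUE
      } else {
        tissue[rr, max(cols):nc] <- TRUE
      }
    }
  }
  chain <- order_chain(chain)
  colnames(chain) <- c("row", "col")
  new_epithelial_boundary(tissue, chain, provenance = "manual",
                          pixel_size = pixel_size,
                          luminal_side = luminal_side)
}

#' Resolve which side of a boundary is the lumen
#'
#' The lumen is identified as the side with lower mean DAPI intensity
#' within a probe depth of the boundary (nuclei are dense in tissue,
#' sparse in the lumen).  If the current tissue mask sits on the dimmer
#' side, the orientation is flipped.  Near-equal intensities raise an
#' ambiguity error prompting a manual override.
#'
#' @param boundary an `epithelial_boundary`.
#' @param dapi the DAPI channel matrix.
#' @param probe_depth_um depth of the band sampled on each side.
#' @param tol relative intensity difference below which the orientation is
#'   declared ambiguous.
#' @return the boundary, with `luminal_side = "oriented"` and possibly a
#'   flipped `tissue_mask`.
#' @export
orient_luminal_side <- function(boundary, dapi, probe_depth_um = 20,
                                tol = 0.1) {
  stopifnot(inherits(boundary, "epithelial_boundary"))
  check_same_shape(boundary$tissue_mask, dapi, "tissue_mask", "dapi")
  ps <- boundary$pixel_size
  if (is.na(ps)) ps <- 1
  m <- matrix(1, nrow(dapi), ncol(dapi))
  m[boundary$coords] <- 0
  dist_px <- as_mat(EBImage::distmap(m, metric = "euclidean"))
  band <- dist_px * ps <= probe_depth_um & dist_px > 0
  on_b <- matrix(FALSE, nrow(dapi), ncol(dapi))
  on_b[boundary$coords] <- TRUE
  side_tissue <- band & boundary$tissue_mask & !on_b
  side_lumen <- band & !boundary$tissue_mask
  if (!any(side_tissue) || !any(side_lumen)) {
    stop("cannot orient: a side of the boundary is empty", call. = FALSE)
  }
  m_t <- mean(dapi[side_tissue])
  m_l <- mean(dapi[side_lumen])
  ref <- max(abs(m_t), abs(m_l), .Machine$double.eps)
  if (abs(m_t - m_l) / ref < tol) {
    stop("ambiguous luminal side: near-equal DAPI intensity on both sides; supply a manual boundary with an explicit luminal side",
         call. = FALSE)
  }
  if (m_t < m_l) {
    flipped <- !boundary$tissue_mask
    coords <- extract_luminal_edge(flipped)
    boundary$tissue_mask <- flipped
    boundary$coords <- coords
  }
  boundary$luminal_side <- "oriented"
  boundary
}

#' Mean symmetric boundary discrepancy in pixels
#'
#' Average over both directions of the mean nearest-neighbor pixel distance
#' between two boundary coordinate sets; used to score detected boundaries
#' against generator ground truth.
#'
#' @param a,b row/col coordinate matrices.
#' @return mean symmetric distance in pixels.
#' @export
boundary_error <- function(a, b) {
  one_way <- function(p, q) {
    mean(vapply(seq_len(nrow(p)), function(i) {
      sqrt(min((p[i, 1] - q[, 1])^2 + (p[i, 2] - q[, 2])^2))
    }, 0))
  }
  (one_way(a, b) + one_way(b, a)) / 2
}
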