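# Internal helpers shared across modules.
#
# Pixel convention (stated once, used everywhere): images are numeric
# matrices indexed [row, col], 1-based, row 1 at the top.  Physical
# coordinates place the center of pixel (r, c) at y = (r - 0.5) * pixel_size,
# x = (c - 0.5) * pixel_size, with y increasing downward.  All distances are
# reported in micrometers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's random-number stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(master, i) {
  m <- 2147483629
  as.integer(((as.double(master) %% m) * 48271 + 9973 * as.double(i)) %% m)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_matrix2d <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a 2-D numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

check_same_shape <- function(a, b, na = "first", nb = "second") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %s is %s, %s is %s", na,
                 paste(dim(a), collapse = "x"), nb,
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(NULL)
}

# Coerce an EBImage result back to a plain matrix.
as_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Sobel gradient magnitude with replicated borders.
gradient_magnitude <- function(m) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), nrow = 3) / 8
  ky <- t(kx)
  gx <- as_mat(EBImage::filter2(m, kx, boundary = "replicate"))
  gy <- as_mat(EBImage::filter2(m, ky, boundary = "replicate"))
  sqrt(gx^2 + gy^2)
}

# Gaussian smoothing in pixel units; sigma 0 is the identity.
smooth_gaussian <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  as_mat(EBImage::gblur(m, sigma = sigma_px, boundary = "replicate"))
}

# Otsu threshold on the original intensity scale; NA for constant input.
otsu_threshold <- function(m, mask = NULL) {
  v <- if (is.null(mask)) m else m[mask]
  lo <- min(v)
  hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < .Machine$double.eps) {
    return(NA_real_)
  }
  x <- (m - lo) / (hi - lo)
  x[x < 0] <- 0
  x[x > 1] <- 1
  if (!is.null(mask)) {
    xm <- x
    xm[!mask] <- 0
    th <- EBImage::otsu(EBImage::Image(matrix(x[mask], ncol = 1)),
                        range = c(0, 1))
  } else {
    th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  }
  th * (hi - lo) + lo
}

# TRUE for mask pixels having at least one FALSE 8-neighbor inside the
# frame.  Image borders do not count as outside.
edge_of_mask <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(TRUE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  any_out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    any_out <- any_out | !pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  mask & any_out
}

# Order an 8-connected pixel chain by greedy walking from an endpoint.
# Falls back to lexicographic order for non-chain sets (ordering is
# presentational; distance computations use the coordinate set).
order_chain <- function(coords) {
  n <- nrow(coords)
  if (n <= 2) return(coords)
  key <- coords[, 1] * 1e6 + coords[, 2]
  idx <- seq_len(n)
  nb <- vector("list", n)
  ord0 <- order(coords[, 2], coords[, 1])
  coords <- coords[ord0, , drop = FALSE]
  key <- key[ord0]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in idx) assign(as.character(key[i]), i, envir = lookup)
  deg <- integer(n)
  for (i in idx) {
    r <- coords[i, 1]; c <- coords[i, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- as.character((r + dr) * 1e6 + (c + dc))
      j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) {
        nb[[i]] <- c(nb[[i]], j)
        deg[i] <- deg[i] + 1L
      }
    }
  }
  start <- which(deg == 1L)
  start <- if (length(start)) start[1] else 1L
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (step in idx) {
    path[step] <- cur
    visited[cur] <- TRUE
    nxt <- nb[[cur]][!visited[nb[[cur]]]]
    if (length(nxt) > 1) {
      # prefer 4-connected continuation so staircase corners are not
      # skipped by a diagonal shortcut
      ortho <- abs(coords[nxt, 1] - coords[cur, 1]) +
        abs(coords[nxt, 2] - coords[cur, 2]) == 1
      nxt <- c(nxt[ortho], nxt[!ortho])
    }
    if (!length(nxt)) {
      rest <- which(!visited)
      if (length(rest)) {
        path[(step + 1):n] <- rest
      }
      break
    }
    cur <- nxt[1]
  }
  coords[path, , drop = FALSE]
}

# Additively render a filled disk, keeping the pointwise maximum.
paint_disk_max <- function(m, r0, c0, radius_px, value) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- max(1L, floor(r0 - radius_px)):min(nr, ceiling(r0 + radius_px))
  cc <- max(1L, floor(c0 - radius_px)):min(nc, ceiling(c0 + radius_px))
  if (!length(rr) || !length(cc)) return(m)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  sub <- m[rr, cc, drop = FALSE]
  sel <- d2 <= radius_px^2 & sub < value
  sub[sel] <- value
  m[rr, cc] <- sub
  m
}

# Render many filled disks at once under pointwise-maximum compositing.
paint_disks_max <- function(m, rr, cc, rad, val) {
  nr <- nrow(m); nc <- ncol(m)
  idx_list <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    r1 <- max(1L, floor(rr[i] - rad[i])); r2 <- min(nr, ceiling(rr[i] + rad[i]))
    c1 <- max(1L, floor(cc[i] - rad[i])); c2 <- min(nc, ceiling(cc[i] + rad[i]))
    if (r1 > r2 || c1 > c2) next
    rs <- r1:r2; cs <- c1:c2
    d2 <- outer((rs - rr[i])^2, (cs - cc[i])^2, `+`)
    sel <- which(d2 <= rad[i]^2)
    if (!length(sel)) next
    idx_list[[i]] <- (rep(cs, each = length(rs))[sel] - 1L) * nr +
      rep(rs, times = length(cs))[sel]
  }
  n_px <- lengths(idx_list)
  if (!sum(n_px)) return(m)
  idx <- unlist(idx_list, use.names = FALSE)
  v <- rep(val, n_px)
  ord <- order(v)           # ascending: larger values overwrite smaller
  idx <- idx[ord]; v <- v[ord]
  keep <- v > m[idx]
  m[idx[keep]] <- v[keep]
  m
}

# Smooth zero-mean, unit-variance random field with a given correlation
# length (Gaussian kernel sigma) in micrometers.
random_field <- function(nr, nc, corr_um, pixel_size) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- smooth_gaussian(z, corr_um / pixel_size)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(matrix(0, nr, nc))
  (f - mean(f)) / s
}
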