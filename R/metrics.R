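#' Clip a circular buffer from a land-cover raster
#'
#' Cell membership is by the cell-centre test: a cell belongs to the buffer
#' when its centre lies within `radius_m` of `centre`. The landscape area of
#' the view is the member-cell count times the cell area.
#'
#' @param raster A `land_cover_raster`.
#' @param centre Numeric (x, y), metres.
#' @param radius_m Buffer radius in metres. The full circle must fit inside
#'   the raster extent.
#' @return An object of class `buffer_view`: the clipped class codes over the
#'   buffer's bounding box (`NA` outside the circle), the bounding-box offset
#'   into the raster, cell size, centre and radius.
#' @export
clip_buffer <- function(raster, centre, radius_m) {
  stopifnot(inherits(raster, "land_cover_raster"))
  if (!is.numeric(radius_m) || radius_m <= 0) stop("radius_m must be > 0")
  cs <- raster$cell_size
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  x0 <- raster$origin[1]; y0 <- raster$origin[2]
  if (centre[1] - radius_m < x0 || centre[1] + radius_m > x0 + nc * cs ||
      centre[2] - radius_m < y0 || centre[2] + radius_m > y0 + nr * cs)
    stop("buffer of radius ", radius_m, " m exceeds the raster extent")
  ## bounding box in matrix indices (row 1 = top)
  col_lo <- max(1L, floor((centre[1] - radius_m - x0) / cs) + 1L)
  col_hi <- min(nc, ceiling((centre[1] + radius_m - x0) / cs))
  row_top_y <- y0 + nr * cs
  row_lo <- max(1L, floor((row_top_y - (centre[2] + radius_m)) / cs) + 1L)
  row_hi <- min(nr, ceiling((row_top_y - (centre[2] - radius_m)) / cs))
  rows <- row_lo:row_hi; cols <- col_lo:col_hi
  cx <- x0 + (cols - 0.5) * cs
  cy <- y0 + (nr - rows + 0.5) * cs
  dx2 <- outer(rep(1, length(rows)), (cx - centre[1])^2)
  dy2 <- outer((cy - centre[2])^2, rep(1, length(cols)))
  inside <- (dx2 + dy2) <= radius_m^2
  if (!any(inside)) stop("buffer contains no cell centres")
  m <- raster$grid[rows, cols, drop = FALSE]
  m[!inside] <- NA_integer_
  structure(
    list(m = m, row0 = row_lo, col0 = col_lo, cell_size = cs,
         centre = as.numeric(centre), radius_m = radius_m,
         origin = raster$origin, raster_nrow = nr),
    class = "buffer_view"
  )
}

#' View covering a whole raster
#'
#' A rectangular `buffer_view` containing every cell of the raster, for
#' whole-landscape metric computation and exhaustive checks on small grids.
#'
#' @param raster A `land_cover_raster`.
#' @return A `buffer_view`.
#' @export
full_view <- function(raster) {
  stopifnot(inherits(raster, "land_cover_raster"))
  nr <- nrow(raster$grid); nc <- ncol(raster$grid); cs <- raster$cell_size
  structure(
    list(m = raster$grid, row0 = 1L, col0 = 1L, cell_size = cs,
         centre = raster$origin + c(nc, nr) * cs / 2, radius_m = Inf,
         origin = raster$origin, raster_nrow = nr),
    class = "buffer_view"
  )
}

## (x, y) centres of view cells given local matrix indices.
view_cell_xy <- function(view, idx) {
  nr_loc <- nrow(view$m)
  row_loc <- (idx - 1L) %% nr_loc + 1L
  col_loc <- (idx - 1L) %/% nr_loc + 1L
  rows <- view$row0 + row_loc - 1L
  cols <- view$col0 + col_loc - 1L
  cbind(x = view$origin[1] + (cols - 0.5) * view$cell_size,
        y = view$origin[2] + (view$raster_nrow - rows + 0.5) * view$cell_size)
}

## Index pairs of adjacent TRUE cells of a logical matrix. rook = E and S
## shifts; with diagonals also SE and SW (8-neighbour sense). Single count.
adjacent_pairs <- function(mask, diagonals = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- matrix(seq_along(mask), nr, nc)
  pairs <- list()
  if (nc > 1L) {
    a <- mask[, -nc, drop = FALSE] & mask[, -1L, drop = FALSE]
    pairs$E <- cbind(idx[, -nc, drop = FALSE][a], idx[, -1L, drop = FALSE][a])
  }
  if (nr > 1L) {
    a <- mask[-nr, , drop = FALSE] & mask[-1L, , drop = FALSE]
    pairs$S <- cbind(idx[-nr, , drop = FALSE][a], idx[-1L, , drop = FALSE][a])
  }
  if (diagonals && nr > 1L && nc > 1L) {
    a <- mask[-nr, -nc, drop = FALSE] & mask[-1L, -1L, drop = FALSE]
    pairs$SE <- cbind(idx[-nr, -nc, drop = FALSE][a],
                      idx[-1L, -1L, drop = FALSE][a])
    a <- mask[-1L, -nc, drop = FALSE] & mask[-nr, -1L, drop = FALSE]
    pairs$SW <- cbind(idx[-1L, -nc, drop = FALSE][a],
                      idx[-nr, -1L, drop = FALSE][a])
  }
  do.call(rbind, pairs)
}

## 8-connected component labelling of TRUE cells; returns an integer matrix
## (0 = not in class or outside view). Shared with the landscape generator,
## which labels its percolation stage 4-connected.
label_mask <- function(mask) label_mask_conn(mask, diagonals = TRUE)

#' Label the patches of a class inside a buffer
#'
#' Connected components of the focal-class mask under 8-neighbour
#' connectivity, restricted to the buffer. Components clipped at the buffer
#' edge count as present.
#'
#' @param view A `buffer_view`.
#' @param class_code Focal land-cover class code (1..7).
#' @return Integer matrix of component labels over the view's bounding box
#'   (0 elsewhere); the number of components is `max(labels)`.
#' @export
label_patches <- function(view, class_code) {
  stopifnot(inherits(view, "buffer_view"))
  mask <- !is.na(view$m) & view$m == class_code
  label_mask(mask)
}

#' Percentage of the buffer covered by a class
#'
#' @inheritParams label_patches
#' @return Percent cover in [0, 100].
#' @export
percent_cover <- function(view, class_code) {
  stopifnot(inherits(view, "buffer_view"))
  n <- sum(!is.na(view$m))
  100 * sum(view$m == class_code, na.rm = TRUE) / n
}

#' Patch density of a class (patches per hectare)
#'
#' Number of 8-connected components of the class divided by the buffer's
#' landscape area in hectares.
#'
#' @inheritParams label_patches
#' @return Patches per hectare (0 when the class is absent).
#' @export
patch_density <- function(view, class_code) {
  labels <- label_patches(view, class_code)
  area_ha <- sum(!is.na(view$m)) * view$cell_size^2 / 1e4
  max(labels) / area_ha
}

#' Aggregation index of a class (percent)
#'
#' Ratio of realized to maximum-possible like-adjacencies (shared edges
#' between same-class cells, rook sense, single count):
#' `AI = 100 * g / g_max`. For a class of `A` cells with `n = floor(sqrt(A))`
#' and `m = A - n^2`, `g_max` is `2n(n-1)` if `m = 0`, `2n(n-1) + 2m - 1` if
#' `m <= n`, and `2n(n-1) + 2m - 2` otherwise (the largest-square rule).
#' 100 means a single maximally compact patch.
#'
#' @inheritParams label_patches
#' @return Percent in [0, 100]; `NA` when the class is absent from the view;
#'   0 for a single-cell class (no adjacency possible).
#' @export
aggregation_index <- function(view, class_code) {
  stopifnot(inherits(view, "buffer_view"))
  mask <- !is.na(view$m) & view$m == class_code
  A <- sum(mask)
  if (A == 0L) return(NA_real_)
  pr <- adjacent_pairs(mask, diagonals = FALSE)
  g <- if (is.null(pr)) 0L else nrow(pr)
  n <- floor(sqrt(A)); m <- A - n^2
  gmax <- if (m == 0) 2 * n * (n - 1)
          else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
          else 2 * n * (n - 1) + 2 * m - 2
  if (gmax == 0) return(0)
  100 * g / gmax
}

#' Patch isolation of a class (metres)
#'
#' Mean over the class's patches of the nearest-neighbour distance to any
#' other patch of the same class, measured between cell centres.
#'
#' @inheritParams label_patches
#' @return Mean nearest-neighbour distance in metres, or `NA` when the view
#'   holds fewer than two patches of the class (isolation undefined).
#' @export
patch_isolation <- function(view, class_code) {
  labels <- label_patches(view, class_code)
  k <- max(labels)
  if (k < 2L) return(NA_real_)
  cells <- which(labels > 0L)
  lab <- labels[cells]
  xy <- view_cell_xy(view, cells)
  nn <- vapply(seq_len(k), function(comp) {
    own <- lab == comp
    dx <- outer(xy[own, 1], xy[!own, 1], "-")
    dy <- outer(xy[own, 2], xy[!own, 2], "-")
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
  mean(nn)
}

#' Area-weighted edge contrast of a class (percent)
#'
#' For each patch `k` of the focal class, the mean contrast over its
#' boundary edges: rook adjacencies between a patch cell and a cell of a
#' different class inside the buffer, weighted by
#' `d = (rank_focal - rank_neighbour) / 6` from the seven-point
#' habitat-quality ranking. Edges at the buffer rim (against cells outside
#' the view) are not counted, and a patch with no boundary edges inside the
#' view (fully interior) contributes 0. The returned value is the
#' area-weighted mean over patches, `sum(EC_k * A_k) / sum(A_k)`, in
#' percent.
#'
#' @inheritParams label_patches
#' @param ranking Named integer vector mapping class code to quality rank
#'   1..7, as from [quality_ranking()].
#' @return Percent in [0, 100] for the top-ranked focal class; `NA` when the
#'   class is absent.
#' @export
edge_contrast <- function(view, class_code, ranking = quality_ranking()) {
  labels <- label_patches(view, class_code)
  k <- max(labels)
  if (k < 1L) return(NA_real_)
  rank_of <- function(code) as.numeric(ranking[as.character(code)])
  r_focal <- rank_of(class_code)
  inview <- !is.na(view$m)
  pr <- adjacent_pairs(inview, diagonals = FALSE)
  wsum <- numeric(k); cnt <- numeric(k)
  if (!is.null(pr) && nrow(pr) > 0L) {
    for (swap in 1:2) {
      a <- pr[, swap]; b <- pr[, 3 - swap]
      sel <- labels[a] > 0L & view$m[b] != class_code
      if (any(sel)) {
        la <- labels[a][sel]
        d <- (r_focal - rank_of(view$m[b][sel])) / 6
        wsum <- wsum + vapply(seq_len(k), function(i) sum(d[la == i]),
                              numeric(1))
        cnt <- cnt + tabulate(la, nbins = k)
      }
    }
  }
  ec <- ifelse(cnt > 0, 100 * wsum / cnt, 0)
  area <- tabulate(labels[labels > 0L], nbins = k)
  sum(ec * area) / sum(area)
}

#' Class-level landscape metrics for patches across nested buffers
#'
#' Computes the six metrics around each patch centre and radius:
#' FC (percent old-growth forest cover), SF (percent secondary-forest
#' cover), PD (forest patch density, n/ha), AI (forest aggregation index,
#' percent), PI (forest patch isolation, metres; `NA` with fewer than two
#' forest patches), and EC (area-weighted forest edge contrast, percent).
#' FC and SF are composition metrics; PD, AI, PI and EC are configuration
#' metrics of the old-growth class.
#'
#' @param raster A `land_cover_raster`.
#' @param centres data.frame with columns patch_id, x, y (metres).
#' @param radii Buffer radii in metres (default the 13 radii 300-1500 m at
#'   100 m steps).
#' @param ranking Quality ranking for EC, see [quality_ranking()].
#' @param metrics Character subset of c("FC","SF","PD","AI","PI","EC").
#' @return data.frame with columns patch_id, radius_m, metric, value; one
#'   row per patch, radius and metric.
#' @export
metric_table <- function(raster, centres, radii = seq(300, 1500, by = 100),
                         ranking = quality_ranking(),
                         metrics = c("FC", "SF", "PD", "AI", "PI", "EC")) {
  stopifnot(inherits(raster, "land_cover_raster"))
  if (is.matrix(centres))
    centres <- data.frame(patch_id = paste0("P", seq_len(nrow(centres))),
                          x = centres[, 1], y = centres[, 2])
  metrics <- match.arg(metrics, several.ok = TRUE)
  cls <- land_cover_classes
  rows <- vector("list", nrow(centres) * length(radii))
  ii <- 0L
  for (p in seq_len(nrow(centres))) {
    for (r in radii) {
      v <- clip_buffer(raster, c(centres$x[p], centres$y[p]), r)
      vals <- c(
        FC = if ("FC" %in% metrics) percent_cover(v, cls[["old_growth"]]) else NA,
        SF = if ("SF" %in% metrics) percent_cover(v, cls[["secondary"]]) else NA,
        PD = if ("PD" %in% metrics) patch_density(v, cls[["old_growth"]]) else NA,
        AI = if ("AI" %in% metrics) aggregation_index(v, cls[["old_growth"]]) else NA,
        PI = if ("PI" %in% metrics) patch_isolation(v, cls[["old_growth"]]) else NA,
        EC = if ("EC" %in% metrics) edge_contrast(v, cls[["old_growth"]], ranking) else NA
      )
      ii <- ii + 1L
      rows[[ii]] <- data.frame(patch_id = centres$patch_id[p], radius_m = r,
                               metric = metrics,
                               value = unname(vals[metrics]),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
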