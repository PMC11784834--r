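#' Electrode-to-grid layout for spatial-spectral maps
#'
#' Places each electrode of the 62-channel extended 10-20 montage in a cell
#' of an `H x W` grid. Coordinates come from a schematic 2-D scalp
#' projection shipped with the package (version `"citnet-62-v1"`;
#' `inst/extdata/electrode_coords_62.tsv`, columns `label`, `x`, `y` in the
#' unit disc, nose up), or from a user file of the same shape. Each
#' electrode is assigned its nearest cell; if two electrodes land in the
#' same cell the later one (montage order) is moved to the nearest free
#' cell by a deterministic outward scan, keeping the mapping injective.
#'
#' @param H,W Grid height and width (default 32 x 32).
#' @param coords_file Optional path to a replacement coordinate table.
#' @return An object of class `electrode_layout`: a list with `table`
#'   (data.frame `label`, `x`, `y`, `row`, `col`), `H`, `W`, `version`.
#' @export
#' @examples
#' lay <- electrode_layout()
#' head(lay$table)
electrode_layout <- function(H = 32, W = 32, coords_file = NULL) {
  stopifnot(H >= 1, W >= 1)
  if (is.null(coords_file))
    coords_file <- system.file("extdata", "electrode_coords_62.tsv",
                               package = "citnet", mustWork = TRUE)
  tab <- utils::read.table(coords_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y") %in% names(tab)))
  if (nrow(tab) > H * W)
    stop("electrode_layout: ", nrow(tab), " electrodes cannot fit a ",
         H, "x", W, " grid injectively")
  clamp <- function(v, n) pmin(pmax(v, 1L), n)
  row <- clamp(1L + floor((1 - tab$y) / 2 * H), H)
  col <- clamp(1L + floor((tab$x + 1) / 2 * W), W)
  taken <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(tab))) {
    r <- row[i]; cl <- col[i]
    if (taken[r, cl]) {
      found <- FALSE
      for (rad in 1:max(H, W)) {
        offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
        offs <- offs[pmax(abs(offs$dr), abs(offs$dc)) == rad, , drop = FALSE]
        offs <- offs[order(offs$dr^2 + offs$dc^2, offs$dr, offs$dc), , drop = FALSE]
        for (j in seq_len(nrow(offs))) {
          rr <- r + offs$dr[j]; cc <- cl + offs$dc[j]
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && !taken[rr, cc]) {
            r <- rr; cl <- cc; found <- TRUE; break
          }
        }
        if (found) break
      }
      if (!found) stop("electrode_layout: no free cell for ", tab$label[i])
    }
    taken[r, cl] <- TRUE
    row[i] <- r; col[i] <- cl
  }
  tab$row <- row; tab$col <- col
  structure(list(table = tab, H = H, W = W, version = "citnet-62-v1"),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d electrodes on a %dx%d grid (version %s)\n",
              nrow(x$table), x$H, x$W, x$version))
  invisible(x)
}

#' Scatter a band-power table onto the scalp grid
#'
#' Builds the spatial-spectral representation: an `H x W x B` array in which
#' band slice `b` holds each electrode's power for band `b` at the
#' electrode's layout cell. In `"scatter"` mode unmapped cells are zero; in
#' `"interpolate"` mode they are filled by inverse-squared-distance weighted
#' averaging of all electrode values.
#'
#' @param bp Nonnegative electrodes x bands matrix with electrode row names
#'   (as from [band_power_table()]).
#' @param layout An [electrode_layout()].
#' @param mode `"scatter"` (default) or `"interpolate"`.
#' @param label Optional class label attached to the result.
#' @return An `H x W x B` array of class `spatial_spectral_map` with
#'   attributes `label` and `layout_version`.
#' @export
build_spatial_spectral <- function(bp, layout, mode = c("scatter", "interpolate"),
                                   label = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "electrode_layout"))
  bp <- as.matrix(bp)
  labs <- rownames(bp)
  if (is.null(labs)) stop("build_spatial_spectral: bp needs electrode row names")
  idx <- match(labs, layout$table$label)
  if (anyNA(idx))
    stop("build_spatial_spectral: electrode(s) missing from layout: ",
         paste(labs[is.na(idx)], collapse = ", "))
  cells <- layout$table[idx, c("row", "col")]
  if (anyDuplicated(cells))
    stop("build_spatial_spectral: layout is not injective for these electrodes")
  H <- layout$H; W <- layout$W; B <- ncol(bp)
  out <- array(0, c(H, W, B))
  lin <- cells$row + H * (cells$col - 1L)
  for (b in seq_len(B)) {
    slice <- matrix(0, H, W)
    slice[lin] <- bp[, b]
    if (mode == "interpolate") {
      grid <- expand.grid(row = seq_len(H), col = seq_len(W))
      empty <- setdiff(seq_len(H * W), lin)
      if (length(empty)) {
        d2 <- outer(grid$row[empty], cells$row, "-")^2 +
              outer(grid$col[empty], cells$col, "-")^2
        wgt <- 1 / pmax(d2, 1)
        slice[empty] <- (wgt %*% bp[, b]) / rowSums(wgt)
      }
    }
    out[, , b] <- slice
  }
  structure(out, label = label, layout_version = layout$version,
            class = c("spatial_spectral_map", "array"))
}

#' Read electrode values back out of a spatial-spectral map
#'
#' Inverse of [build_spatial_spectral()] in scatter mode: looks up each
#' layout cell and returns the electrodes x bands matrix.
#'
#' @param map A `spatial_spectral_map`.
#' @param layout The [electrode_layout()] used to build it.
#' @return Electrodes x bands matrix with electrode row names.
#' @export
read_map_cells <- function(map, layout) {
  H <- layout$H
  lin <- layout$table$row + H * (layout$table$col - 1L)
  B <- dim(map)[3]
  out <- vapply(seq_len(B), function(b) {
    slice <- map[, , b]
    slice[lin]
  }, numeric(nrow(layout$table)))
  rownames(out) <- layout$table$label
  out
}
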