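#' Electrode grid layout
#'
#' Describes the high-density surface EMG montage: grids of `rows x cols`
#' monopolar electrodes whose single-differential derivation along columns
#' yields a `(rows-1) x cols` channel map per grid. Several grids are assumed
#' coplanar and collinear along the muscle axis, separated edge-to-edge by
#' `inter_grid_mm`. The exact montage is configurable since it varies between
#' laboratories; the in-line default matches a four-grid vastus lateralis
#' setup with 8 mm inter-electrode distance.
#'
#' @param rows,cols Monopolar electrode rows and columns (13 x 5).
#' @param inter_electrode_mm Inter-electrode distance in mm (8 for large
#'   grids, 4 for small).
#' @param n_grids Number of grids (1 by default; 4 in the multi-grid montage).
#' @param inter_grid_mm Edge-to-edge distance between consecutive grids (mm).
#' @return A `grid_layout` object.
#' @export
grid_layout <- function(rows = 13, cols = 5, inter_electrode_mm = 8,
                        n_grids = 1, inter_grid_mm = 24) {
  stopifnot(rows >= 2, cols >= 1, inter_electrode_mm > 0, n_grids >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 inter_electrode_mm = inter_electrode_mm,
                 n_grids = as.integer(n_grids),
                 inter_grid_mm = inter_grid_mm),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout> %d grid(s) of %dx%d electrodes (%g mm), differential map %dx%d\n",
              x$n_grids, x$rows, x$cols, x$inter_electrode_mm,
              x$rows - 1L, x$cols))
  invisible(x)
}

#' Positions of differential channels in a common mm frame
#'
#' Differential channels sit midway between the two monopolar electrodes they
#' subtract; the y axis runs along the muscle (and grid sequence), x across
#' columns. Channel indices are column-major within a grid.
#'
#' @param layout A [grid_layout()].
#' @param grid Restrict to one grid index, or `NULL` for all grids.
#' @return A tibble: `grid`, `row`, `col`, `channel` (within-grid), `x_mm`,
#'   `y_mm`.
#' @export
electrode_positions <- function(layout, grid = NULL) {
  ie <- layout$inter_electrode_mm
  extent <- (layout$rows - 1L) * ie
  grids <- grid %||% seq_len(layout$n_grids)
  purrr::map_dfr(grids, function(g) {
    df <- expand.grid(row = seq_len(layout$rows - 1L),
                      col = seq_len(layout$cols))
    tibble(grid = g, row = df$row, col = df$col,
           channel = df$row + (df$col - 1L) * (layout$rows - 1L),
           x_mm = (df$col - 1) * ie,
           y_mm = (df$row - 0.5) * ie +
             (g - 1) * (extent + layout$inter_grid_mm))
  })
}

#' Spike-triggered average of multi-channel EMG
#'
#' Averages windows of the differential EMG centred on each firing time. The
#' average converges to the unit's action-potential waveform on every channel
#' as uncorrelated activity cancels. Spikes whose window would extend past
#' the recording edges are skipped and counted.
#'
#' @param emg Channels x samples matrix of single-differential EMG.
#' @param times Firing times (s) of one unit.
#' @param fs EMG sampling rate.
#' @param window Window duration in seconds (default 0.050), centred on the
#'   firing time.
#' @param unit_id Optional label carried in the result.
#' @return A `muap_template`: `waveforms` (channels x window-samples),
#'   `n_spikes` used, `n_skipped`, `fs`, `unit_id`.
#' @export
spike_triggered_average <- function(emg, times, fs, window = 0.050,
                                    unit_id = NULL) {
  nw <- round(window * fs)
  half <- floor(nw / 2)
  n <- ncol(emg)
  starts <- round(times * fs) - half + 1L
  ok <- starts >= 1L & (starts + nw - 1L) <= n
  if (!any(ok)) abort("No spike has a full averaging window inside the recording.")
  acc <- matrix(0, nrow(emg), nw)
  for (s in starts[ok]) acc <- acc + emg[, s:(s + nw - 1L), drop = FALSE]
  structure(
    list(waveforms = acc / sum(ok), n_spikes = sum(ok),
         n_skipped = sum(!ok), fs = fs, unit_id = unit_id),
    class = "muap_template"
  )
}

#' @export
print.muap_template <- function(x, ...) {
  cat(sprintf("<muap_template> %d channels x %d samples (%d spikes, %d skipped)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$n_spikes, x$n_skipped))
  invisible(x)
}

#' Peak-to-peak amplitude map of a MUAP template
#'
#' Computes the per-channel peak-to-peak amplitude and reshapes it onto the
#' `(rows-1) x cols` differential map. A 3 x 3 box blur guards the subsequent
#' argmax localization against single-channel artifacts; at map edges the
#' kernel is renormalized over the in-bounds neighbours (zero padding would
#' bias the argmax away from edges, defeating the purpose of the blur).
#'
#' @param tpl A `muap_template` (or a bare channels x samples matrix).
#' @param layout A [grid_layout()] defining the map shape.
#' @param blur Apply the 3 x 3 box blur (default `TRUE`).
#' @return A `(rows-1) x cols` numeric matrix of non-negative amplitudes.
#' @export
amplitude_map <- function(tpl, layout = grid_layout(), blur = TRUE) {
  w <- if (inherits(tpl, "muap_template")) tpl$waveforms else as.matrix(tpl)
  nr <- layout$rows - 1L
  if (nrow(w) != nr * layout$cols) {
    abort(sprintf("Template has %d channels; layout expects %d.",
                  nrow(w), nr * layout$cols))
  }
  p2p <- apply(w, 1, max) - apply(w, 1, min)
  m <- matrix(p2p, nrow = nr, ncol = layout$cols) # column-major channel order
  if (blur) m <- box_blur3(m)
  m
}

# 3x3 mean filter, kernel renormalized over in-bounds neighbours
box_blur3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1, i - 1):min(nr, i + 1)
    for (j in seq_len(nc)) {
      cj <- max(1, j - 1):min(nc, j + 1)
      out[i, j] <- mean(m[ri, cj])
    }
  }
  out
}

#' Locate a motor unit on the electrode montage
#'
#' The unit is placed at the differential channel with the highest (blurred)
#' amplitude across all grids. Argmax ties are broken towards the lowest
#' `(grid, row, col)` with a warning.
#'
#' @param maps A list of per-grid amplitude maps (as from [amplitude_map()]),
#'   in grid order.
#' @param layout A [grid_layout()] whose `n_grids` matches `length(maps)`.
#' @return A one-row tibble: `grid`, `row`, `col`, `x_mm`, `y_mm`.
#' @export
locate_unit <- function(maps, layout = grid_layout(n_grids = length(maps))) {
  if (!is.list(maps)) maps <- list(maps)
  stopifnot(length(maps) == layout$n_grids)
  v_max <- max(vapply(maps, max, numeric(1)))
  hits <- purrr::map_dfr(seq_along(maps), function(g) {
    hit <- which(maps[[g]] == v_max, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    tibble(grid = g, row = hit[, 1], col = hit[, 2])
  })
  if (nrow(hits) > 1) {
    warn("locate_unit: amplitude tie; lowest (grid, row, col) wins.")
    hits <- hits[order(hits$grid, hits$row, hits$col), ]
  }
  top <- hits[1, ]
  pos <- electrode_positions(layout, grid = top$grid)
  pos <- pos[pos$row == top$row & pos$col == top$col, ]
  tibble(grid = top$grid, row = top$row, col = top$col,
         x_mm = pos$x_mm, y_mm = pos$y_mm)
}

#' Distance between two located motor units
#'
#' @param loc_a,loc_b Locations from [locate_unit()].
#' @return Euclidean distance in mm within the common frame.
#' @export
unit_distance <- function(loc_a, loc_b) {
  sqrt((loc_a$x_mm - loc_b$x_mm)^2 + (loc_a$y_mm - loc_b$y_mm)^2)
}

#' @rdname unit_distance
#' @param maps_a,maps_b Per-grid amplitude maps for the two units.
#' @param layout A [grid_layout()].
#' @export
locate_and_distance <- function(maps_a, maps_b,
                                layout = grid_layout(n_grids = 4)) {
  unit_distance(locate_unit(maps_a, layout), locate_unit(maps_b, layout))
}
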