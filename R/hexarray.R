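#' Hexagonal microwell arrays
#'
#' A `well_array` describes the physical microwell chip: a bounded hexagonal
#' grid of wells, each carrying a distinct spatial barcode that is built into
#' its reverse-transcription primer. Wells are addressed by offset
#' coordinates `(row, col)` at the file boundary ("odd-r" packing: odd rows
#' are shifted half a pitch to the right) and by axial coordinates `(q, r)`
#' internally, where neighbor and ring arithmetic is simplest.
#'
#' @param wells data.frame with columns `well_id`, `row`, `col` (0-based
#'   offsets) and `spatial_barcode` (16-nt ACGT by default).
#' @param n_rows,n_cols grid bounds; wells must fall inside them.
#' @param pitch_um center-to-center well spacing in micrometers (default 500).
#' @param barcode_width expected spatial-barcode length.
#' @return An object of class `well_array`.
#' @export
well_array <- function(wells, n_rows = max(wells$row) + 1L,
                       n_cols = max(wells$col) + 1L, pitch_um = 500,
                       barcode_width = 16L) {
  stopifnot(is.data.frame(wells))
  need <- c("well_id", "row", "col", "spatial_barcode")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("well map is missing columns: ", paste(miss, collapse = ", "))
  wells <- as.data.frame(wells)[, need]
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  if (anyNA(wells$row) || anyNA(wells$col)) stop("malformed row/col in well map")
  if (any(wells$row < 0L) || any(wells$col < 0L) ||
      any(wells$row >= n_rows) || any(wells$col >= n_cols))
    stop("well offsets outside the ", n_rows, " x ", n_cols, " array bounds")
  if (anyDuplicated(wells[, c("row", "col")]))
    stop("duplicate (row, col) positions in well map")
  if (anyDuplicated(wells$well_id)) stop("duplicate well_id in well map")
  if (anyDuplicated(wells$spatial_barcode))
    stop("duplicate spatial barcodes in well map")
  if (!all(is_dna(wells$spatial_barcode)) ||
      !all(nchar(wells$spatial_barcode) == barcode_width))
    stop("spatial barcodes must be ", barcode_width, "-nt strings over ACGT")
  if (pitch_um <= 0) stop("pitch_um must be positive")
  # odd-r offset -> axial
  wells$q <- wells$col - (wells$row - wells$row %% 2L) %/% 2L
  wells$r <- wells$row
  rownames(wells) <- wells$well_id
  structure(list(wells = wells, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), pitch_um = pitch_um),
            class = "well_array")
}

#' @export
print.well_array <- function(x, ...) {
  cat(sprintf("well_array: %d wells on a %d x %d hex grid (pitch %g um)\n",
              nrow(x$wells), x$n_rows, x$n_cols, x$pitch_um))
  invisible(x)
}

#' Build a fully populated array with generated spatial barcodes
#'
#' Generates a complete `n_rows * n_cols` array (default 24 x 32 = 768 wells)
#' whose random 16-nt barcodes are pairwise at Hamming distance >= `min_dist`,
#' which makes single-mismatch correction unambiguous.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param seed RNG seed for barcode generation.
#' @param barcode_width barcode length in nt.
#' @param min_dist minimum pairwise Hamming distance between barcodes.
#' @param pitch_um well pitch in micrometers.
#' @return A `well_array`.
#' @export
make_well_array <- function(n_rows = 24L, n_cols = 32L, seed = 1L,
                            barcode_width = 16L, min_dist = 3L, pitch_um = 500) {
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  grid <- grid[, c("row", "col")]
  bcs <- with_seed(seed, random_barcodes(nrow(grid), barcode_width, min_dist))
  wells <- data.frame(
    well_id = sprintf("R%02dC%02d", grid$row, grid$col),
    row = grid$row, col = grid$col,
    spatial_barcode = bcs, stringsAsFactors = FALSE)
  well_array(wells, n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
             barcode_width = barcode_width)
}

well_index <- function(array, well_id) {
  i <- match(well_id, array$wells$well_id)
  if (anyNA(i)) stop("well(s) not on this array: ",
                     paste(well_id[is.na(i)], collapse = ", "))
  i
}

#' Hexagonal graph distance between wells
#'
#' Number of well-to-well steps separating two wells, i.e. shortest-path
#' length on the hexagonal adjacency graph. In axial coordinates the closed
#' form is `(|dq| + |dr| + |dq + dr|) / 2`.
#'
#' @param array a `well_array`.
#' @param a,b well ids (vectorized, recycled).
#' @return Integer vector of distances.
#' @export
hex_distance <- function(array, a, b) {
  ia <- well_index(array, a); ib <- well_index(array, b)
  w <- array$wells
  dq <- w$q[ia] - w$q[ib]
  dr <- w$r[ia] - w$r[ib]
  as.integer((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
}

#' Concentric layer of wells around a center
#'
#' Layer `l` is the set of wells at hexagonal distance exactly `l` from the
#' center: layer 1 is the immediate neighbors, layer 2 the wells two steps
#' away, and so on. On an unbounded grid layer `l >= 1` has `6 l` wells; on a
#' bounded chip edge layers are simply truncated.
#'
#' @param array a `well_array`.
#' @param center a well id.
#' @param l non-negative layer index.
#' @return Character vector of well ids (possibly empty at edges).
#' @export
well_layer <- function(array, center, l) {
  stopifnot(length(l) == 1, l >= 0)
  d <- hex_distance(array, array$wells$well_id, center)
  array$wells$well_id[d == l]
}

#' Read / write a well map
#'
#' The well map is a UTF-8, LF-terminated TSV with header columns
#' `well_id`, `row`, `col` (0-based), `spatial_barcode`. `write_well_map`
#' followed by `read_well_map` reproduces the array (grid bounds are taken
#' from the maximum occupied offsets).
#'
#' @param path TSV file path.
#' @param ... passed to [well_array()] (e.g. `pitch_um`).
#' @return `read_well_map` returns a `well_array`; `write_well_map`
#'   invisibly returns `path`.
#' @export
read_well_map <- function(path, ...) {
  df <- read_tsv(path, colClasses = c("character", "integer", "integer", "character"))
  well_array(df, ...)
}

#' @rdname read_well_map
#' @param array a `well_array`.
#' @export
write_well_map <- function(array, path) {
  stopifnot(inherits(array, "well_array"))
  write_tsv(array$wells[, c("well_id", "row", "col", "spatial_barcode")], path)
}
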