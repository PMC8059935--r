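#' Per-cell species call from a barnyard experiment
#'
#' In a mixed human/mouse run each cell barcode is called for the species
#' holding the majority of its UMIs: if the majority species carries at
#' least `threshold` of the cell's human + mouse UMIs the cell is assigned
#' to it, otherwise the barcode is deemed a collision (two cells of
#' different species sharing one combinatorial barcode). The default 0.66
#' is the canonical "less than 66% to a single species = collision" rule;
#' the boundary is inclusive. Cells with zero informative UMIs return NA.
#'
#' @param human_umis,mouse_umis per-cell UMI counts (vectorized).
#' @param threshold majority fraction required for a single-species call.
#' @return Character vector in `{"human", "mouse", "collision", NA}`.
#' @export
call_species <- function(human_umis, mouse_umis, threshold = 0.66) {
  tot <- human_umis + mouse_umis
  frac_major <- pmax(human_umis, mouse_umis) / tot
  out <- ifelse(frac_major >= threshold,
                ifelse(human_umis >= mouse_umis, "human", "mouse"),
                "collision")
  out[tot == 0] <- NA_character_
  out
}

#' Barcode collision rate
#'
#' Fraction of called cells deemed collisions. NA calls (zero-UMI cells)
#' are excluded from the denominator.
#'
#' @param calls character vector of species calls (see [call_species()]).
#' @return Fraction in `[0, 1]`.
#' @export
collision_rate <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) stop("no called cells")
  mean(calls == "collision")
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurements with the identity line:
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, computed with
#' population (1/n) moments as in Lin's original definition. Unlike Pearson
#' correlation it penalizes scale and location shifts, so
#' `|CCC| <= |Pearson r|`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Value in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("degenerate input: both vectors constant and equal")
  2 * sxy / denom
}

#' The 21-column species-mixing gradient design
#'
#' The mixing experiment deposits human and mouse cells across the array
#' columns at ratios 100/0, 90/10, ..., 0/100, ..., 90/10, 100/0: human
#' fractions descend from 1 to 0 over the first 11 columns and ascend back
#' to 1, giving 21 columns with exactly 11 distinct ratios (pure human at
#' the flanks, pure mouse in the center column).
#'
#' @return data.frame with columns `col` (0-based array column) and
#'   `human_frac`.
#' @export
gradient_design <- function() {
  frac <- c(seq(1, 0, by = -0.1), seq(0.1, 1, by = 0.1))
  data.frame(col = seq_along(frac) - 1L, human_frac = round(frac, 10))
}

#' Column-wise concordance with the gradient design
#'
#' Computes, for every array column with called cells, the observed human
#' fraction among single-species calls, pairs it with the design fraction,
#' and summarizes agreement by Lin's CCC.
#'
#' @param x a `spatial_counts` whose `cell_meta` carries `col` and
#'   `species` (see [build_count_matrix()]), or a data.frame with those
#'   columns.
#' @param design gradient design data.frame (default [gradient_design()]).
#' @return list with `columns` (data.frame: col, n_cells, observed_frac,
#'   expected_frac) and `ccc`.
#' @export
gradient_concordance <- function(x, design = gradient_design()) {
  cm <- if (inherits(x, "spatial_counts")) x$cell_meta else x
  stopifnot(all(c("col", "species") %in% names(cm)))
  cm <- cm[cm$species %in% c("human", "mouse"), , drop = FALSE]
  obs <- tapply(cm$species == "human", cm$col, mean)
  n <- tapply(cm$species, cm$col, length)
  cols <- as.integer(names(obs))
  exp_frac <- design$human_frac[match(cols, design$col)]
  missing_cols <- setdiff(design$col, cols)
  if (length(missing_cols))
    warning("design columns with no called cells excluded: ",
            paste(missing_cols, collapse = ", "))
  columns <- data.frame(col = cols, n_cells = as.integer(n),
                        observed_frac = as.numeric(obs),
                        expected_frac = exp_frac)
  list(columns = columns, ccc = lin_ccc(columns$observed_frac, columns$expected_frac))
}

#' Barnyard report table
#'
#' Per-cell species accounting: human/mouse UMIs, majority fraction and
#' call, in the layout written by the pipeline's `barnyard_report.tsv`.
#'
#' @param x a `spatial_counts` with `human_umis`/`mouse_umis` cell metadata.
#' @param threshold see [call_species()].
#' @return data.frame with columns `cell_id`, `human_umis`, `mouse_umis`,
#'   `fraction_major`, `call`.
#' @export
barnyard_report <- function(x, threshold = 0.66) {
  cm <- x$cell_meta
  tot <- cm$human_umis + cm$mouse_umis
  data.frame(cell_id = cm$cell_id, human_umis = cm$human_umis,
             mouse_umis = cm$mouse_umis,
             fraction_major = ifelse(tot > 0, pmax(cm$human_umis, cm$mouse_umis) / tot, NA),
             call = call_species(cm$human_umis, cm$mouse_umis, threshold),
             stringsAsFactors = FALSE)
}
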