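halfplane_cells <- function(array, n_per_well = 10, boundary_col = NULL) {
  w <- array$wells
  if (is.null(boundary_col)) boundary_col <- array$n_cols %/% 2
  data.frame(well_id = rep(w$well_id, each = n_per_well),
             cell_type = rep(ifelse(w$col < boundary_col, "MC38", "hepatocyte"),
                             each = n_per_well))
}

test_that("well composition tallies exactly and conserves cells", {
  a <- make_well_array(3, 3, seed = 1)
  cells <- data.frame(
    well_id = c(rep("R00C00", 3), rep("R01C01", 2), "R02C02"),
    cell_type = c("hepatocyte", "hepatocyte", "MC38", "MSC", "MC38", "hepatocyte"))
  comp <- well_composition(cells, a)
  expect_equal(comp$counts["R00C00", c("MC38", "hepatocyte")], c(MC38 = 1L, hepatocyte = 2L))
  expect_equal(sum(comp$counts), nrow(cells))          # conservation
  expect_equal(sum(comp$wells$n_cells == 0), 6)        # empty wells kept
  expect_error(well_composition(data.frame(well_id = "nope", cell_type = "MSC"), a),
               "not on the array")
})

test_that("colocalization matches the direct Pearson formula", {
  a <- make_well_array(2, 2, seed = 1)
  cells <- data.frame(
    well_id = rep(a$wells$well_id, times = c(4, 3, 2, 3)),
    cell_type = c("A", "A", "B", "B",  "A", "B", "B",  "A", "B",  "A", "A", "B"))
  comp <- well_composition(cells, a)
  x <- comp$counts[, "A"]; y <- comp$counts[, "B"]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cc <- colocalization(comp, "A", "B")
  expect_equal(cc$r, r_hand)
  # identical per-well counts give r = 1
  n_per_well <- c(3, 1, 2, 5)
  cells2 <- data.frame(
    well_id = rep(rep(a$wells$well_id, n_per_well), 2),
    cell_type = rep(c("A", "B"), each = sum(n_per_well)))
  comp2 <- well_composition(cells2, a)
  expect_equal(colocalization(comp2, "A", "B")$r, 1)
  # planted colocalization: two types share the same hot wells
  set.seed(8)
  b <- make_well_array(6, 6, seed = 2)
  hot <- sample(b$wells$well_id, 8)
  cells3 <- rbind(
    data.frame(well_id = rep(hot, each = 6), cell_type = rep(c("A", "B"), 24)),
    data.frame(well_id = sample(b$wells$well_id, 30, replace = TRUE),
               cell_type = sample(c("A", "B"), 30, replace = TRUE)))
  expect_gt(colocalization(well_composition(cells3, b), "A", "B")$r, 0)
  # degenerate input flagged: one C cell in every well => zero variance
  cells4 <- rbind(cells, data.frame(well_id = a$wells$well_id, cell_type = "C"))
  expect_warning(out <- colocalization(well_composition(cells4, a), "A", "C"),
                 "zero variance")
  expect_true(is.na(out$r))
})

test_that("decay weights normalize to 1 with geometric ratios", {
  w <- decay_weights(1.05, 10)
  expect_equal(sum(w$u), 1, tolerance = 1e-12)
  expect_equal(w$u[1] / w$u[10], 1.05^9)
  expect_true(all(diff(w$u) < 0))
  expect_equal(decay_weights(1, 10)$u, rep(0.1, 10))
  expect_error(decay_weights(0), "positive")
  expect_error(decay_weights(-1.05), "positive")
})

test_that("layered proximity scores hit the pure, boundary and mirrored cases", {
  a <- make_well_array(8, 10, seed = 3)
  all_tumor <- data.frame(well_id = rep(a$wells$well_id, each = 3), cell_type = "MC38")
  f1 <- tumor_proximity(well_composition(all_tumor, a), a)
  expect_equal(f1$score, rep(1, nrow(a$wells)))
  all_ref <- data.frame(well_id = rep(a$wells$well_id, each = 3), cell_type = "hepatocyte")
  expect_equal(tumor_proximity(well_composition(all_ref, a), a)$score,
               rep(0, nrow(a$wells)))
  # half-plane: boundary pair averages ~0.5 and column means fall tumor->tissue
  # (on compact arrays the L = 10 neighborhood is edge-truncated everywhere,
  # so per-row monotonicity is only exact at full chip scale -- covered by
  # the acceptance suite on the 24 x 32 array)
  cells <- halfplane_cells(a)
  comp <- well_composition(cells, a)
  f <- tumor_proximity(comp, a)
  colmeans <- tapply(f$score, f$col, mean)
  expect_equal(unname((colmeans["4"] + colmeans["5"]) / 2), 0.5, tolerance = 0.1)
  ord <- order(as.integer(names(colmeans)))
  expect_true(all(colmeans[ord][1:5] >= 0.5))   # tumor side above 0.5
  expect_true(all(colmeans[ord][6:10] <= 0.5))  # tissue side below 0.5
  expect_gt(colmeans[["0"]], colmeans[["9"]])
  # label swap mirrors the score
  f_ref <- tumor_proximity(comp, a, orientation = "reference")
  expect_equal(f_ref$score, 1 - f$score)
  swapped <- cells
  swapped$cell_type <- ifelse(cells$cell_type == "MC38", "hepatocyte", "MC38")
  f_sw <- tumor_proximity(well_composition(swapped, a), a)
  expect_equal(f_sw$score, 1 - f$score)
  # uniform composition is a fixed point
  mixed <- data.frame(well_id = rep(a$wells$well_id, each = 4),
                      cell_type = rep(c("MC38", "hepatocyte"), 2 * nrow(a$wells)))
  fu <- tumor_proximity(well_composition(mixed, a), a)
  expect_equal(fu$score, rep(0.5, nrow(a$wells)))
  # wells without scored cells drop their own term but still get a score
  sparse <- cells[cells$well_id != a$wells$well_id[1], ]
  fs <- tumor_proximity(well_composition(sparse, a), a)
  expect_false(anyNA(fs$score))
})

test_that("seeded linear scores equal the nearest-seed BFS evaluation", {
  a <- make_well_array(12, 12, seed = 5)
  seeds <- c("R00C11", "R05C11", "R11C11")
  f <- seeded_proximity(a, seeds, L = 10)
  expect_true(all(f$score[f$well_id %in% seeds] == 1))
  dmin <- do.call(pmin, lapply(seeds, function(s) bfs_distances(a, s)))
  expect_equal(f$score, pmax(0, 1 - dmin / 10))
  expect_equal(unique(f$score[dmin == 10]), 0)
  expect_equal(unique(f$score[dmin == 5]), 0.5)
  expect_error(seeded_proximity(a, character(0)), "seed well")
})

test_that("cells inherit their well's score", {
  a <- make_well_array(4, 4, seed = 6)
  f <- seeded_proximity(a, "R00C00", L = 10)
  wells <- c("R01C01", "R01C01", "R01C01", "R03C03")
  sc <- cell_scores(f, wells)
  expect_equal(sc[1:3], rep(f$score[f$well_id == "R01C01"], 3))
  # per-cell distribution = well distribution weighted by cells per well
  tab <- table(wells)
  expect_equal(sort(unname(sc)),
               sort(rep(f$score[match(names(tab), f$well_id)], tab)))
  expect_true(is.na(cell_scores(f, "R99C99")))
})
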