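make_toy_counts <- function(counts, gene_species, cell_species) {
  genes <- colnames(counts)
  x <- spatial_counts(counts,
                      data.frame(cell_id = rownames(counts),
                                 species = cell_species,
                                 human_umis = 0, mouse_umis = 0),
                      data.frame(gene_id = genes, species = gene_species,
                                 is_mito = FALSE))
  x
}

test_that("cross-species outlier flagging targets only high mouse genes", {
  counts <- rbind(h1 = c(500, 3, 1000, 0), h2 = c(10, 2, 900, 0),
                  m1 = c(5, 80, 0, 700))
  colnames(counts) <- c("mm10_hot", "mm10_cold", "GRCh38_a", "mm10_zero")
  x <- make_toy_counts(counts, c("mouse", "mouse", "human", "mouse"),
                       c("human", "human", "mouse"))
  flagged <- flag_cross_species_outliers(x)
  # mouse gene with 510 counts in human cells: log(511) = 6.24 > 6
  expect_equal(flagged, "mm10_hot")
  # raising the threshold clears it; human genes are never candidates
  expect_length(flag_cross_species_outliers(x, log_threshold = 7), 0)
  x2 <- make_toy_counts(counts, c("mouse", "mouse", "human", "mouse"),
                        c("mouse", "mouse", "mouse"))
  expect_warning(out <- flag_cross_species_outliers(x2), "no human cells")
  expect_length(out, 0)
})

test_that("EM recovers the analytic theta under disjoint cluster supports", {
  # cluster A expresses genes 1-4, cluster B genes 5-8; each A cell carries
  # 2 of its 10 counts on B's support => theta = 0.2 exactly
  # genes g1,g2 are A's support (native ratio 10:6); g3,g4 are B's; foreign
  # counts arrive in the other cluster's native proportions, with the
  # foreign load varying across cells so theta is identifiable per cell
  nA <- 15; nB <- 15
  mkA <- function(j) c(10, 6, 5 * j, 3 * j)  # theta = 8j / (16 + 8j)
  mkB <- function(j) c(5 * j, 3 * j, 10, 6)
  counts <- rbind(t(sapply(rep(0:2, 5), mkA)), t(sapply(rep(0:2, 5), mkB)))
  colnames(counts) <- paste0("g", 1:4)
  rownames(counts) <- paste0("c", 1:(nA + nB))
  x <- spatial_counts(counts, data.frame(cell_id = rownames(counts)),
                      data.frame(gene_id = colnames(counts)))
  cl <- rep(c("A", "B"), c(nA, nB))
  fit <- fit_decontamination(x, cl, max_iter = 2000, tol = 1e-12, seed = 3)
  truth <- rep(rep(c(0, 1 / 3, 1 / 2), 5), 2)
  expect_lte(max(abs(fit$theta - truth)), 2e-6)
  expect_true(all(rowSums(fit$phi) - 1 < 1e-12))
  expect_true(all(rowSums(fit$eta) - 1 < 1e-12))
  expect_error(fit_decontamination(x, rep("A", nA + nB)), ">= 2 clusters")
})

test_that("EM objective is monotone and clean data yields near-zero theta", {
  bn <- simulate_barnyard(n_rows = 5, cells_per_well = 6, seed = 31)
  cl <- bn$counts$cell_meta$species
  fit <- fit_decontamination(bn$counts, cl, max_iter = 60, seed = 1)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  expect_lt(median(fit$theta), 0.01)
})

test_that("planted Beta(2,8) contamination is recovered within tolerance", {
  bn <- simulate_barnyard(n_rows = 8, cells_per_well = 6,
                          n_genes_per_species = 150, seed = 13)
  amb <- inject_ambient(bn$counts, clusters = bn$truth$cells$species,
                        alpha = 2, beta = 8, seed = 14)
  cl <- ifelse(amb$counts$cell_meta$human_umis >=
                 amb$counts$cell_meta$mouse_umis, "human", "mouse")
  fit <- fit_decontamination(amb$counts, cl, seed = 2)
  med_est <- tapply(fit$theta, cl, median)
  med_true <- tapply(amb$theta, cl, median)
  expect_true(all(abs(med_est - med_true) <= 0.05))
  smry <- contamination_summary(fit)
  expect_equal(smry$median_theta_pct, 100 * as.numeric(med_est))
  expect_true(all(abs(smry$median_theta_pct - 100 * med_true) <= 2))
})

test_that("decontamination shrinks counts, preserves totals in expectation,
           and reduces the collision rate", {
  bn <- simulate_barnyard(n_rows = 8, cells_per_well = 6,
                          n_genes_per_species = 150, seed = 13)
  amb <- inject_ambient(bn$counts, clusters = bn$truth$cells$species,
                        alpha = 2, beta = 8, seed = 14)
  cl <- ifelse(amb$counts$cell_meta$human_umis >=
                 amb$counts$cell_meta$mouse_umis, "human", "mouse")
  fit <- fit_decontamination(amb$counts, cl, seed = 2)
  clean <- decontaminate(amb$counts, fit)
  raw <- amb$counts$counts
  expect_true(all(clean$counts@x >= 0))
  expect_true(all((raw - clean$counts)@x >= 0))  # never increases an entry
  real <- attr(clean, "corrected_real")
  expect_equal(as.numeric(Matrix::rowSums(real)),
               as.numeric((1 - fit$theta) * Matrix::rowSums(raw)),
               tolerance = 0.02)
  expect_lt(collision_rate(clean$cell_meta$species),
            collision_rate(amb$counts$cell_meta$species))
  # theta = 0 model acts as identity
  fit0 <- fit
  fit0$theta[] <- 0
  ident <- decontaminate(amb$counts, fit0)
  expect_true(all(ident$counts == raw))
})

test_that("per-cluster medians handle constant theta and singleton clusters", {
  counts <- matrix(5, 6, 4, dimnames = list(paste0("c", 1:6), paste0("g", 1:4)))
  x <- spatial_counts(counts, data.frame(cell_id = rownames(counts)),
                      data.frame(gene_id = colnames(counts)))
  model <- structure(list(theta = setNames(rep(0.1, 6), rownames(counts)),
                          clusters = factor(c("A", "A", "A", "B", "B", "C"))),
                     class = "contamination_model")
  smry <- contamination_summary(model)
  expect_equal(smry$median_theta_pct, rep(10, 3))
  model$theta[6] <- 0.42
  expect_equal(contamination_summary(model)$median_theta_pct[3], 42)
})
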