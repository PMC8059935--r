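test_that("NMF recovers planted low-rank structure with a monotone objective", {
  set.seed(12)
  W <- matrix(runif(80 * 2, 0.1, 1), 80, 2)
  H <- matrix(runif(2 * 50, 0.1, 1), 2, 50)
  X <- W %*% H
  ms <- fit_gene_modules(X, rank = 2, seed = 4, max_iter = 3000, tol = 1e-10)
  rel_err <- sqrt(sum((X - ms$basis %*% ms$coef)^2)) / sqrt(sum(X^2))
  expect_lt(rel_err, 1e-3)
  expect_true(all(diff(ms$objective) <= 1e-8 * ms$objective[-length(ms$objective)] + 1e-12))
  expect_true(all(ms$basis >= 0) && all(ms$coef >= 0))
  # rank-1 input: exact recovery up to scaling
  w1 <- runif(40, 0.5, 2); h1 <- runif(30, 0.5, 2)
  X1 <- outer(w1, h1)
  m1 <- fit_gene_modules(X1, rank = 1, seed = 4, max_iter = 2000, tol = 1e-12)
  expect_gt(abs(cor(as.numeric(m1$basis), w1)), 1 - 1e-6)
  expect_error(fit_gene_modules(-X, rank = 2), "non-negative")
  # smoothing interposition still factorizes
  msm <- fit_gene_modules(X, rank = 2, seed = 4, smoothing = 0.3, max_iter = 500)
  expect_true(all(diff(msm$objective) <= 1e-8 * msm$objective[-length(msm$objective)] + 1e-12))
  # determinism under a fixed seed
  ms2 <- fit_gene_modules(X, rank = 2, seed = 4, max_iter = 3000, tol = 1e-10)
  expect_identical(ms$basis, ms2$basis)
})

test_that("top contributing genes form the longest dominating prefix", {
  basis <- rbind(g1 = c(5, 1, 0), g2 = c(4, 2, 1), g3 = c(3, 1, 2),
                 g4 = c(1, 6, 0), g5 = c(2.5, 1, 1))
  colnames(basis) <- paste0("M", 1:3)
  ms <- fake_module_set(list(), basis = basis)
  # sorted by M1: g1 g2 g3 g5 g4; g1..g3 dominate, then g5 dominates too,
  # g4 peaks in M2 -> prefix of 4
  expect_equal(top_contributing_genes(ms, 1), c("g1", "g2", "g3", "g5"))
  expect_equal(top_contributing_genes(ms, "M2"), "g4")
  # a module dominated everywhere yields an empty prefix
  expect_length(top_contributing_genes(ms, 3), 0)
  # module whose every gene dominates returns the full list
  b2 <- cbind(M1 = c(5, 4, 3), M2 = c(1, 1, 1))
  rownames(b2) <- paste0("g", 1:3)
  expect_equal(top_contributing_genes(fake_module_set(list(), b2), 1),
               c("g1", "g2", "g3"))
  # brute-force oracle agreement on random bases
  set.seed(77)
  for (k in 1:20) {
    b <- matrix(runif(50 * 4), 50, 4, dimnames = list(paste0("g", 1:50), paste0("M", 1:4)))
    m <- sample(4, 1)
    expect_equal(top_contributing_genes(fake_module_set(list(), b), m),
                 brute_top_genes(b, m))
  }
  # output is always a prefix of the sorted list
  set.seed(78)
  b <- matrix(runif(200), 50, 4, dimnames = list(paste0("g", 1:50), paste0("M", 1:4)))
  ms_r <- fit_gene_modules(matrix(runif(50 * 30), 50, 30,
                                  dimnames = list(paste0("g", 1:50), NULL)),
                           rank = 4, seed = 9, max_iter = 200)
  for (m in 1:4) {
    top <- top_contributing_genes(ms_r, m)
    expect_identical(top, head(ms_r$sorted_genes[[m]], length(top)))
  }
})

test_that("module matching keeps best overlaps at or above 25%", {
  genes <- sprintf("g%04d", 1:1000)
  set.seed(3)
  mk_sets <- function() lapply(1:3, function(i) sample(genes, 400))
  a_lists <- mk_sets(); names(a_lists) <- paste0("LM", 1:3)
  # identical sets: every module matches itself with full overlap
  ms_a <- fake_module_set(a_lists)
  self <- match_modules(ms_a, ms_a, top_n = 200)
  expect_equal(self$module_b, self$module_a)
  expect_equal(self$overlap_count, rep(200L, 3))
  # disjoint top sets: nothing retained
  b_lists <- list(SM1 = rev(genes)[1:400])
  expect_equal(nrow(match_modules(fake_module_set(list(LM1 = genes[1:400])),
                                  fake_module_set(b_lists), top_n = 200)), 0)
  # planted 50/200 overlap sits exactly on the inclusive 25% boundary
  shared <- genes[1:50]
  la <- list(LM1 = c(shared, genes[101:250]))
  lb <- list(SM1 = c(shared, genes[301:450]))
  hit <- match_modules(fake_module_set(la), fake_module_set(lb), top_n = 200)
  expect_equal(hit$overlap_fraction, 0.25)
  expect_equal(nrow(hit), 1)
  # and one gene fewer falls below the cut
  lb49 <- list(SM1 = c(shared[1:49], genes[301:451]))
  expect_equal(nrow(match_modules(fake_module_set(la), fake_module_set(lb49),
                                  top_n = 200)), 0)
  # brute-force oracle agreement on random instances
  for (k in 1:10) {
    la_r <- lapply(1:3, function(i) sample(genes, 300)); names(la_r) <- paste0("LM", 1:3)
    lb_r <- lapply(1:4, function(i) sample(genes, 300)); names(lb_r) <- paste0("SM", 1:4)
    got <- match_modules(fake_module_set(la_r), fake_module_set(lb_r),
                         top_n = 250, min_frac = 0.1)
    want <- brute_match(lapply(la_r, head, 250), lapply(lb_r, head, 250),
                        250, 0.1)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("module_a", "module_b", "overlap_count")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("cell-type fractions normalize median-of-mean expression", {
  expr <- rbind(gA = c(4, 4, 0, 0), gB = c(2, 2, 0, 0), gC = c(1, 3, 1, 1))
  colnames(expr) <- paste0("c", 1:4)
  types <- c("T1", "T1", "T2", "T2")
  # genes expressed only in T1
  fr <- celltype_fractions(expr, types, c("gA", "gB"))
  expect_equal(unname(fr), c(1, 0))
  # hand computation for a 3-gene set: per-type means then median then normalize
  fr2 <- celltype_fractions(expr, types, c("gA", "gB", "gC"))
  m_t1 <- median(c(4, 2, 2)); m_t2 <- median(c(0, 0, 1))
  expect_equal(unname(fr2), c(m_t1, m_t2) / (m_t1 + m_t2))
  expect_equal(sum(fr2), 1)
  # equal expression splits evenly
  expr_eq <- rbind(g1 = rep(3, 4))
  expect_equal(unname(celltype_fractions(expr_eq, types, "g1")), c(0.5, 0.5))
  expect_error(celltype_fractions(expr, types, "missing"), "absent")
  expect_warning(celltype_fractions(expr * 0, types, c("gA", "gB")), "zero")
})

test_that("module projection binarizes wells against the weighted average", {
  a <- make_well_array(2, 3, seed = 1)
  wells <- a$wells$well_id
  # 2 cells per well; module gene hot in well 1 only
  cell_wells <- rep(wells[1:4], each = 2)
  expr <- rbind(mod1 = c(5, 5, 0, 0, 0, 0, 0.2, 0.2),
                other = runif(8))
  proj <- project_module(expr, cell_wells, "mod1", a)
  expect_equal(proj$label[match(wells[1], proj$well_id)], "high")
  expect_equal(proj$label[match(wells[4], proj$well_id)], "low")
  expect_equal(proj$label[match(wells[2], proj$well_id)], "none")
  expect_true(all(is.na(proj$label[proj$n_cells == 0])))
  # scaling invariance
  proj10 <- project_module(expr * 10, cell_wells, "mod1", a)
  expect_equal(proj10$label, proj$label)
  # uniform expression: nothing is strictly above the average
  expr_u <- rbind(mod1 = rep(2, 8))
  proj_u <- project_module(expr_u, cell_wells, "mod1", a)
  expect_false(any(proj_u$label == "high", na.rm = TRUE))
  # constant cells/well: weighted threshold equals the plain mean
  vals <- proj$mean_expr[proj$n_cells > 0]
  expect_equal(sum(proj$n_cells[proj$n_cells > 0] * vals) / sum(proj$n_cells),
               mean(vals))
})
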