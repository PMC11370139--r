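test_that("ranking sorts by expression and breaks ties reproducibly", {
  x <- c(g1 = 5, g2 = 9, g3 = 1, g4 = 7)
  r <- rank_genes(x)
  expect_equal(r[order(names(r))],
               c(g1 = 3L, g2 = 1L, g3 = 4L, g4 = 2L))
  # all-equal vector: a seeded permutation, identical across calls
  z <- setNames(rep(0, 20), paste0("g", 1:20))
  expect_identical(rank_genes(z, tie_seed = 7), rank_genes(z, tie_seed = 7))
  expect_false(identical(rank_genes(z, tie_seed = 7),
                         rank_genes(z, tie_seed = 8)))
  # ranks form a permutation
  expect_setequal(rank_genes(z, 3), 1:20)
})

test_that("tie-break order is uniform over seeds within a tied block", {
  # 4 tied genes -> 24 possible orders; chi-square over many seeds
  z <- rep(0, 4)
  n_seeds <- 4800
  perm_id <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    r <- rank_genes(z, tie_seed = s)
    perm_id[s] <- sum(r * 4^(0:3))
  }
  tab <- table(perm_id)
  expect_equal(length(tab), 24L)
  p <- chisq.test(as.vector(tab))$p.value
  expect_gt(p, 0.01)
})

test_that("recovery AUC hits its boundary values exactly", {
  n <- 100
  x <- setNames(seq(n, 1), paste0("g", 1:n))  # g1 highest ... g100 lowest
  r <- rank_genes(x)
  # the 5 top-ranked genes as the set, theta = 0.05 (T = 5) -> auc 1
  expect_equal(recovery_auc(r, paste0("g", 1:5), top_fraction = 0.05), 1.0)
  # a set entirely below the threshold -> 0
  expect_equal(recovery_auc(r, paste0("g", 50:59), top_fraction = 0.05), 0.0)
  # theta = 1 with the whole universe as the set -> 1
  expect_equal(recovery_auc(r, names(x), top_fraction = 1), 1.0)
  # empty overlap errors and names the unmatched ids
  expect_error(recovery_auc(r, c("nope1", "nope2")), "nope1")
})

test_that("recovery AUC equals a literal step-function accumulator", {
  set.seed(51)
  for (i in 1:50) {
    n <- 200
    x <- rnbinom(n, mu = 3, size = 1)
    r <- rank_genes(x, tie_seed = i)
    set_idx <- sample(n, 10)
    got <- recovery_auc(r, set_idx, top_fraction = 0.05)
    want <- brute_auc(r, set_idx, top_fraction = 0.05)
    expect_lt(abs(got - want), 1e-12)
  }
})

test_that("moving a set gene to a better rank never decreases the AUC", {
  set.seed(9)
  n <- 100
  r <- rank_genes(rnorm(n))
  set_idx <- which(r %in% c(3, 20, 40, 80))
  base <- recovery_auc(r, set_idx, top_fraction = 0.2)
  # swap the rank-40 set gene with the rank-10 non-set gene
  g40 <- which(r == 40); g10 <- which(r == 10)
  r2 <- r; r2[g40] <- 10L; r2[g10] <- 40L
  expect_gte(recovery_auc(r2, set_idx, top_fraction = 0.2), base)
})

test_that("AUC is invariant under strictly monotone transforms", {
  sim <- simulate_expression(n_genes = 150, n_cells_active = 5,
                             n_cells_inactive = 5, set_size = 8, seed = 21)
  a <- score_signatures(sim$counts, list(s = sim$set), seed = 4)
  b <- score_signatures(log1p(as.matrix(sim$counts)) * 7 + 2,
                        list(s = sim$set), seed = 4)
  expect_equal(a$auc, b$auc)
})

test_that("scoring is deterministic and independent of cell order", {
  sim <- simulate_expression(n_genes = 120, n_cells_active = 6,
                             n_cells_inactive = 6, set_size = 6, seed = 33)
  s1 <- score_signatures(sim$counts, list(s = sim$set), seed = 2)
  s2 <- score_signatures(sim$counts, list(s = sim$set), seed = 2)
  expect_identical(s1, s2)
  perm <- sample(ncol(sim$counts))
  s3 <- score_signatures(sim$counts[, perm], list(s = sim$set), seed = 2)
  m <- match(s1$barcode, s3$barcode)
  expect_equal(s1$auc, s3$auc[m])
})

test_that("missing set genes are dropped with a message, empty overlap warns NA", {
  sim <- simulate_expression(n_genes = 100, n_cells_active = 4,
                             n_cells_inactive = 4, set_size = 5, seed = 3)
  sets <- list(partial = c(sim$set, "NOT_A_GENE"),
               absent = c("FOO", "BAR"))
  expect_message(
    expect_warning(sc <- score_signatures(sim$counts, sets, seed = 1),
                   "absent"),
    "dropping 1/6")
  expect_true(all(is.na(sc$auc[sc$set == "absent"])))
  expect_true(all(!is.na(sc$auc[sc$set == "partial"])))
  expect_equal(unique(sc$n_set_genes[sc$set == "partial"]), 5L)
})

test_that("GMT files round-trip through write and read", {
  sets <- list(SASP_like = paste0("G", 1:12), tiny = c("A1", "B2"))
  p <- tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  back <- read_gmt(p)
  expect_equal(back, sets, ignore_attr = TRUE)
})

test_that("MTX triplets round-trip with dimnames intact", {
  sim <- simulate_expression(n_genes = 60, n_cells_active = 4,
                             n_cells_inactive = 3, set_size = 5, seed = 13)
  d <- file.path(tempfile(), "mtx")
  write_mtx_matrix(sim$counts, d)
  back <- read_mtx_matrix(d, strip_suffix = FALSE)
  expect_equal(as.matrix(back), as.matrix(sim$counts))
  expect_identical(rownames(back), rownames(sim$counts))
  expect_identical(colnames(back), colnames(sim$counts))
})
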