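test_that("beta-MNTD matches hand cases", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  m <- comm_matrix(rbind(s1 = c(a = 1, b = 0), s2 = c(a = 0, b = 1)))
  expect_equal(as.vector(beta_mntd(m, two)), 2)
  ident <- comm_matrix(rbind(s1 = c(a = 3, b = 1), s2 = c(a = 3, b = 1)))
  expect_equal(as.vector(beta_mntd(ident, two)), 0)
})

test_that("beta-MNTD equals the brute-force oracle and picante", {
  for (seed in 1:6) {
    tr <- simulate_tree(12, seed = seed)
    m <- random_comm(5, 12, seed = seed + 20)
    x <- unclass(m); colnames(x) <- tr$tip.label
    cm <- comm_matrix(x)
    D <- ape::cophenetic.phylo(tr)[colnames(x), colnames(x)]
    mine_w <- as.matrix(beta_mntd(cm, tr, abundance_weighted = TRUE))
    mine_u <- as.matrix(beta_mntd(cm, tr, abundance_weighted = FALSE))
    for (i in 1:4) {
      for (j in (i + 1):5) {
        expect_equal(mine_w[i, j], bmntd_brute(x[i, ], x[j, ], D, TRUE),
                     tolerance = 1e-10)
        expect_equal(mine_u[i, j], bmntd_brute(x[i, ], x[j, ], D, FALSE),
                     tolerance = 1e-10)
      }
    }
    skip_if_not_installed("picante")
    ref <- as.matrix(picante::comdistnt(x, D, abundance.weighted = TRUE))
    expect_equal(mine_w, ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("beta-NTI handles degenerate nulls and validates n_null", {
  ## star tree: all tip shuffles equivalent -> sd_null = 0 -> z = 0
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  m <- comm_matrix(rbind(s1 = c(a = 3, b = 1, c = 0, d = 0),
                         s2 = c(a = 0, b = 0, c = 2, d = 2)))
  z <- beta_nti(m, star, n_null = 99, seed = 1)
  expect_equal(z[1, 2], 0)
  expect_error(beta_nti(m, star, n_null = 50), "at least 99")
})

test_that("raup_crick_bray respects bounds, resolution and invariances", {
  m <- random_comm(6, 25, seed = 12, depth_range = c(100, 200))
  rc <- raup_crick_bray(m, n_null = 200, seed = 5)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_equal(rc, t(rc))

  ## invariant to taxon column order and sample order (same seed)
  x <- unclass(m)
  perm_t <- sample(ncol(x)); perm_s <- sample(nrow(x))
  rc2 <- raup_crick_bray(comm_matrix(x[, perm_t]), n_null = 200, seed = 5)
  expect_equal(rc, rc2[rownames(rc), colnames(rc)], tolerance = 1e-12)
  rc3 <- raup_crick_bray(comm_matrix(x[perm_s, ]), n_null = 200, seed = 5)
  expect_equal(rc, rc3[rownames(rc), colnames(rc)], tolerance = 1e-12)

  expect_error(raup_crick_bray(to_relative(m)), "integer counts")
})

test_that("process classification reproduces the threshold rules", {
  expect_equal(as.character(classify_processes(2.5, 0)), "variable_selection")
  expect_equal(as.character(classify_processes(-2.5, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_processes(0.5, 0.97)), "dispersal_limitation")
  expect_equal(as.character(classify_processes(1.0, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_processes(0, 0)), "drift")
  ## boundaries fall on the stochastic / drift side
  expect_equal(as.character(classify_processes(2, 0.99)), "dispersal_limitation")
  expect_equal(as.character(classify_processes(-2, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_processes(0, 0.95)), "drift")
  expect_equal(as.character(classify_processes(0, -0.95)), "drift")
  expect_error(classify_processes(NaN, 0), "non-finite")
})

test_that("process fractions sum to 100 per group and pool correctly", {
  pairs <- data.frame(
    sample_i = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
    sample_j = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
    process = factor(c("drift", "drift", "variable_selection",
                       "homogenizing_dispersal", "homogenizing_dispersal",
                       "drift", "drift"),
                     levels = assembly_processes()))
  groups <- c(a1 = "g1", a2 = "g1", a3 = "g1", b1 = "g2", b2 = "g2", b3 = "g2")
  fr <- process_fractions(pairs, groups)
  expect_equal(colSums(fr[, c("g1", "g2")]), c(g1 = 100, g2 = 100))
  ## cross-group pair (a1, b1) is excluded
  expect_equal(fr[fr$process == "drift", "g1"], 2 / 3 * 100)
  expect_equal(fr[fr$process == "homogenizing_dispersal", "g2"], 2 / 3 * 100)

  ## all-drift input gives a pure drift column
  all_drift <- pairs
  all_drift$process <- factor("drift", levels = assembly_processes())
  fr2 <- process_fractions(all_drift, groups)
  expect_equal(fr2[fr2$process == "drift", "g1"], 100)

  ## singleton group is omitted with a warning
  g3 <- c(groups, c1 = "g3")
  expect_warning(process_fractions(pairs, g3), "fewer than 2")
})

test_that("assembly_pairs classifies every pair deterministically", {
  sim <- simulate_metacommunity(sim_params(n_taxa = 60, n_per_group = 1,
                                           seed = 2))
  rar <- rarefy(sim$counts, 514, seed = 1)
  p1 <- assembly_pairs(rar, sim$tree, n_null_bnti = 99, n_null_rc = 99,
                       seed = 7)
  p2 <- assembly_pairs(rar, sim$tree, n_null_bnti = 99, n_null_rc = 99,
                       seed = 7)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), choose(nrow(rar), 2))
  expect_true(all(!is.na(p1$process)))
})
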