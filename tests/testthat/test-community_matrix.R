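test_that("community matrix validation and TSV round-trip", {
  counts <- matrix(c(1, 0, 3, 2, 5, 0, 0, 1, 4, 2, 2, 7), 3, 4,
                   dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  m <- comm_matrix(counts)
  expect_equal(dim(m), c(3, 4))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_community_matrix(m, path)
  m2 <- read_community_matrix(path)
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)

  ## taxa-as-rows orientation reads transposed
  tab <- data.frame(taxon_id = paste0("t", 1:4), t(counts))
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  m3 <- read_community_matrix(tpath, orientation = "taxa_rows")
  expect_equal(unclass(m3)[rownames(m), colnames(m)], unclass(m),
               ignore_attr = TRUE)

  counts[2, 3] <- -1
  expect_error(comm_matrix(counts), "negative.*s2.*t3")
  dup <- counts; dup[2, 3] <- 0; rownames(dup) <- c("a", "a", "b")
  expect_error(comm_matrix(dup), "duplicate sample")
})

test_that("filter_low_depth keeps samples at or above the cutoff", {
  counts <- rbind(s1 = c(499, 0), s2 = c(250, 250), s3 = c(300, 271))
  colnames(counts) <- c("t1", "t2")
  m <- comm_matrix(counts)
  out <- filter_low_depth(m, 500)
  expect_equal(rownames(out), c("s2", "s3"))
  expect_equal(rownames(filter_low_depth(m, 0)), rownames(m))
  expect_error(filter_low_depth(m, 1000), "below 1000")
})

test_that("rarefy hits exact depth, is seeded, and drops shallow samples", {
  m <- random_comm(6, 20, seed = 11, depth_range = c(400, 900))
  out <- rarefy(m, 514, seed = 5)
  expect_true(all(rowSums(out) == 514))
  out2 <- rarefy(m, 514, seed = 5)
  expect_identical(unclass(out), unclass(out2))
  expect_error(rarefy(m, 0), "depth")

  ## single-taxon sample passes through unchanged
  one <- comm_matrix(matrix(514, 1, 1, dimnames = list("s", "t")))
  expect_equal(as.vector(rarefy(one, 514, seed = 1)), 514)

  ## filtering at the rarefaction depth means rarefy drops nothing
  mf <- filter_low_depth(m, 514)
  expect_silent(r2 <- rarefy(mf, 514, seed = 2))
  expect_equal(nrow(r2), nrow(mf))
})

test_that("rarefaction matches the hypergeometric expectation", {
  ## mean taxon count over many rarefactions ~ depth * relative abundance
  counts <- matrix(c(200, 100, 50, 25, 25), 1, 5,
                   dimnames = list("s", paste0("t", 1:5)))
  m <- comm_matrix(counts)
  depth <- 80
  draws <- sapply(1:1000, function(i) unclass(rarefy(m, depth, seed = i))[1, ])
  expected <- depth * counts[1, ] / sum(counts)
  ## hypergeometric variance for each taxon count
  N <- sum(counts)
  vr <- depth * (counts[1, ] / N) * (1 - counts[1, ] / N) * (N - depth) / (N - 1)
  se <- sqrt(vr / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * pmax(se, 1e-9)))
})

test_that("to_relative normalises rows and is idempotent", {
  m <- comm_matrix(matrix(c(2, 2, 4, 1, 0, 1), 2, 3, byrow = TRUE,
                          dimnames = list(c("a", "b"), c("x", "y", "z"))))
  r <- to_relative(m)
  expect_equal(unname(unclass(r)["a", ]), c(0.25, 0.25, 0.5))
  expect_true(is_relative(r))
  expect_identical(to_relative(r), r)
  z <- comm_matrix(matrix(c(1, 0, 0, 0), 2, 2,
                          dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(to_relative(z), "zero-sum")
})

test_that("habitat class is a deterministic recode of habitat size", {
  expect_equal(habitat_class(c("1-ha", "10-ha", "100-ha", "continuous")),
               c("small", "small", "large", "large"))
  expect_error(habitat_class("5-ha"), "unknown habitat_size")
})
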