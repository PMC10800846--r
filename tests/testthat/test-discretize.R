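test_that("worked examples match the hand-computed class vectors", {
  a <- discretize_abundance(c(s1 = 0, s2 = 10, s3 = 30))
  expect_equal(a$scheme, "with_absent")
  expect_equal(a$mean, 20)
  expect_equal(as.character(a$classes$class), c("Absent", "Low", "High"))

  b <- discretize_abundance(c(s1 = 2, s2 = 10, s3 = 30))
  expect_equal(b$scheme, "all_present")
  expect_equal(b$mean, 14)
  expect_equal(unname(b$cutoffs), c(7, 21))
  expect_equal(as.character(b$classes$class), c("Low", "Medium", "High"))

  cst <- discretize_abundance(c(5, 5, 5))
  expect_true(cst$degenerate)
  expect_equal(as.character(cst$classes$class), rep("Medium", 3))
})

test_that("boundary counts follow the strict-inequality reading", {
  # with_absent: a count exactly at the nonzero mean is Low
  wa <- discretize_abundance(c(0, 10, 10, 40))  # nonzero mean = 20
  expect_equal(as.character(wa$classes$class),
               c("Absent", "Low", "Low", "High"))
  wa2 <- discretize_abundance(c(0, 20, 20, 20))  # all at the mean
  expect_equal(as.character(wa2$classes$class),
               c("Absent", "Low", "Low", "Low"))
  # all_present: counts exactly at 0.5m or 1.5m are Medium
  ap <- discretize_abundance(c(10, 20, 30))  # mean 20, cutoffs 10 and 30
  expect_equal(as.character(ap$classes$class), rep("Medium", 3))
})

test_that("discretization invariants hold on 1000 random count vectors", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      n <- sample(3:20, 1)
      x <- rnbinom(n, mu = sample(c(2, 20, 200), 1), size = 0.7)
      if (all(x == 0)) x[1] <- 1
      cl <- discretize_abundance(x)
      lab <- as.character(cl$classes$class)
      # exactly one class per sample, Absent iff zero
      expect_equal(length(lab), n)
      expect_false(anyNA(lab))
      expect_identical(lab == "Absent", x == 0)
      # scheme-specific exclusions
      if (cl$scheme == "with_absent") {
        expect_false(any(lab == "Medium"))
      } else {
        expect_false(any(lab == "Absent"))
      }
      # scale equivariance
      k <- runif(1, 0.1, 50)
      expect_identical(lab,
                       as.character(discretize_abundance(x * k)$classes$class))
    }
  })
})

test_that("degenerate and invalid inputs are handled", {
  expect_error(discretize_abundance(c(0, 0, 0)), "all counts are zero")
  expect_error(discretize_abundance(c(-1, 2)), "non-negative")
})

test_that("the class grid uses single letters and flags degenerate OTUs", {
  counts <- rbind(c(0, 5, 5), c(10, 5, 5), c(30, 5, 5), c(25, 5, 5))
  tb <- toy_table(counts, line = c("HAS", "HAS", "LAS", "LAS"))
  cg <- class_grid(tb, c("OTU_0001", "OTU_0002"))
  cells <- unlist(cg$grid[, -1])
  expect_true(all(cells %in% c("A", "L", "M", "H")))
  expect_identical(cg$degenerate, "OTU_0002")
  expect_error(class_grid(tb, "OTU_9999"), "absent")
})

test_that("ordinal encoding follows the realized class ladder", {
  wa <- discretize_abundance(c(a = 0, b = 10, c = 30))
  expect_equal(unname(class_ordinal(wa)), c(0, 1, 2))
  ap <- discretize_abundance(c(a = 2, b = 10, c = 30))
  expect_equal(unname(class_ordinal(ap)), c(0, 1, 2))
})
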