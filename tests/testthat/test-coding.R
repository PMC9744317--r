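# Survey coding: education recoding, involvement scales, alpha, z-scores.

child_pairs <- c(
  "8th grade or less" = 8,
  "some high school" = 10,
  "high school graduate" = 12,
  "some vocational/technical training" = 13,
  "completed vocational/technical training" = 14,
  "some college" = 14,
  "completed college" = 16,
  "some graduate school" = 17,
  "completed a master's degree" = 18,
  "some graduate training beyond a master's degree" = 19,
  "completed a doctoral degree" = 20,
  "some post-baccalaureate professional education" = 18,
  "completed post-baccalaureate professional education" = 19
)

parent_pairs <- c(
  "never went to school" = 0,
  "8th grade or less" = 8,
  "more than eighth grade, but did not graduate from high school" = 10,
  "went to a business, trade, or vocational school instead of high school" = 10,
  "high school graduate" = 12,
  "completed a GED" = 12,
  "went to a business, trade, or vocational school after high school" = 14,
  "went to college, but did not graduate" = 14,
  "graduated from a college or university" = 16,
  "professional training beyond a four-year college or university" = 18
)

test_that("every documented education category maps to its years", {
  expect_identical(recode_child_education(names(child_pairs)),
                   unname(as.integer(child_pairs)))
  expect_identical(recode_parent_education(names(parent_pairs)),
                   unname(as.integer(parent_pairs)))
  # the two maps cover exactly the documented label sets
  expect_setequal(education_map("child")$years, unique(unname(child_pairs)))
  expect_equal(nrow(education_map("child")), 13)
  expect_equal(nrow(education_map("parent")), 10)
})

test_that("label matching normalizes case and whitespace, rejects unknowns", {
  expect_equal(recode_child_education("  High School   Graduate "), 12L)
  expect_equal(recode_parent_education("COMPLETED A GED"), 12L)
  expect_error(recode_child_education("graduated summa cum laude"),
               "graduated summa cum laude")
  expect_identical(recode_child_education(c("some college", NA)),
                   c(14L, NA_integer_))
  # recoding is idempotent over the label set (total lookup)
  expect_identical(recode_child_education(toupper(names(child_pairs))),
                   recode_child_education(names(child_pairs)))
})

test_that("involvement scales sum their binary items within range", {
  expect_equal(build_involvement_scale(c(0, 0, 0), "school"), 0L)
  expect_equal(build_involvement_scale(c(1, 1, 1), "school"), 3L)
  expect_equal(build_involvement_scale(c(1, 0, 1, 0, 1), "leisure"), 3L)
  m <- matrix(rbinom(300, 1, 0.5), ncol = 3)
  s <- build_involvement_scale(m, "school")
  expect_true(all(s >= 0 & s <= 3))
  # invariant to item order
  expect_equal(build_involvement_scale(m[, 3:1], "school"), s)
  # missing item flags the person (NA), listwise for the scale
  m[1, 2] <- NA
  expect_true(is.na(build_involvement_scale(m, "school")[1]))
  expect_error(build_involvement_scale(c(1, 0), "school"), "3 items")
  expect_error(build_involvement_scale(c(1, 0, 2), "school"), "binary")
})

test_that("cronbach_alpha matches a hand evaluation and its properties", {
  # perfect consistency
  x <- rnorm(20)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)

  # 4-person x 3-item matrix against the direct formula computed by hand
  m <- matrix(c(1, 0, 1,
                0, 0, 1,
                1, 1, 1,
                0, 1, 0), nrow = 4, byrow = TRUE)
  k <- 3
  expected <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), expected, tolerance = 1e-12)

  # no common factor: alpha indistinguishable from 0 at n = 10,000
  set.seed(401)
  ind <- matrix(rbinom(30000, 1, 0.5), ncol = 3)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)

  # invariant to adding a constant to an item column
  m2 <- m; m2[, 1] <- m2[, 1] + 7
  expect_equal(cronbach_alpha(m2), cronbach_alpha(m), tolerance = 1e-12)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), "2 items")
})

test_that("standardize yields exact z-scores and rejects constants", {
  x <- rexp(50)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("wave coalescing prefers the primary wave", {
  expect_identical(coalesce_waves(c("a", NA, NA), c("x", "y", NA)),
                   c("a", "y", NA))
  expect_error(coalesce_waves(1:3, 1:2), "equal length")
})
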