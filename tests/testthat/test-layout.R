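test_that("built-in layouts have 64 uniquely labelled unit-norm electrodes", {
  for (kind in c("ten_twenty", "equidistant")) {
    l <- builtin_layout(kind)
    expect_equal(nrow(l), 64)
    expect_false(any(duplicated(l$label)))
    expect_true(all(abs(l$x^2 + l$y^2 + l$z^2 - 1) < 1e-9))
  }
  expect_true(all(c("Fp1", "Fp2", "Fz", "Cz", "Oz") %in%
                    builtin_layout("ten_twenty")$label))
  expect_true(all(c("1L", "1R") %in% builtin_layout("equidistant")$label))
  expect_error(builtin_layout("banana"), "unknown layout kind")
})

test_that("built-in layouts are deterministic and anatomically oriented", {
  expect_identical(builtin_layout("ten_twenty"), builtin_layout("ten_twenty"))
  expect_identical(builtin_layout("equidistant"),
                   builtin_layout("equidistant"))
  tt <- builtin_layout("ten_twenty")
  # frontal electrodes have y > 0 (nasion), occipital y < 0, left x < 0
  expect_gt(tt$y[tt$label == "Fp1"], 0.8)
  expect_lt(tt$y[tt$label == "Oz"], -0.8)
  expect_lt(tt$x[tt$label == "C3"], 0)
  expect_gt(tt$x[tt$label == "C4"], 0)
  eq <- builtin_layout("equidistant")
  expect_gt(eq$y[eq$label == "1L"], 0.8)  # 1L/1R are the frontal pair
  expect_lt(eq$x[eq$label == "1L"], 0)
})

test_that("equidistant layout is quasi-uniform (NN distance CV < 0.35)", {
  a <- capcompare:::nn_angles(builtin_layout("equidistant"))
  expect_lt(stats::sd(a) / mean(a), 0.35)
})

test_that("combined_layout unions by label with conflict detection", {
  tt <- builtin_layout("ten_twenty")
  eq <- builtin_layout("equidistant")
  cb <- combined_layout(tt, eq)
  expect_equal(nrow(cb), 128)
  expect_identical(cb$label[1:64], tt$label)
  # idempotence: a layout combined with itself is unchanged in content
  self <- combined_layout(tt, tt)
  expect_equal(nrow(self), 64)
  expect_identical(self$label, tt$label)
  # shared label count arithmetic
  sub <- eeg_layout(tt[1:10, ], kind = "custom")
  expect_equal(nrow(combined_layout(tt, sub)), 64)
  # conflicting shared position errors
  moved <- tt
  moved$x[moved$label == "Cz"] <- 0.3
  moved <- eeg_layout(tibble::as_tibble(moved), kind = "custom")
  expect_error(combined_layout(tt, moved), "conflicting positions")
})

test_that("angular_distance matches closed-form special cases", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(angular_distance(e1, e1), 0)
  expect_equal(angular_distance(e1, -e1), pi)
  expect_equal(angular_distance(e1, e2), pi / 2)
  expect_error(angular_distance(c(1, 1, 0), e1), "unit vectors")
})

test_that("electrodes.tsv round-trips and rejects malformed rows", {
  l <- builtin_layout("equidistant")
  path <- withr::local_tempfile(fileext = ".tsv")
  save_layout(l, path)
  l2 <- load_layout(path)
  expect_identical(l2$label, l$label)
  expect_lt(max(abs(layout_positions(l2) - layout_positions(l))), 1e-9)

  # missing column
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tx\ty", "Cz\t0\t0"), bad)
  expect_error(load_layout(bad), "missing column")

  # zero-norm position names the row
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tx\ty\tz", "Cz\t0\t0\t1", "Pz\t0\t0\t0"), bad2)
  expect_error(load_layout(bad2), "zero-norm")

  # duplicate label
  bad3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tx\ty\tz", "Cz\t0\t0\t1", "Cz\t0\t1\t0"), bad3)
  expect_error(load_layout(bad3), "duplicate")
})

test_that("layout constructor renormalizes and enforces separation", {
  df <- tibble::tibble(label = c("a", "b"), x = c(0, 0), y = c(0, 2),
                       z = c(2, 0.01))
  l <- eeg_layout(df)
  expect_equal(sqrt(l$x^2 + l$y^2 + l$z^2), c(1, 1))
  near <- tibble::tibble(label = c("a", "b"), x = c(0, 1e-9), y = c(0, 0),
                         z = c(1, 1))
  expect_error(eeg_layout(near), "closer than")
})
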