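# Raster stacks, ASCII grid round-trips, accessible areas and the Pearson
# variable screen.

test_that("stack construction intersects per-layer validity masks", {
  a <- matrix(1, 10, 10)
  b <- matrix(2, 10, 10)
  s <- env_stack(list(a = a, b = b), "T1")
  expect_equal(sum(s$mask), 100)

  b[1, 1:5] <- NA
  s2 <- env_stack(list(a = a, b = b), "T1")
  expect_equal(sum(s2$mask), 95)

  expect_error(env_stack(list(a = a, b = matrix(0, 10, 11)), "T1"),
               "alignment error.*b")
})

test_that("asc files round-trip values, nodata and geometry", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  p <- file.path(dir, "x.asc")
  write_asc(m, p, geometry = list(xll = -105, yll = 18.5, cellsize = 0.25))
  r <- read_asc(p)
  expect_equal(r$data, m)
  expect_equal(r$geometry$xll, -105)
  expect_equal(r$geometry$yll, 18.5)
  expect_equal(r$geometry$cellsize, 0.25)
  expect_equal(r$geometry$nrow, 5)
})

test_that("load_stack assembles layers and flags geometry mismatches", {
  dir <- withr::local_tempdir()
  write_asc(matrix(1:100, 10, 10), file.path(dir, "v1.asc"))
  write_asc(matrix(101:200, 10, 10), file.path(dir, "v2.asc"))
  s <- load_stack(c(v1 = file.path(dir, "v1.asc"),
                    v2 = file.path(dir, "v2.asc")), "T1")
  expect_named(s$variables, c("v1", "v2"))
  expect_equal(sum(s$mask), 100)

  write_asc(matrix(0, 10, 11), file.path(dir, "bad.asc"))
  expect_error(load_stack(c(v1 = file.path(dir, "v1.asc"),
                            bad = file.path(dir, "bad.asc")), "T1"),
               "alignment error.*bad")
  expect_error(load_stack(c(v = file.path(dir, "absent.asc")), "T1"),
               "cannot read")
})

test_that("manifest loading builds aligned period stacks", {
  dir <- withr::local_tempdir()
  for (per in c("t1", "t2")) for (v in c("bio1", "bio2"))
    write_asc(matrix(rnorm(100), 10, 10),
              file.path(dir, paste0(per, "_", v, ".asc")))
  yaml::write_yaml(list(T1 = list(bio1 = "t1_bio1.asc", bio2 = "t1_bio2.asc"),
                        T2 = list(bio1 = "t2_bio1.asc", bio2 = "t2_bio2.asc")),
                   file.path(dir, "manifest.yaml"))
  stacks <- load_stack_manifest(file.path(dir, "manifest.yaml"))
  expect_named(stacks, c("T1", "T2"))
  expect_named(stacks$T2$variables, c("bio1", "bio2"))
})

test_that("extract_values honours the half-open cell convention", {
  s <- toy_stack(4, 4)
  # cell centers: x = col - 0.5, y = 4 - row + 0.5 (unit cells, origin 0)
  v <- extract_values(s, cbind(1.5, 2.5))   # col 2, row 2
  expect_equal(v$row, 2)
  expect_equal(v$col, 2)
  expect_equal(v$a, s$variables$a[2, 2])

  expect_error(extract_values(s, cbind(9, 1)), "bounds error.*1")

  s$variables$a[1, 1] <- NA
  s <- env_stack(s$variables, "T1")
  v2 <- extract_values(s, rbind(c(0.5, 3.5), c(1.5, 2.5), c(2.5, 2.5)))
  expect_equal(v2$valid, c(FALSE, TRUE, TRUE))
  expect_true(is.na(v2$a[1]))
  expect_equal(sum(v2$valid), 2)
})

test_that("extract_values is unchanged after a write/read round-trip", {
  s <- toy_stack(8, 8, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_stack(s, dir)
  s2 <- load_stack(paths, "T1")
  pts <- cbind(runif(20, 0, 8), runif(20, 0, 8))
  expect_equal(extract_values(s2, pts), extract_values(s, pts))
})

test_that("accessible area clipping follows occupied ecoregions", {
  s <- toy_stack(6, 6)
  eco <- matrix(rep(1:3, each = 12), 6, 6, byrow = TRUE)  # 3 horizontal bands
  occ <- occ_at_cells(s, c(1, 3))           # both in region 1 (rows 1-2)
  m <- clip_to_accessible_area(s, eco, occ)
  expect_equal(sum(m$mask), 12)
  expect_equal(m$source_polygons, 1)

  occ2 <- occ_at_cells(s, c(1, 35))         # regions 1 and 3
  m2 <- clip_to_accessible_area(s, eco, occ2)
  expect_equal(sum(m2$mask), 24)
  expect_setequal(m2$source_polygons, c(1, 3))

  # synthetic mode: full grid, then an explicit rectangle
  expect_equal(sum(clip_to_accessible_area(s, NULL, occ)$mask), 36)
  r <- clip_to_accessible_area(s, NULL, occ, rectangle = c(1, 2, 1, 3))
  expect_equal(sum(r$mask), 6)

  eco_na <- matrix(NA_integer_, 6, 6)
  expect_error(clip_to_accessible_area(s, eco_na, occ), "empty-M")
})

test_that("accessible area never grows when occurrences shrink", {
  s <- toy_stack(6, 6)
  eco <- matrix(rep(1:4, each = 9), 6, 6, byrow = TRUE)
  cells <- c(1, 10, 20, 30)
  for (k in length(cells):2) {
    big <- clip_to_accessible_area(s, eco, occ_at_cells(s, cells[1:k]))
    small <- clip_to_accessible_area(s, eco, occ_at_cells(s, cells[1:(k - 1)]))
    expect_true(all(big$mask | !small$mask))  # small subset of big
  }
})

test_that("variable screen drops duplicates and respects the threshold", {
  set.seed(5)
  a <- matrix(rnorm(100), 10, 10)
  c_ <- matrix(rnorm(100), 10, 10)
  s <- env_stack(list(A = a, B = a, C = c_), "T1")
  kept <- select_uncorrelated_variables(s, full_area(s), threshold = 0.8)
  expect_setequal(kept, c("A", "C"))

  s2 <- env_stack(list(A = a, C = c_), "T1")
  expect_equal(select_uncorrelated_variables(s2, full_area(s2)), c("A", "C"))

  expect_error(select_uncorrelated_variables(
    env_stack(list(A = a), "T1"), full_area(s)), "at least 2")
  s3 <- env_stack(list(A = a, K = matrix(1, 10, 10), C = c_), "T1")
  expect_warning(k3 <- select_uncorrelated_variables(s3, full_area(s3)),
                 "constant")
  expect_setequal(k3, c("A", "C"))
})

test_that("variable screen matches a greedy brute-force oracle and is idempotent", {
  # oracle: same greedy rule, written independently over the plain matrix
  greedy_oracle <- function(x, thr) {
    keep <- seq_len(ncol(x))
    repeat {
      cm <- abs(stats::cor(x[, keep, drop = FALSE]))
      diag(cm) <- 0
      if (all(cm <= thr)) return(colnames(x)[keep])
      off <- unique(as.vector(which(cm > thr, arr.ind = TRUE)))
      off <- sort(off)
      score <- sapply(off, function(i) mean(cm[i, -i]))
      keep <- keep[-off[order(-score, -off)][1]]
    }
  }
  set.seed(11)
  for (rep in 1:5) {
    L <- matrix(rnorm(25), 5, 5)
    z <- matrix(rnorm(200 * 5), 200, 5) %*% (L + diag(2, 5))
    colnames(z) <- paste0("v", 1:5)
    layers <- lapply(1:5, function(j) matrix(z[, j], 20, 10))
    names(layers) <- colnames(z)
    s <- env_stack(layers, "T1")
    kept <- select_uncorrelated_variables(s, full_area(s), 0.6)
    expect_equal(kept, greedy_oracle(z, 0.6))
    # idempotence
    s_kept <- subset_stack(s, kept)
    expect_equal(select_uncorrelated_variables(s_kept, full_area(s_kept), 0.6),
                 kept)
  }
})
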