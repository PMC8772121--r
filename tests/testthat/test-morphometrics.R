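test_that("read_tps parses LM, SCALE and multiple specimens", {
  f <- tempfile(fileext = ".tps")
  writeLines(c("LM=3", "2 4", "6 8", "10 0", "ID=spec1", "SCALE=0.5",
               "LM=3", "0 0", "1 0", "0 1", "IMAGE=img2.jpg"), f)
  cfg <- read_tps(f)
  expect_length(cfg, 2)
  expect_equal(cfg[[1]]$id, "spec1")
  expect_equal(cfg[[1]]$coords, rbind(c(1, 2), c(3, 4), c(5, 0)))
  expect_equal(cfg[[2]]$id, "img2.jpg")
  expect_null(cfg[[2]]$scale)
  # landmark-count mismatch names the specimen
  f2 <- tempfile(fileext = ".tps")
  writeLines(c("LM=20", "0 0", "1 1", "ID=bad"), f2)
  expect_error(read_tps(f2), "bad")
})

test_that("TPS write/read round trip is exact", {
  set.seed(14)
  cfgs <- lapply(1:4, function(i)
    list(id = paste0("w", i), coords = matrix(rnorm(20), 10, 2),
         scale = if (i %% 2) 0.3742 else NULL))
  f <- tempfile(fileext = ".tps")
  write_tps(cfgs, f)
  back <- read_tps(f)
  for (i in 1:4) {
    expect_equal(back[[i]]$id, cfgs[[i]]$id)
    expect_equal(back[[i]]$coords, cfgs[[i]]$coords, tolerance = 1e-14)
  }
})

test_that("centroid size follows its definition and invariances", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(centroid_size(sq), 2 * sqrt(2))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(centroid_size(sweep(sq %*% R, 2, c(3, -2), `+`)),
               centroid_size(sq))
  expect_equal(centroid_size(sq * 2), 2 * centroid_size(sq))
  expect_warning(centroid_size(matrix(1, 3, 2)), "degenerate")
})

test_that("baseline registration maps the baseline to (0,0)-(1,0)", {
  set.seed(3)
  x <- matrix(rnorm(16), 8, 2)
  reg <- baseline_register(x, 2, 6)
  expect_equal(reg[2, ], c(0, 0), tolerance = 1e-12)
  expect_equal(reg[6, ], c(1, 0), tolerance = 1e-12)
  # already registered input is unchanged
  expect_equal(baseline_register(reg, 2, 6), reg, tolerance = 1e-12)
  # a baseline of length 2 halves all inter-landmark distances
  y <- x; y[2, ] <- c(0, 0); y[6, ] <- c(2, 0)
  expect_equal(as.matrix(dist(baseline_register(y, 2, 6))),
               as.matrix(dist(y)) / 2, tolerance = 1e-12)
  expect_error(baseline_register(rbind(c(0, 0), c(0, 0), c(1, 1)), 1, 2),
               "coincide")
})

test_that("GPA exactly superimposes similarity-transformed copies", {
  tpl <- default_wing_template(12)
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shapes <- array(0, c(2, 12, 2))
  shapes[1, , ] <- tpl
  shapes[2, , ] <- sweep(tpl %*% R, 2, c(5, -3), `+`)
  res <- gpa_align(shapes)
  expect_true(res$converged)
  expect_lt(sum((res$aligned[1, , ] - res$aligned[2, , ])^2), 1e-20)
  expect_lt(tail(res$objective, 1), 1e-10)
})

test_that("GPA consensus recovers the generating shape from noisy copies", {
  tpl <- default_wing_template(20)
  set.seed(1)
  n <- 50
  shapes <- array(0, c(n, 20, 2))
  for (i in seq_len(n)) {
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shapes[i, , ] <- (tpl + matrix(rnorm(40, 0, 0.01), 20, 2)) %*% R *
      runif(1, 0.5, 2) + rep(runif(2, -3, 3), each = 20)
  }
  res <- gpa_align(shapes)
  expect_lt(procrustes_distance(res$mean_shape, tpl), 0.005)
  # normalization postconditions
  expect_lt(max(abs(colMeans(res$mean_shape))), 1e-12)
  expect_equal(sum(res$mean_shape^2), 1, tolerance = 1e-10)
  # objective is monotone non-increasing
  expect_true(all(diff(res$objective) <= 1e-12))
  # order invariance of the converged objective
  res2 <- gpa_align(shapes[n:1, , ])
  expect_lt(abs(tail(res$objective, 1) - tail(res2$objective, 1)), 1e-10)
})

test_that("two-shape GPA agrees with an independent Procrustes solver", {
  skip_if_not_installed("vegan")
  set.seed(8)
  a <- matrix(rnorm(24), 12, 2)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  b <- (a + matrix(rnorm(24, 0, 0.05), 12, 2)) %*% R * 1.7 + 2
  shapes <- array(0, c(2, 12, 2)); shapes[1, , ] <- a; shapes[2, , ] <- b
  res <- gpa_align(shapes)
  # vegan solves the pairwise orthogonal-Procrustes problem; on pre-centred
  # unit-size shapes (where the optimum is a proper rotation) the minimised
  # residual sum of squares must agree with the two-shape GPA superimposition
  cs <- function(x) { x <- sweep(x, 2, colMeans(x)); x / sqrt(sum(x^2)) }
  v <- vegan::procrustes(cs(a), cs(b), scale = FALSE)
  d_pkg <- sum((res$aligned[1, , ] - res$aligned[2, , ])^2)
  d_veg <- sum((v$X - v$Yrot)^2)
  expect_equal(d_pkg, d_veg, tolerance = 1e-8)
})

test_that("shape PCA separates simulated shape groups", {
  tpl <- default_wing_template(20)
  off <- 0.05 * tpl[, 2:1]
  set.seed(6)
  shapes <- array(0, c(40, 20, 2))
  grp <- rep(c("A", "B"), each = 20)
  for (i in 1:40)
    shapes[i, , ] <- tpl + (if (grp[i] == "A") off else -off) +
      matrix(rnorm(40, 0, 0.01), 20, 2)
  res <- gpa_align(shapes)
  pc <- shape_pca(res)
  sgn <- sign(pc$scores[, 1])
  expect_gte(max(mean(sgn[grp == "A"] == 1), mean(sgn[grp == "A"] == -1)),
             0.95)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  ms <- group_mean_shapes(res, grp)
  expect_named(ms, c("A", "B"))
})

test_that("one-way ANOVA with LSD reproduces hand computations", {
  a <- anova_lsd(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 13.5)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  expect_equal(a$ms_within, 1)
  # two identical groups: F ~ 0, shared letter
  b <- anova_lsd(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(b$F, 0)
  expect_equal(unname(b$letters["g1"]), unname(b$letters["g2"]))
  # a far-separated group receives its own letter
  set.seed(2)
  v <- c(rnorm(5, 0), rnorm(5, 0.2), rnorm(5, 30))
  cc <- anova_lsd(v, rep(c("lo", "mid", "hi"), each = 5))
  expect_false(grepl(cc$letters["hi"], paste0(cc$letters["lo"],
                                              cc$letters["mid"])))
  expect_error(suppressWarnings(anova_lsd(c(1, 1, 2, 2),
                                          c("a", "a", "b", "b"))),
               "zero within-group variance")
})

test_that("stepwise regression recovers a pure latitude effect exactly", {
  set.seed(11)
  d <- data.frame(latitude = seq(20, 49), longitude = rnorm(30),
                  altitude = rnorm(30))
  d$cs <- 2 + 0.5 * d$latitude
  st <- suppressWarnings(stepwise_cs_regression(d))
  expect_equal(st$terms, "latitude")
  expect_equal(unname(st$coefficients["latitude"]), 0.5, tolerance = 1e-10)
  expect_gt(unname(st$coefficients["latitude"]), 0)
})

test_that("stepwise regression never admits a duplicated covariate twice", {
  set.seed(12)
  d <- data.frame(latitude = seq(20, 49), longitude = rnorm(30))
  d$altitude <- d$latitude  # perfect collinearity
  d$cs <- 1 + 0.3 * d$latitude + rnorm(30, 0, 0.1)
  st <- suppressWarnings(stepwise_cs_regression(d))
  expect_length(intersect(c("latitude", "altitude"), st$terms), 1)
  expect_error(stepwise_cs_regression(data.frame(cs = 1:3, latitude = 1:3,
                                                 longitude = 1:3,
                                                 altitude = 1:3)),
               ">= 5")
})
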