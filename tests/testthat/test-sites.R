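test_that("classification matches an independent percentile oracle", {
  met <- fake_metrics(rdf = 1:8, wbr = seq(0.8, 0.1, by = -0.1))
  out <- classify_sites(met)
  q3 <- unname(quantile(met$RDF_Hz, 0.75, type = 7))
  q1 <- unname(quantile(met$WBR_per_s, 0.25, type = 7))
  oracle <- met$RDF_Hz >= q3 & met$WBR_per_s <= q1
  expect_identical(out$flag_upRDF_downWBR, oracle)
  expect_true(any(out$flag_upRDF_downWBR))

  set.seed(14)
  for (i in 1:10) {
    met <- fake_metrics(rdf = runif(12, 3, 8), wbr = runif(12, 0, 0.6))
    out <- classify_sites(met)
    q3 <- unname(quantile(met$RDF_Hz, 0.75, type = 7))
    q1 <- unname(quantile(met$WBR_per_s, 0.25, type = 7))
    expect_identical(out$flag_upRDF_downWBR,
                     met$RDF_Hz >= q3 & met$WBR_per_s <= q1)
  }
})

test_that("classification is invariant to site ordering", {
  set.seed(3)
  met <- fake_metrics(rdf = runif(10, 3, 8), wbr = runif(10, 0, 0.6))
  out <- classify_sites(met)
  perm <- sample(10)
  out_p <- classify_sites(met[perm, ])
  expect_identical(out_p$flag_upRDF_downWBR, out$flag_upRDF_downWBR[perm])
})

test_that("degenerate and undersized patients are handled as specified", {
  same <- fake_metrics(rdf = rep(5, 6), wbr = rep(0.2, 6))
  expect_warning(out <- classify_sites(same), "all sites flagged")
  expect_true(all(out$flag_upRDF_downWBR))

  small <- fake_metrics(rdf = c(4, 5, 6), wbr = c(0.1, 0.2, 0.3))
  expect_warning(out <- classify_sites(small), "< 4")
  expect_false(any(out$flag_upRDF_downWBR))

  mixed <- fake_metrics(rdf = 1:4, wbr = 1:4,
                        patient = c("a", "a", "b", "b"))
  expect_error(classify_sites(mixed), "single patient")
})

test_that("flag fraction stays near or below a quarter on continuous data", {
  set.seed(19)
  for (i in 1:20) {
    met <- fake_metrics(rdf = runif(16, 3, 8), wbr = runif(16, 0, 0.6))
    out <- classify_sites(met)
    expect_lte(mean(out$flag_upRDF_downWBR), 0.25)
  }
})

test_that("colorize bins linearly from blue (0) to red (63)", {
  expect_identical(colorize(c(0, 1)), c(0L, 63L))
  expect_identical(colorize(c(0, 0.5, 1)), c(0L, 32L, 63L))
  expect_warning(idx <- colorize(rep(2.5, 5)), "degenerate")
  expect_identical(idx, rep(0L, 5))
  # monotone in the metric value
  set.seed(2)
  v <- sort(runif(50, 2, 9))
  expect_true(all(diff(colorize(v)) >= 0))
  expect_length(wb_colormap(), 64L)
})

test_that("geometry maps carry one colored point per site", {
  set.seed(40)
  met <- fake_metrics(rdf = runif(24, 3, 8), wbr = runif(24, 0, 0.6))
  met$x <- rnorm(24); met$y <- rnorm(24); met$z <- rnorm(24)
  gm_rdf <- build_map(met, "rdf")
  gm_wbr <- build_map(met, "wbr")
  expect_identical(nrow(gm_rdf), 24L)
  expect_setequal(range(gm_rdf$color_index), c(0L, 63L))
  # independent scales per metric
  expect_false(identical(gm_rdf$color_index, gm_wbr$color_index))

  expect_warning(one <- build_map(met[1, ], "rdf"), "degenerate")
  expect_identical(one$color_index, 0L)

  met$x[3] <- NA
  expect_error(build_map(met, "rdf"), met$site_id[3])
})

test_that("region summaries group by anatomical label", {
  met <- fake_metrics(rdf = c(5, 6, 7, 4), wbr = c(0.1, 0.2, 0.3, 0.4))
  met$anatomical_label <- c("LSPV", "LSPV", "roof", "roof")
  met$flag_upRDF_downWBR <- c(TRUE, FALSE, FALSE, FALSE)
  out <- region_summary(met)
  expect_identical(sort(out$anatomical_label), c("LSPV", "roof"))
  expect_equal(out$mean_RDF_Hz[out$anatomical_label == "LSPV"], 5.5)
  expect_equal(out$n_flagged[out$anatomical_label == "LSPV"], 1)
})

test_that("geometry files round-trip points and indices", {
  met <- fake_metrics(rdf = c(4, 6, 8), wbr = c(0.1, 0.2, 0.3))
  met$x <- 1:3; met$y <- 4:6; met$z <- 7:9
  gm <- build_map(met, "rdf")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_geometry_csv(gm, csv)
  back <- read.csv(csv)
  expect_equal(back$value, gm$value)
  expect_equal(back$color_index, gm$color_index)
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_geometry_vtk(gm, vtk)
  lines <- readLines(vtk)
  expect_identical(lines[4], "DATASET POLYDATA")
  expect_identical(sum(lines == "LOOKUP_TABLE default"), 2L)
})
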