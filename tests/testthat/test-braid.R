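fx <- four_node_example()

test_that("the worked-example braid diagram reproduces its two known staging orderings", {
  bd <- braid_diagram(fx$laplacian, fx$partition,
    ln_beta = fx$params$ln_beta,
    thresholds = c(0.01, 0.05, 0.40, 0.80)
  )
  strings <- vapply(bd$patterns, function(p) p$string, character(1))
  expect_equal(strings[2], pat("I", "III", "II", "IV")) # T = 5%
  expect_equal(strings[3], pat("I", "III", "IV", "II")) # T = 40%

  df <- tidy(bd)
  expect_named(df, c("threshold", "region", "rank", "time", "pattern"))
  expect_equal(nrow(df), 4 * 4)
})

test_that("a single-threshold diagram reduces to one staging call", {
  bd <- braid_diagram(fx$laplacian, fx$partition,
    ln_beta = fx$params$ln_beta, thresholds = 0.05
  )
  expect_length(bd$patterns, 1)
  direct <- staging_order(bd$crossing_table, threshold = 0.05)
  expect_equal(bd$patterns[[1]]$string, direct$string)
})

test_that("a symmetric two-node graph always stages I before II", {
  cx <- connectome(tibble::tibble(i = 0, j = 1, n = 10, l = 10))
  part <- region_partition(list(1, 2))
  # at large beta the two nodes equalize to machine precision long before
  # crossing, so the race is a numerical tie; the index rule then puts the
  # seeded region first, which is also the exact-arithmetic answer
  for (lb in c(-3, 0, 3)) {
    bd <- braid_diagram(cx, part,
      ln_beta = lb,
      thresholds = c(0.05, 0.5, 0.9), scheme = "LW", tie_tol = 1e-6
    )
    for (p in bd$patterns) {
      expect_equal(p$string, pat("I", "II"))
    }
  }
})

test_that("diagram accepts a connectome plus scheme and validates beta input", {
  bd <- braid_diagram(fx$connectome, fx$partition,
    ln_beta = fx$params$ln_beta, thresholds = c(0.05, 0.40), scheme = "DW"
  )
  expect_equal(bd$patterns[[1]]$string, pat("I", "III", "II", "IV"))
  expect_error(braid_diagram(fx$laplacian, fx$partition),
    class = "braidr_invalid_input"
  ) # neither beta nor ln_beta
  expect_error(
    braid_diagram(fx$laplacian, fx$partition, beta = 1, ln_beta = 0),
    class = "braidr_invalid_input"
  )
})

test_that("the fixture braid surface registers exactly the two known patterns", {
  bs <- braid_surface(fx$laplacian, fx$partition,
    values = seq(-2, 6, length.out = 17),
    thresholds = seq(0.05, 0.95, by = 0.1)
  )
  expect_setequal(
    bs$registry,
    c(pat("I", "III", "II", "IV"), pat("I", "III", "IV", "II"))
  )
  expect_true(all(!is.na(bs$ids)))
  expect_equal(nrow(bs$failures), 0)

  # discovery order: the low-threshold pattern at the lowest beta comes first
  expect_equal(bs$registry[1], pat("I", "III", "II", "IV"))
})

test_that("a one-point sweep equals the braid diagram", {
  th <- seq(0.05, 0.95, by = 0.15)
  bs <- braid_surface(fx$laplacian, fx$partition,
    values = fx$params$ln_beta, thresholds = th
  )
  bd <- braid_diagram(fx$laplacian, fx$partition,
    ln_beta = fx$params$ln_beta, thresholds = th
  )
  expect_equal(
    bs$registry[bs$ids[1, ]],
    vapply(bd$patterns, function(p) p$string, character(1))
  )
})

test_that("surfaces are deterministic and parallel equals serial", {
  run <- function(cores) {
    braid_surface(fx$laplacian, fx$partition,
      values = seq(0, 5, length.out = 9),
      thresholds = seq(0.1, 0.9, by = 0.2), cores = cores
    )
  }
  a <- run(1)
  b <- run(1)
  expect_identical(a$ids, b$ids)
  expect_identical(a$registry, b$registry)
  p <- run(2)
  expect_identical(a$ids, p$ids)
  expect_identical(a$registry, p$registry)
})

test_that("surface summaries partition the grid into unit area", {
  bs <- braid_surface(fx$laplacian, fx$partition,
    values = seq(-2, 6, length.out = 9),
    thresholds = seq(0.1, 0.9, by = 0.2)
  )
  sm <- surface_summary(bs)
  expect_equal(sum(sm$area), 1)
  expect_equal(sum(sm$cells), length(bs$values) * length(bs$thresholds))

  # hand-built 2 x 2 grid splits areas evenly
  hand <- structure(
    list(
      param = "ln_beta", values = c(0, 1), thresholds = c(0.3, 0.6),
      ids = matrix(c(1L, 1L, 2L, 2L), 2, 2), registry = c("A", "B"),
      failures = tibble::tibble(value = numeric(0), message = character(0)),
      marker = "seed", delta = 1, beta = NULL
    ),
    class = "braid_surface"
  )
  expect_equal(surface_summary(hand)$area, c(0.5, 0.5))
  # single-pattern surface has area 1
  hand$ids[] <- 1L
  hand$registry <- "A"
  expect_equal(surface_summary(hand)$area, 1)
})

test_that("surface export and reimport round-trip exactly", {
  bs <- braid_surface(fx$laplacian, fx$partition,
    values = seq(0, 5, length.out = 7),
    thresholds = seq(0.1, 0.9, by = 0.2)
  )
  dir <- withr::local_tempdir()
  out <- file.path(dir, "surface_out")
  write_braid_surface(bs, out)
  back <- read_braid_surface(out)
  expect_equal(back$ids, bs$ids)
  expect_identical(back$registry, bs$registry)
  expect_equal(back$values, bs$values)
  expect_equal(back$thresholds, bs$thresholds)

  # registry JSON lists patterns in discovery order
  reg <- jsonlite::read_json(file.path(out, "registry.json"), simplifyVector = TRUE)
  expect_identical(as.character(reg$registry), bs$registry)

  # bitwise-equal export on a repeat run
  out2 <- file.path(dir, "surface_out2")
  write_braid_surface(bs, out2)
  expect_identical(
    readLines(file.path(out, "surface.tsv")),
    readLines(file.path(out2, "surface.tsv"))
  )
})

test_that("grid refinement does not invent new registry entries", {
  coarse <- braid_surface(fx$laplacian, fx$partition,
    values = seq(-1, 5, length.out = 7),
    thresholds = seq(0.1, 0.9, by = 0.2)
  )
  fine <- braid_surface(fx$laplacian, fx$partition,
    values = seq(-1, 5, length.out = 13),
    thresholds = seq(0.1, 0.9, by = 0.1)
  )
  expect_setequal(fine$registry, coarse$registry)
})

test_that("delta sweeps stage the tangle marker", {
  bs <- braid_surface(fx$laplacian, fx$partition,
    values = c(0.5, 1, 2), sweep = "delta", beta = fx$params$beta,
    thresholds = seq(0.1, 0.9, by = 0.2)
  )
  expect_equal(bs$marker, "nft")
  expect_true(all(!is.na(bs$ids)))
  expect_error(
    braid_surface(fx$laplacian, fx$partition,
      values = c(0.5, 1), sweep = "delta"
    ),
    class = "braidr_invalid_input"
  ) # missing fixed beta
})

test_that("autoplot produces ggplot objects for every result type", {
  bd <- braid_diagram(fx$laplacian, fx$partition,
    ln_beta = fx$params$ln_beta, thresholds = c(0.05, 0.40)
  )
  bs <- braid_surface(fx$laplacian, fx$partition,
    values = c(0, 2), thresholds = c(0.1, 0.5)
  )
  expect_s3_class(autoplot(bd), "ggplot")
  expect_s3_class(autoplot(bs), "ggplot")
  expect_s3_class(autoplot(bd$series), "ggplot")
  expect_s3_class(glance(bs), "tbl_df")
  expect_equal(glance(bs)$n_patterns, length(bs$registry))
})
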