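test_that("GC-density relation and label shift are the documented lines", {
  expect_equal(unlabeled_density(0.5), 1.709)
  expect_equal(unlabeled_density(0), 1.660)
  expect_equal(unlabeled_density(1), 1.758)
  expect_equal(labeled_density(0.5, 0), unlabeled_density(0.5))
  expect_equal(labeled_density(0.5, 1, 0.036), 1.745)
  expect_equal(labeled_density(0.3, 0.5),
               (labeled_density(0.3, 0) + labeled_density(0.3, 1)) / 2)
})

test_that("synthetic communities carry exact, unique T-RF ground truth", {
  cfg <- sim_config(seed = 17)
  com <- sim_community(cfg)
  expect_equal(sum(com$abundance), 1)
  expect_false(anyDuplicated(com$trf_length) > 0)
  got <- vapply(com$seq_16S, predict_trf_length, integer(1),
                USE.NAMES = FALSE)
  expect_equal(got, com$trf_length)
  # no disqualifying homopolymers anywhere in the templates
  expect_false(any(grepl("(.)\\1{5,}", com$seq_16S, perl = TRUE)))
  # label schedule is non-decreasing by construction
  expect_error(sim_config(label_schedule = c("0" = 0.5, "64" = 0.1)))
})

test_that("noiseless gradients match the analytic Gaussian integrals", {
  cfg <- sim_config(seed = 1, peak_noise_cv = 0, detection_floor = 0)
  com <- sim_community(cfg)
  g <- simulate_gradient(com, cfg, 0, "unlabeled")
  iv <- sipshift:::fraction_intervals(cfg)
  for (t in c(1, 6, 12)) {
    rho <- unlabeled_density(com$gc_fraction[t])
    want <- com$abundance[t] *
      (pnorm(iv$upper, rho, cfg$band_sigma) -
       pnorm(iv$lower, rho, cfg$band_sigma)) * cfg$area_scale
    got <- vapply(g$profiles, function(p) {
      i <- match(com$trf_length[t], p$length)
      if (is.na(i)) 0 else p$area[i]
    }, numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("banding first moments recover the taxon densities", {
  cfg <- sim_config(seed = 2)
  com <- sim_community(cfg)
  iv <- sipshift:::fraction_intervals(cfg)
  mid <- (iv$lower + iv$upper) / 2
  mu <- simulate_gradient(com, cfg, 64, "unlabeled")$mass
  ml <- simulate_gradient(com, cfg, 64, "labeled")$mass
  for (t in seq_len(nrow(com))) {
    wm <- sum(mid * mu[, t]) / sum(mu[, t])
    expect_equal(wm, unlabeled_density(com$gc_fraction[t]), tolerance = 2e-3)
  }
  # fully labeled taxa shift by at least 80% of the full-label delta
  for (t in which(com$labeled)) {
    shift <- sum(mid * ml[, t]) / sum(ml[, t]) -
             sum(mid * mu[, t]) / sum(mu[, t])
    expect_gte(shift, 0.8 * 0.99 * cfg$delta_rho_full_label)
  }
})

test_that("gradient simulation is seed-deterministic and label-local", {
  cfg <- sim_config(seed = 23)
  com <- sim_community(cfg)
  a <- simulate_gradient(com, cfg, 64, "labeled")
  b <- simulate_gradient(com, cfg, 64, "labeled")
  expect_identical(a, b)
  # treatments differ only for taxa with a nonzero label schedule
  u <- simulate_gradient(com, cfg, 64, "unlabeled")
  unl <- com$trf_length[!com$labeled]
  for (i in seq_along(a$profiles)) {
    pa <- as.data.frame(a$profiles[[i]]); pu <- as.data.frame(u$profiles[[i]])
    expect_equal(pa[pa$length %in% unl, ], pu[pu$length %in% unl, ],
                 ignore_attr = TRUE)
  }
})

test_that("refractometer readings in emitted fractions invert to densities", {
  cfg <- sim_config(seed = 3)
  g <- simulate_gradient(sim_community(cfg), cfg, 0, "unlabeled")
  fr <- g$fractions
  expect_equal(fr$buoyant_density,
               density_from_refractive_index(fr$refractive_index))
  expect_equal(fr$index, 1:22)
  expect_true(all(diff(fr$buoyant_density) < 0))  # bottom-up: densest first
})

test_that("error-free reads match their source templates exactly", {
  cfg <- sim_config(seed = 4, error_rate = 0, reads_per_fraction = 100)
  com <- sim_community(cfg)
  g <- simulate_gradient(com, cfg, 64, "labeled")
  h <- select_heavy_fraction(g$fractions)
  reads <- simulate_reads(com, g$mass[h$index, ], cfg, 64, "labeled", h$index)
  for (i in seq_len(NROW(reads))) {
    tmpl <- substring(com$seq_16S[com$id == reads$source_taxon[i]], 201, 350)
    expect_identical(reads$sequence[i], tmpl)
  }
})

test_that("read counts follow the multinomial weights", {
  cfg <- sim_config(seed = 5, reads_per_fraction = 10000)
  com <- sim_community(cfg)
  g <- simulate_gradient(com, cfg, 64, "labeled")
  h <- select_heavy_fraction(g$fractions)
  w <- g$mass[h$index, ]; p <- w / sum(w)
  reads <- simulate_reads(com, w, cfg, 64, "labeled", h$index)
  counts <- table(factor(reads$source_taxon, levels = com$id))
  n <- NROW(reads)
  for (t in seq_len(nrow(com))) {
    sd3 <- 3 * sqrt(n * p[t] * (1 - p[t]))
    expect_lte(abs(counts[t] - n * p[t]), max(sd3, 1))
  }
  # symmetric two-taxon fraction splits evenly within sampling error
  w2 <- setNames(c(0.5, 0.5, rep(0, 10)), com$id)
  r2 <- simulate_reads(com, w2, cfg, 64, "labeled", 1)
  frac <- mean(r2$source_taxon == "taxon_01")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000) + 1e-3)
})

test_that("a written experiment reloads through the analysis readers", {
  cfg <- sim_config(seed = 6, reads_per_fraction = 50)
  exp <- simulate_experiment(cfg, reads_for = 64)
  dir <- withr::local_tempdir()
  paths <- write_experiment(exp, dir)
  fr <- read_fraction_table(paths[["fractions"]])
  expect_equal(NROW(fr), 22 * 2 * 4)  # 22 fractions, 2 treatments, 4 days
  pk <- read_peak_table(paths[["peaks"]])
  expect_true(all(pk$peak_area >= cfg$detection_floor))
  reads <- read_fastq(paths[["reads_day64"]])
  expect_equal(NROW(reads), 2 * 50)
  gas <- read_gas_series(paths[["gas"]])
  expect_equal(balance_from_series(gas)$mineralization_pct, 72,
               tolerance = 0.02)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$labeled_taxa, exp$community$id[exp$community$labeled])
})
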