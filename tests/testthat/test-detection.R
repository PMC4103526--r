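# profiles for one simulated treatment/day, cleaned the standard way
sim_profiles <- function(com, cfg, day, treatment) {
  g <- simulate_gradient(com, cfg, day, treatment)
  bin_trf_lengths(lapply(g$profiles, function(p)
    normalize_profile(filter_peaks(p))), 1)
}

test_that("top T-RF screening keeps the k largest with shorter-first ties", {
  p <- make_profile(101:112, c(12:3, 2, 2))
  expect_equal(sort(top_trfs(p, 10)), 101:110)
  expect_equal(top_trfs(make_profile(c(95, 284, 300), c(1, 2, 3)), 10),
               c(300, 284, 95))
  # tie at the cut rank: the shorter fragment is retained
  p <- make_profile(c(10 + 1:9, 200, 150), c(100:92, 5, 5))
  expect_true(150 %in% top_trfs(p, 10))
  expect_false(200 %in% top_trfs(p, 10))
  expect_error(top_trfs(trf_profile(data.frame(length = 1, area = 1))),
               "normalized")
})

test_that("enrichment score is a windowed mean difference, antisymmetric", {
  cv <- function(d, r) data.frame(density = d, rel_abundance = r)
  d <- seq(1.70, 1.76, by = 0.01)
  a <- cv(d, rep(0.4, 7)); b <- cv(d, rep(0.1, 7))
  expect_equal(enrichment_score(a, a), 0)
  expect_equal(enrichment_score(a, b), 0.3)
  # antisymmetry on random curves
  set.seed(11)
  for (i in 1:10) {
    x <- cv(d, runif(7)); y <- cv(d, runif(7))
    expect_equal(enrichment_score(x, y), -enrichment_score(y, x))
  }
  expect_error(enrichment_score(cv(1.70, 0.5), cv(1.70, 0.5)), "window")
})

test_that("labeled T-RFs are recovered exactly from a synthetic gradient", {
  cfg <- sim_config(seed = 5)
  com <- sim_community(cfg)
  rep64 <- detect_labeled_trfs(sim_profiles(com, cfg, 64, "labeled"),
                               sim_profiles(com, cfg, 64, "unlabeled"))
  truth <- as.character(sort(com$trf_length[com$labeled]))
  expect_setequal(rep64$phylotype_id[rep64$is_labeled], truth)
  # flagged set is a subset of the top-10 screen
  hp <- sim_profiles(com, cfg, 64, "labeled")
  heavy <- hp[[sipshift:::select_heavy_index(
    sipshift:::profile_densities(hp))]]
  expect_true(all(rep64$phylotype_id %in% as.character(top_trfs(heavy, 10))))
})

test_that("identical treatments yield no labeled calls", {
  cfg <- sim_config(seed = 6)
  com <- sim_community(cfg)
  pu <- sim_profiles(com, cfg, 64, "unlabeled")
  r <- detect_labeled_trfs(pu, pu)
  expect_false(any(r$is_labeled))
  expect_true(all(abs(r$enrichment_score) < 1e-12))
})

test_that("a fully labeled community enriches every screened T-RF", {
  # with all 12 taxa labeled, relative abundances in the heavy window are
  # shared compositionally (~1/(2N) each), so the per-taxon additive score
  # stays below the 2-of-12 calling threshold; the recoverable invariant is
  # that every screened fragment is strictly enriched over the control
  cfg <- sim_config(seed = 8, labeled_taxa = sprintf("taxon_%02d", 1:12))
  com <- sim_community(cfg)
  r <- detect_labeled_trfs(sim_profiles(com, cfg, 64, "labeled"),
                           sim_profiles(com, cfg, 64, "unlabeled"))
  expect_true(all(r$enrichment_score > 0))
  expect_gt(min(r$enrichment_score), 0.02)
})

test_that("enrichment score grows monotonically with atom fraction 13C", {
  scores <- vapply(c(0, 0.25, 0.5, 0.75, 0.99), function(af) {
    cfg <- sim_config(seed = 9, label_schedule = c("0" = 0, "23" = 0,
                                                   "38" = 0, "64" = af))
    com <- sim_community(cfg)
    r <- detect_labeled_trfs(sim_profiles(com, cfg, 64, "labeled"),
                             sim_profiles(com, cfg, 64, "unlabeled"),
                             candidates = com$trf_length[com$labeled][1])
    r$enrichment_score[1]
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("labeled OTU detection applies candidate and call thresholds", {
  counts <- matrix(c(300L, 650L, 41L, 9L), ncol = 1,
                   dimnames = list(sprintf("OTU_%04d", 1:4), "s"))
  seqs <- setNames(vapply(1:4, function(i) {
    set.seed(i); paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  }, character(1)), rownames(counts))
  tab <- sip_otu_table(counts, seqs)
  # identical tables: nothing flagged
  r <- detect_labeled_otus(tab, tab)
  expect_false(any(r$is_labeled))
  # OTU_0004 sits at 0.009 < the 1% candidate screen: excluded even though
  # it is absent from the unlabeled table
  other <- sip_otu_table(counts[1:3, , drop = FALSE], seqs[1:3])
  r <- detect_labeled_otus(tab, other)
  expect_false("OTU_0004" %in% r$phylotype_id)
  expect_error(detect_labeled_otus(tab,
    sip_otu_table(matrix(integer(0), 0, 1,
                         dimnames = list(NULL, "s")), character(0))))
})

test_that("four labeled OTUs are recovered from heavy-fraction reads", {
  cfg <- otu_experiment_config(seed = 2)
  com <- sim_community(cfg)
  tabs <- lapply(c("labeled", "unlabeled"), function(tr) {
    g <- simulate_gradient(com, cfg, 64, tr)
    h <- select_heavy_fraction(g$fractions)
    cluster_otus(qc_filter(simulate_reads(
      com, g$mass[h$index, ], cfg, 64, tr, h$index)))
  })
  r <- detect_labeled_otus(tabs[[1]], tabs[[2]])
  expect_equal(sum(r$is_labeled), 4)
  # flagged representatives trace back to the configured assimilators
  hits <- vapply(r$phylotype_id[r$is_labeled], function(o)
    assign_taxonomy_nearest(tabs[[1]]$representative_seqs[[o]],
                            setNames(com$seq_16S, com$id))$taxonomy,
    character(1))
  expect_setequal(unname(hits), com$id[com$labeled])
})

test_that("first labeled day is the earliest flagged day per phylotype", {
  rep_at <- function(flag) structure(
    data.frame(phylotype_id = c("95", "284"),
               enrichment_score = c(0.3, 0.05),
               is_labeled = c(flag, FALSE)),
    class = c("shift_report", "data.frame"))
  out <- first_labeled_day(list("23" = rep_at(FALSE), "38" = rep_at(TRUE),
                                "64" = rep_at(TRUE)))
  expect_equal(out$first_labeled_day[out$phylotype_id == "95"], 38)
  expect_true(is.na(out$first_labeled_day[out$phylotype_id == "284"]))
  # order of the day list does not matter
  out2 <- first_labeled_day(list("64" = rep_at(TRUE), "23" = rep_at(FALSE),
                                 "38" = rep_at(TRUE)))
  expect_equal(out2[order(out2$phylotype_id), ],
               out[order(out$phylotype_id), ], ignore_attr = TRUE)
})

test_that("label onset between days 23 and 38 is detected on day 38", {
  cfg <- sim_config(seed = 12)
  com <- sim_community(cfg)
  reports <- lapply(c(23, 38, 64), function(d)
    detect_labeled_trfs(sim_profiles(com, cfg, d, "labeled"),
                        sim_profiles(com, cfg, d, "unlabeled")))
  names(reports) <- c(23, 38, 64)
  out <- first_labeled_day(reports)
  truth <- as.character(com$trf_length[com$labeled])
  expect_equal(out$first_labeled_day[out$phylotype_id %in% truth], c(38, 38))
})
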