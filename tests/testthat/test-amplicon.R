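mk_read <- function(seq, q = 35L, id = "r1", sample = "s1") {
  data.frame(id = id, sequence = seq,
             quality = strrep(intToUtf8(q + 33L), nchar(seq)),
             sample = sample, stringsAsFactors = FALSE)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("read QC applies length, quality and homopolymer rules", {
  set.seed(1)
  base <- paste(rep(c("A", "C", "G", "T"), 40), collapse = "")  # 160 bp, no runs
  r99 <- mk_read(substr(base, 1, 99))
  r100 <- mk_read(substr(base, 1, 100))
  expect_equal(NROW(qc_filter(r99)), 0)
  expect_equal(NROW(qc_filter(r100)), 1)
  r391 <- mk_read(paste(rep(c("A", "C"), 196), collapse = ""))  # 392 bp
  expect_equal(NROW(qc_filter(r391)), 0)
  # homopolymer: a 6-mer kills the read, a 5-mer does not
  hp6 <- mk_read(paste0(substr(base, 1, 100), "AAAAAA", "CGT"))
  hp5 <- mk_read(paste0(substr(base, 1, 100), "AAAAA", "CGT"))
  expect_equal(NROW(qc_filter(hp6)), 0)
  expect_equal(NROW(qc_filter(hp5)), 1)
  # mean quality boundary: exactly 25 survives, 24 does not
  expect_equal(NROW(qc_filter(mk_read(substr(base, 1, 120), q = 25L))), 1)
  expect_equal(NROW(qc_filter(mk_read(substr(base, 1, 120), q = 24L))), 0)
  expect_equal(NROW(qc_filter(mk_read("ACGT")[0, ])), 0)
  # idempotent
  mixed <- rbind(r100, hp6, r99)
  expect_equal(qc_filter(qc_filter(mixed)), qc_filter(mixed))
})

test_that("greedy clustering merges near-identical and splits distant reads", {
  set.seed(42)
  a <- rand_seq(250)
  a_mut <- a
  substr(a_mut, 125, 125) <- setdiff(c("A", "C", "G", "T"),
                                     substr(a, 125, 125))[1]
  reads <- rbind(
    do.call(rbind, replicate(10, mk_read(a), simplify = FALSE)),
    do.call(rbind, replicate(5, mk_read(a_mut), simplify = FALSE)))
  tab <- cluster_otus(reads)
  expect_equal(length(tab$otu_ids), 1)          # 249/250 = 99.6% identity
  expect_equal(unname(tab$representative_seqs[1]), a)
  expect_equal(sum(tab$counts), 15)
  # ~90% identity splits into two OTUs
  b <- a
  pos <- sample(250, 25)
  for (p in pos) substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                                            substr(a, p, p))[1]
  tab2 <- cluster_otus(rbind(mk_read(a), mk_read(b)))
  expect_equal(length(tab2$otu_ids), 2)
  # single read
  tab3 <- cluster_otus(mk_read(a))
  expect_equal(unname(tab3$counts[1, 1]), 1)
})

test_that("clustering at identity 1 equals hash-based dereplication", {
  set.seed(7)
  pool <- replicate(4, rand_seq(120))
  reads <- do.call(rbind, lapply(sample(pool, 60, TRUE), mk_read))
  tab <- cluster_otus(reads, identity = 1.0)
  want <- oracle_dereplicate(reads)
  expect_equal(length(tab$otu_ids), length(want))
  expect_equal(sort(as.integer(tab$counts[, 1])), sort(unname(want)))
  expect_setequal(unname(tab$representative_seqs), names(want))
})

test_that("assigned reads are conserved and abundances sum to one", {
  cfg <- sim_config(seed = 3)
  com <- sim_community(cfg)
  g <- simulate_gradient(com, cfg, 64, "labeled")
  h <- select_heavy_fraction(g$fractions)
  reads <- qc_filter(simulate_reads(com, g$mass[h$index, ], cfg, 64,
                                    "labeled", h$index))
  tab <- cluster_otus(reads)
  expect_equal(sum(tab$counts), NROW(reads))
  rel <- relative_abundance(tab, colnames(tab$counts)[1])
  expect_equal(sum(rel), 1, tolerance = 1e-9)
  expect_equal(unname(relative_abundance(
    sip_otu_table(matrix(c(30L, 70L), 2, 1,
                         dimnames = list(c("OTU_0001", "OTU_0002"), "s")),
                  c(OTU_0001 = "ACGT", OTU_0002 = "TGCA")), "s")),
    c(0.3, 0.7))
})

test_that("well-separated taxa round-trip into exactly k OTUs", {
  cfg <- sim_config(seed = 4)
  com <- sim_community(cfg)
  # error-free reads from 5 taxa, 12 each
  reads <- do.call(rbind, lapply(1:5, function(t) {
    do.call(rbind, lapply(1:12, function(i)
      mk_read(substring(com$seq_16S[t], 201, 350),
              id = sprintf("t%d_r%d", t, i))))
  }))
  tab <- cluster_otus(reads)
  expect_equal(length(tab$otu_ids), 5)
  expect_true(all(tab$counts == 12))
})

test_that("nearest-reference taxonomy labels simulated reads correctly", {
  cfg <- sim_config(seed = 10)
  com <- sim_community(cfg)
  refs <- setNames(com$seq_16S, com$taxonomy)
  hit <- assign_taxonomy_nearest(substring(com$seq_16S[4], 201, 350), refs)
  expect_equal(hit$taxonomy, com$taxonomy[4])
  expect_equal(hit$identity, 1.0)
  # below the identity floor -> unclassified
  set.seed(5)
  hit2 <- assign_taxonomy_nearest(rand_seq(150), refs)
  expect_equal(hit2$taxonomy, "unclassified")
  expect_error(assign_taxonomy_nearest("ACGT", character(0)), "empty")
})

test_that("FASTQ round-trips and barcodes split exactly", {
  reads <- rbind(mk_read(rand_seq(120), id = "a"),
                 mk_read(rand_seq(130), id = "b"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path, sample = "s1")
  expect_equal(back[, c("id", "sequence", "quality")],
               reads[, c("id", "sequence", "quality")])
  tagged <- reads
  tagged$sequence <- paste0(c("ACGTACGT", "TTTTCCCC"), tagged$sequence)
  tagged$quality <- paste0(strrep("I", 8), tagged$quality)
  out <- split_barcodes(tagged, c(v1 = "ACGTACGT", v2 = "TTTTCCCC"))
  expect_equal(out$sample, c("v1", "v2"))
  expect_equal(out$sequence, reads$sequence)
})
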