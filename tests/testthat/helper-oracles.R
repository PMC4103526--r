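# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations, kept separate from the package code
# paths they check.

# exhaustive position-scan T-RF oracle: try the primer at every position
# with a hand-coded IUPAC table, then scan every downstream position for
# the first recognition site
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_trf <- function(seq, primer = "AGAGTTTGATCMTGGCTCAG",
                       site = "GCGC", offset = 3L) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(primer, "")[[1]]
  n <- length(s); np <- length(p); ns <- nchar(site)
  site_ch <- strsplit(site, "")[[1]]
  for (pos in seq_len(n - np + 1L)) {
    ok <- all(vapply(seq_len(np), function(i)
      s[pos + i - 1L] %in% IUPAC_SETS[[p[i]]], logical(1)))
    if (!ok) next
    if (pos + np > n - ns + 1L) return(NA_integer_)
    for (cut in (pos + np):(n - ns + 1L)) {
      if (all(s[cut:(cut + ns - 1L)] == site_ch))
        return(as.integer(cut + offset - pos))
    }
    return(NA_integer_)
  }
  NA_integer_
}

# random amplicon with the concrete Ba27f site planted at position 1 and a
# recognition site planted at a random position (or none)
random_amplicon <- function(len = 300, plant_site = TRUE) {
  body <- sample(c("A", "C", "G", "T"), len - 20L, replace = TRUE)
  s <- c(strsplit("AGAGTTTGATCCTGGCTCAG", "")[[1]], body)
  if (plant_site) {
    at <- sample(21:(len - 4L), 1)
    s[at:(at + 3L)] <- c("G", "C", "G", "C")
  }
  paste(s, collapse = "")
}

# single-linkage binning oracle via hclust on 1-D lengths
oracle_bin_map <- function(lengths, tolerance) {
  u <- sort(unique(lengths))
  if (length(u) == 1L) return(stats::setNames(u, u))
  cl <- stats::cutree(stats::hclust(stats::dist(u), method = "single"),
                      h = tolerance)
  canon <- as.integer(round(tapply(u, cl, mean)))
  stats::setNames(canon[cl], u)
}

# hash-based exact dereplication oracle for clustering at identity 1
oracle_dereplicate <- function(reads) {
  sp <- split(seq_len(nrow(reads)), reads$sequence)
  counts <- vapply(sp, length, integer(1))
  counts[order(-counts, names(counts))]
}

# small helper: build a normalized profile from peak vectors
make_profile <- function(lengths, areas, density = NA_real_, index = NA,
                         treatment = "labeled", day = 64) {
  normalize_profile(trf_profile(
    data.frame(length = lengths, area = areas),
    fraction = list(treatment = treatment, day = day, index = index,
                    buoyant_density = density)))
}
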