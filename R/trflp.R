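#' Primer specification
#'
#' A PCR primer given as an IUPAC nucleotide string (degenerate codes
#' allowed). [ba27f()] returns the standard bacterial forward primer used
#' for fluorescently labeled T-RFLP amplicons.
#'
#' @param name Primer name.
#' @param sequence IUPAC nucleotide string.
#' @return An object of class `primer_spec`.
#' @export
primer_spec <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("primer sequence must be non-empty")
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop("primer contains non-IUPAC characters")
  structure(list(name = name, sequence = sequence), class = "primer_spec")
}

#' @rdname primer_spec
#' @export
ba27f <- function() primer_spec("Ba27f", "AGAGTTTGATCMTGGCTCAG")

#' Restriction enzyme specification
#'
#' `cut_offset` is the number of bases from the start of the recognition
#' site to the cut on the labeled (forward) strand: HhaI recognizes GCGC and
#' cuts GCG^C, so its offset is 3.
#'
#' @param name Enzyme name.
#' @param recognition_site Concrete nucleotide recognition sequence.
#' @param cut_offset Bases from site start to the cut, in
#'   `[0, nchar(recognition_site)]`.
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, recognition_site, cut_offset) {
  recognition_site <- toupper(recognition_site)
  if (grepl("[^ACGT]", recognition_site))
    stop("recognition site must be a concrete ACGT string")
  if (cut_offset < 0 || cut_offset > nchar(recognition_site))
    stop("cut_offset must lie within the recognition site")
  structure(list(name = name, recognition_site = recognition_site,
                 cut_offset = as.integer(cut_offset)), class = "enzyme_spec")
}

#' @rdname enzyme_spec
#' @export
hhai <- function() enzyme_spec("HhaI", "GCGC", 3L)

#' Predict the terminal restriction fragment length of a sequence
#'
#' Locates the forward primer on the sense strand (IUPAC degeneracies in the
#' primer match concrete template bases), then the first enzyme recognition
#' site downstream of the primer, and returns the fragment
#' length from the primer's 5' end through the cut position, inclusive of
#' the primer bases. Only the forward strand is considered: in T-RFLP only
#' the 5'-fluorophore-labeled strand is detected, so fragments released from
#' the reverse strand are invisible.
#'
#' @param seq Sense-strand nucleotide string containing the priming site.
#' @param primer A [primer_spec()] (default Ba27f).
#' @param enzyme An [enzyme_spec()] (default HhaI).
#' @param max_mismatch Mismatches allowed in the primer match (default 0).
#' @return Integer fragment length in bases, or `NA_integer_` if the primer
#'   does not match or no recognition site lies downstream.
#' @examples
#' predict_trf_length(paste0("AGAGTTTGATCCTGGCTCAG", "GCGC",
#'                           strrep("A", 40)))  # 23
#' @export
predict_trf_length <- function(seq, primer = ba27f(), enzyme = hhai(),
                               max_mismatch = 0L) {
  seq <- toupper(seq)
  if (!nzchar(seq) || grepl("[^ACGTRYSWKMBDHVN]", seq))
    stop("sequence contains non-IUPAC characters")
  subject <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(primer$sequence, subject,
                                   max.mismatch = max_mismatch,
                                   fixed = "subject")
  if (length(hits) == 0L) return(NA_integer_)
  p <- min(BiocGenerics::start(hits))
  sites <- BiocGenerics::start(
    Biostrings::matchPattern(enzyme$recognition_site, subject, fixed = TRUE))
  # first site fully downstream of the primer (a site straddling the primer
  # boundary would imply a fragment shorter than primer + cut offset)
  sites <- sites[sites >= p + nchar(primer$sequence)]
  if (length(sites) == 0L) return(NA_integer_)
  s <- min(sites)
  len <- s + enzyme$cut_offset - p
  if (len < 1L || s + nchar(enzyme$recognition_site) - 1L > nchar(seq))
    return(NA_integer_)
  as.integer(len)
}

#' Construct a T-RFLP profile
#'
#' A profile is a data frame of peaks (`length` in bases, `area` in
#' arbitrary fluorescence units, optionally `rel_abundance`) carrying the
#' identity of the gradient fraction it was measured on.
#'
#' @param peaks Data frame with columns `length` and `area`.
#' @param fraction Optional list identifying the source fraction (fields
#'   such as `treatment`, `day`, `index`, `buoyant_density`).
#' @param normalized Logical: has [normalize_profile()] been applied?
#' @return An object of class `trf_profile` (a classed data frame).
#' @export
trf_profile <- function(peaks, fraction = NULL, normalized = FALSE) {
  if (NROW(peaks) > 0L) {
    stopifnot(all(c("length", "area") %in% names(peaks)),
              all(peaks$length >= 1), all(peaks$area >= 0))
  } else {
    peaks <- data.frame(length = integer(0), area = numeric(0))
  }
  structure(as.data.frame(peaks), fraction = fraction, normalized = normalized,
            class = c("trf_profile", "data.frame"))
}

#' @export
print.trf_profile <- function(x, ...) {
  fr <- attr(x, "fraction")
  if (!is.null(fr))
    cat(sprintf("T-RF profile [%s day %s fraction %s, d = %s g/cm^3]\n",
                fr$treatment %||% "?", fr$day %||% "?", fr$index %||% "?",
                format(fr$buoyant_density %||% NA, digits = 5)))
  cat(sprintf("%d peak(s)%s\n", NROW(x),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter raw T-RFLP peaks
#'
#' Applies the standard validity filters: peaks with an area smaller than
#' `min_area` arbitrary units are eliminated (an area exactly equal to the
#' threshold survives), and only fragment lengths between `min_len` and
#' `max_len` bases (both inclusive) are retained. Order is preserved and an
#' empty result is allowed.
#'
#' @param raw Data frame with columns `length` and `area`, or a
#'   `trf_profile`.
#' @param min_area Minimum retained peak area (default 50).
#' @param min_len,max_len Inclusive fragment-length window (default 20-600).
#' @return A `trf_profile` of the retained peaks (fraction metadata kept).
#' @export
filter_peaks <- function(raw, min_area = 50, min_len = 20, max_len = 600) {
  if (NROW(raw) == 0L)
    return(trf_profile(data.frame(length = integer(0), area = numeric(0)),
                       fraction = attr(raw, "fraction")))
  if (any(raw$area < 0)) stop("peak areas must be >= 0")
  keep <- raw$area >= min_area & raw$length >= min_len & raw$length <= max_len
  trf_profile(as.data.frame(raw)[keep, , drop = FALSE],
              fraction = attr(raw, "fraction"))
}

#' Normalize a filtered profile to relative abundances
#'
#' Each peak's relative abundance is its area divided by the total area of
#' all valid peaks in the same fraction. A profile whose total area is zero
#' normalizes to an empty profile with a warning. Idempotent.
#'
#' @param profile A `trf_profile` (already filtered).
#' @return The profile with a `rel_abundance` column and the normalized
#'   flag set.
#' @export
normalize_profile <- function(profile) {
  fr <- attr(profile, "fraction")
  if (NROW(profile) == 0L)
    return(trf_profile(profile, fraction = fr, normalized = TRUE))
  total <- sum(profile$area)
  if (total <= 0) {
    warning("total peak area is zero; returning empty normalized profile")
    return(trf_profile(data.frame(length = integer(0), area = numeric(0)),
                       fraction = fr, normalized = TRUE))
  }
  out <- as.data.frame(profile)
  out$rel_abundance <- out$area / total
  trf_profile(out, fraction = fr, normalized = TRUE)
}

# Single-linkage 1-D binning: sorted unique lengths chain together while
# consecutive gaps are <= tolerance; canonical length = rounded centroid.
trf_bin_map <- function(lengths, tolerance) {
  u <- sort(unique(lengths))
  if (length(u) == 0L) return(integer(0))
  brk <- c(0L, which(diff(u) > tolerance), length(u))
  bin <- rep.int(seq_len(length(brk) - 1L),
                 diff(brk))
  canon <- as.integer(round(tapply(u, bin, mean)))
  stats::setNames(canon[bin], u)
}

#' Align T-RF lengths across profiles by binning
#'
#' Capillary sizing jitters fragment lengths by about a base between runs,
#' so profiles are aligned before comparison: all observed lengths within
#' `tolerance` bases of each other (single-linkage chaining across the
#' pooled profiles) share one canonical length, the rounded centroid of the
#' bin. Within one profile, peaks merged into a bin sum their areas (and
#' relative abundances, if present). `tolerance = 0` merges only identical
#' lengths.
#'
#' @param profiles List of `trf_profile` objects.
#' @param tolerance Non-negative binning tolerance in bases (default 1).
#' @return List of `trf_profile` objects with binned lengths.
#' @export
bin_trf_lengths <- function(profiles, tolerance = 1) {
  stopifnot(tolerance >= 0)
  all_len <- unlist(lapply(profiles, function(p) p$length), use.names = FALSE)
  map <- trf_bin_map(all_len, tolerance)
  lapply(profiles, function(p) {
    if (NROW(p) == 0L) return(p)
    canon <- unname(map[as.character(p$length)])
    has_rel <- "rel_abundance" %in% names(p)
    agg <- if (has_rel) {
      stats::aggregate(cbind(area, rel_abundance) ~ length,
                       data = data.frame(length = canon, area = p$area,
                                         rel_abundance = p$rel_abundance),
                       FUN = sum)
    } else {
      stats::aggregate(area ~ length,
                       data = data.frame(length = canon, area = p$area),
                       FUN = sum)
    }
    agg <- agg[order(agg$length), , drop = FALSE]
    rownames(agg) <- NULL
    trf_profile(agg, fraction = attr(p, "fraction"),
                normalized = isTRUE(attr(p, "normalized")))
  })
}

#' Read a raw T-RFLP peak table from TSV
#'
#' Expects columns `treatment`, `day`, `fraction_index`, `trf_length`,
#' `peak_area`, one row per detected peak.
#'
#' @param path Path to a tab-separated peak table.
#' @return Data frame of peaks.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("treatment", "day", "fraction_index", "trf_length", "peak_area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Assemble per-fraction profiles from peak and fraction tables
#'
#' Joins a raw peak table to its fraction table, then filters, normalizes
#' and (optionally) bins each fraction's profile.
#'
#' @param peaks Data frame from [read_peak_table()].
#' @param fractions A `gradient_fractions` table covering the same
#'   treatment/day/index combinations.
#' @param min_area,min_len,max_len Passed to [filter_peaks()].
#' @param bin_tolerance Passed to [bin_trf_lengths()]; `NULL` skips binning.
#' @return Named list of normalized `trf_profile`s, names
#'   `"treatment|day|index"`, ordered densest first within each group.
#' @export
build_profiles <- function(peaks, fractions, min_area = 50, min_len = 20,
                           max_len = 600, bin_tolerance = 1) {
  key <- interaction(peaks$treatment, peaks$day, peaks$fraction_index, drop = TRUE)
  groups <- split(peaks, key)
  profs <- lapply(groups, function(g) {
    i <- which(fractions$treatment == g$treatment[1] &
               fractions$day == g$day[1] & fractions$index == g$fraction_index[1])
    if (length(i) != 1L)
      stop(sprintf("no unique fraction for %s day %s index %s",
                   g$treatment[1], g$day[1], g$fraction_index[1]))
    fr <- as.list(fractions[i, c("treatment", "day", "index",
                                 "refractive_index", "buoyant_density")])
    p <- trf_profile(data.frame(length = g$trf_length, area = g$peak_area),
                     fraction = fr)
    normalize_profile(filter_peaks(p, min_area, min_len, max_len))
  })
  names(profs) <- vapply(profs, function(p) {
    fr <- attr(p, "fraction")
    paste(fr$treatment, fr$day, fr$index, sep = "|")
  }, character(1))
  if (!is.null(bin_tolerance)) profs <- bin_trf_lengths(profs, bin_tolerance)
  profs
}

# density vector of a list of profiles
profile_densities <- function(profiles) {
  vapply(profiles, function(p) attr(p, "fraction")$buoyant_density, numeric(1))
}
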