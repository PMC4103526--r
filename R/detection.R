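#' Most abundant T-RFs in a profile
#'
#' Returns the `k` fragment lengths with the largest relative abundance in
#' a normalized profile; ties at the cut rank retain the shorter fragment.
#' Profiles with fewer than `k` peaks return all of them.
#'
#' @param heavy_profile A normalized `trf_profile` (typically the heavy
#'   fraction of the labeled treatment).
#' @param k Number of fragments to return (default 10).
#' @return Integer vector of T-RF lengths, most abundant first.
#' @export
top_trfs <- function(heavy_profile, k = 10) {
  if (!isTRUE(attr(heavy_profile, "normalized")))
    stop("profile must be normalized first")
  if (NROW(heavy_profile) == 0L) return(integer(0))
  ord <- order(-heavy_profile$rel_abundance, heavy_profile$length)
  utils::head(heavy_profile$length[ord], k)
}

#' Heavy-window enrichment score for one phylotype
#'
#' Quantifies a shift toward the heavy fractions of the labeled treatment:
#' the mean relative abundance of the phylotype over the heavy density
#' window in the labeled treatment, minus the same mean in the matched
#' unlabeled fractions. Positive scores mean the phylotype is
#' over-represented in heavy labeled DNA; the score is antisymmetric under
#' swapping the treatments.
#'
#' @param curve_labeled,curve_unlabeled Data frames with columns `density`
#'   and `rel_abundance`, row-aligned by a matched-fraction pairing
#'   (see [match_fractions()]); window membership is evaluated on the
#'   labeled densities.
#' @param heavy_window Numeric length-2 density interval in g cm^-3
#'   (default `c(1.725, Inf)`: all fractions at or above 1.725).
#' @return Dimensionless score in [-1, 1].
#' @export
enrichment_score <- function(curve_labeled, curve_unlabeled,
                             heavy_window = c(1.725, Inf)) {
  stopifnot(NROW(curve_labeled) == NROW(curve_unlabeled))
  sel <- curve_labeled$density >= heavy_window[1] &
         curve_labeled$density <= heavy_window[2]
  if (!any(sel)) stop("no fractions fall inside the heavy density window")
  mean(curve_labeled$rel_abundance[sel]) - mean(curve_unlabeled$rel_abundance[sel])
}

# rel abundance of one T-RF length in each profile (0 when absent)
trf_abundance_curve <- function(profiles, trf_length) {
  data.frame(
    density = profile_densities(profiles),
    rel_abundance = vapply(profiles, function(p) {
      i <- match(trf_length, p$length)
      if (is.na(i)) 0 else p$rel_abundance[i]
    }, numeric(1)),
    row.names = NULL)
}

#' Detect 13C-labeled phylotypes from T-RFLP density profiles
#'
#' Screens the `k` most abundant T-RFs in the heavy fraction of the labeled
#' treatment (or a supplied candidate list, e.g. the day-64 candidates when
#' re-screening earlier days), builds each candidate's density-abundance
#' curve in both treatments over density-matched fractions, and flags those
#' whose [enrichment_score()] meets `threshold`.
#'
#' @param profiles_labeled,profiles_unlabeled Lists of filtered, normalized,
#'   binned `trf_profile`s for one day (see [build_profiles()]).
#' @param threshold Enrichment-score cutoff for calling a phylotype labeled
#'   (default 0.1).
#' @param k Number of top T-RFs screened (default 10).
#' @param target Heavy-fraction target density, g cm^-3 (default 1.732).
#' @param heavy_window Density window for the score (default
#'   `c(1.725, Inf)`).
#' @param candidates Optional integer vector of T-RF lengths to screen
#'   instead of the top-`k` rule.
#' @return A `shift_report` data frame: one row per screened T-RF with
#'   `phylotype_id`, `enrichment_score`, `is_labeled`; the per-phylotype
#'   density-abundance curves are kept in `attr(, "curves")`.
#' @export
detect_labeled_trfs <- function(profiles_labeled, profiles_unlabeled,
                                threshold = 0.1, k = 10, target = 1.732,
                                heavy_window = c(1.725, Inf),
                                candidates = NULL) {
  if (length(profiles_labeled) == 0L || length(profiles_unlabeled) == 0L)
    stop("need profiles from both treatments")
  dl <- profile_densities(profiles_labeled)
  heavy_profile <- profiles_labeled[[select_heavy_index(dl, target)]]
  if (NROW(heavy_profile) == 0L) stop("heavy fraction has no peaks")
  if (is.null(candidates)) candidates <- top_trfs(heavy_profile, k)
  pairing <- match_density(dl, profile_densities(profiles_unlabeled))
  matched_unlabeled <- profiles_unlabeled[pairing]
  curves <- lapply(candidates, function(trf) {
    list(labeled = trf_abundance_curve(profiles_labeled, trf),
         unlabeled = trf_abundance_curve(matched_unlabeled, trf))
  })
  names(curves) <- as.character(candidates)
  score <- vapply(curves, function(cv)
    enrichment_score(cv$labeled, cv$unlabeled, heavy_window), numeric(1))
  out <- data.frame(phylotype_id = as.character(candidates),
                    enrichment_score = unname(score),
                    is_labeled = unname(score) >= threshold)
  structure(out, curves = curves, threshold = threshold,
            class = c("shift_report", "data.frame"))
}

# best-identity match of each labeled representative into the unlabeled set
match_otus_by_sequence <- function(rep_l, rep_u, identity_threshold = 0.97) {
  if (length(rep_u) == 0L) return(rep(NA_integer_, length(rep_l)))
  subj <- Biostrings::DNAStringSet(rep_u)
  vapply(rep_l, function(s) {
    ident <- alignment_identity(subj, s)
    j <- which.max(ident)
    if (ident[j] >= identity_threshold) j else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Detect 13C-labeled OTUs from heavy-fraction amplicon tables
#'
#' Candidate OTUs are those exceeding `min_abundance` relative abundance in
#' the heavy fraction of the labeled treatment; a candidate is flagged as
#' labeled when its labeled-minus-unlabeled relative abundance meets
#' `threshold`. OTU identity across the two independently clustered tables
#' is established by matching representative sequences at the clustering
#' identity (>= 97% by default), not by OTU ids; a labeled OTU with no
#' unlabeled counterpart gets unlabeled abundance 0.
#'
#' @param otu_heavy_labeled,otu_heavy_unlabeled [sip_otu_table()] objects
#'   from the matched heavy fractions of the same day. Each must contain
#'   one sample (or name the sample via `sample_labeled`/`sample_unlabeled`).
#' @param min_abundance Candidate screening threshold (default 0.01, i.e.
#'   strictly greater than 1%).
#' @param threshold Labeling call on the abundance difference (default 0.1).
#' @param identity_threshold Representative-sequence matching identity
#'   (default 0.97).
#' @param sample_labeled,sample_unlabeled Optional sample (column) names.
#' @return A `shift_report` data frame with `phylotype_id` (labeled-table
#'   OTU id), `rel_labeled`, `rel_unlabeled`, `enrichment_score`,
#'   `is_labeled`.
#' @export
detect_labeled_otus <- function(otu_heavy_labeled, otu_heavy_unlabeled,
                                min_abundance = 0.01, threshold = 0.1,
                                identity_threshold = 0.97,
                                sample_labeled = NULL, sample_unlabeled = NULL) {
  if (length(otu_heavy_labeled$otu_ids) == 0L ||
      length(otu_heavy_unlabeled$otu_ids) == 0L)
    stop("OTU tables must be non-empty")
  sl <- sample_labeled %||% colnames(otu_heavy_labeled$counts)[1]
  su <- sample_unlabeled %||% colnames(otu_heavy_unlabeled$counts)[1]
  rel_l <- relative_abundance(otu_heavy_labeled, sl)
  rel_u <- relative_abundance(otu_heavy_unlabeled, su)
  cand <- names(rel_l)[rel_l > min_abundance]
  if (length(cand) == 0L)
    return(structure(data.frame(phylotype_id = character(0),
                                rel_labeled = numeric(0),
                                rel_unlabeled = numeric(0),
                                enrichment_score = numeric(0),
                                is_labeled = logical(0)),
                     class = c("shift_report", "data.frame")))
  m <- match_otus_by_sequence(otu_heavy_labeled$representative_seqs[cand],
                              otu_heavy_unlabeled$representative_seqs,
                              identity_threshold)
  ru <- ifelse(is.na(m), 0, rel_u[m])
  score <- unname(rel_l[cand] - ru)
  structure(data.frame(phylotype_id = cand,
                       rel_labeled = unname(rel_l[cand]),
                       rel_unlabeled = unname(ru),
                       enrichment_score = score,
                       is_labeled = score >= threshold),
            threshold = threshold,
            class = c("shift_report", "data.frame"))
}

#' First day a phylotype is called labeled
#'
#' Given shift reports from successive sampling days, returns the earliest
#' day on which each phylotype was flagged; phylotypes never flagged get
#' `NA`.
#'
#' @param reports_by_day Named list of `shift_report`s; names are the
#'   sampling days (coercible to integer), in any order.
#' @return Data frame with `phylotype_id` and `first_labeled_day`
#'   (integer, `NA` when never labeled).
#' @export
first_labeled_day <- function(reports_by_day) {
  days <- as.integer(names(reports_by_day))
  if (any(is.na(days))) stop("reports_by_day must be named by integer day")
  ord <- order(days)
  ids <- unique(unlist(lapply(reports_by_day, function(r) r$phylotype_id)))
  first <- vapply(ids, function(id) {
    for (i in ord) {
      r <- reports_by_day[[i]]
      j <- match(id, r$phylotype_id)
      if (!is.na(j) && isTRUE(r$is_labeled[j])) return(days[i])
    }
    NA_integer_
  }, integer(1))
  data.frame(phylotype_id = ids, first_labeled_day = unname(first))
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("SIP shift report: %d phylotype(s), %d labeled (threshold %s)\n",
              NROW(x), sum(x$is_labeled), format(attr(x, "threshold"))))
  print(as.data.frame(x), ...)
  invisible(x)
}
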