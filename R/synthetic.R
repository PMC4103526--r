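#' Simulation configuration
#'
#' Defines the conditions of a synthetic SIP experiment: a mixed community
#' in which a known subset of taxa incorporates 13C, unlabeled buoyant
#' density driven by GC content, a label-driven density shift, Gaussian
#' banding over 22 gradient fractions, multiplicative peak-area noise with
#' a detection floor, multinomial read sampling of heavy fractions, and a
#' benzene degradation schedule reaching about 0/33/66/100% at days
#' 0/23/38/64.
#'
#' @param n_taxa Number of taxa (default 12).
#' @param labeled_taxa Ids of the taxa that assimilate the labeled
#'   substrate (default `c("taxon_08", "taxon_11")`, two of twelve).
#' @param n_fractions Gradient fractions collected per sample (default 22).
#' @param density_range Density grid covered by the gradient, g cm^-3
#'   (default `c(1.66, 1.78)`).
#' @param band_sigma Gaussian banding width of one taxon's DNA, g cm^-3
#'   (default 0.008: diffusion and fragment-length spread put measurable
#'   DNA in the heavy fractions of both treatments, as observed gradient
#'   profiles do).
#' @param delta_rho_full_label Density shift of fully 13C-labeled DNA,
#'   g cm^-3 (default 0.036, in `(0, 0.05]`).
#' @param peak_noise_cv Coefficient of variation of the lognormal
#'   multiplicative noise on peak areas (default 0.2).
#' @param detection_floor Peak areas below this are not reported by the
#'   simulated instrument (default 50 arbitrary units, so the analysis-side
#'   area filter is exercised).
#' @param area_scale Total fluorescence area corresponding to the whole
#'   community in one gradient (default 2e5 arbitrary units).
#' @param reads_per_fraction Amplicon reads sequenced per heavy fraction
#'   (default 500).
#' @param read_length Read length in bases (default 150).
#' @param error_rate Per-base substitution error rate of simulated reads
#'   (default 0.005).
#' @param days Sampling days (default `c(0, 23, 38, 64)`).
#' @param label_schedule Named numeric vector mapping day to the atom
#'   fraction 13C reached by labeled taxa (non-decreasing; default
#'   0/0/0.6/0.99 at days 0/23/38/64: assimilation begins between days 23
#'   and 38 and is essentially complete by day 64).
#' @param seed Integer seed; every simulator output is a deterministic
#'   function of it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 12,
                       labeled_taxa = c("taxon_08", "taxon_11"),
                       n_fractions = 22,
                       density_range = c(1.66, 1.78),
                       band_sigma = 0.008,
                       delta_rho_full_label = 0.036,
                       peak_noise_cv = 0.2,
                       detection_floor = 50,
                       area_scale = 2e5,
                       reads_per_fraction = 500,
                       read_length = 150,
                       error_rate = 0.005,
                       days = c(0, 23, 38, 64),
                       label_schedule = c("0" = 0, "23" = 0, "38" = 0.6,
                                          "64" = 0.99),
                       seed = 1) {
  stopifnot(n_fractions >= 2, band_sigma > 0,
            delta_rho_full_label > 0, delta_rho_full_label <= 0.05,
            peak_noise_cv >= 0, detection_floor >= 0,
            all(diff(as.integer(names(label_schedule))) > 0),
            all(diff(label_schedule) >= 0),
            all(label_schedule >= 0), all(label_schedule <= 1))
  structure(as.list(environment()), class = "sim_config")
}

#' Configuration of the four-assimilator amplicon experiment
#'
#' Preset for the OTU-level detection scenario: four of twelve taxa
#' (three bacterial, one archaeal) assimilate the labeled substrate. The
#' assimilators sit in the low-to-mid GC range (taxa 03-06, GC 0.40-0.46),
#' so their unlabeled DNA stays well below the heavy fractions and their
#' labeled DNA bands at the heavy-fraction target — the configuration in
#' which density-gradient sequencing resolves assimilation cleanly.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
otu_experiment_config <- function(seed = 1, ...) {
  sim_config(labeled_taxa = sprintf("taxon_%02d", 3:6), seed = seed, ...)
}

#' Synthetic community with exact T-RF ground truth
#'
#' Builds `n_taxa` taxa with equal abundance, GC contents evenly spaced in
#' `gc_range`, and 16S-like sequences constructed from a random template
#' with a planted forward-primer site at the 5' end and a planted HhaI site
#' at a controlled position, so every taxon has a unique, known terminal
#' restriction fragment length. Any accidental upstream recognition site is
#' rewritten away, making the T-RF-to-taxon map exact. Labeled taxa follow
#' the configured `label_schedule`; all other taxa stay at atom fraction 0.
#'
#' @param cfg A [sim_config()].
#' @param gc_range GC-content range spanned by the community (default
#'   `c(0.36, 0.58)`).
#' @param trf_lengths Optional integer vector of target T-RF lengths, one
#'   per taxon (default: evenly spread over 60-500 bases).
#' @param seq_length Length of each synthetic 16S sequence (default 600).
#' @return Data frame of class `sim_community`: `id`, `taxonomy`,
#'   `seq_16S`, `abundance`, `gc_fraction`, `trf_length`, `labeled`.
#' @export
sim_community <- function(cfg = sim_config(), gc_range = c(0.36, 0.58),
                          trf_lengths = NULL, seq_length = 600) {
  n <- cfg$n_taxa
  if (is.null(trf_lengths))
    trf_lengths <- as.integer(round(seq(60, 500, length.out = n)))
  stopifnot(length(trf_lengths) == n, !anyDuplicated(trf_lengths),
            all(trf_lengths >= 24), all(trf_lengths <= seq_length - 4))
  ids <- sprintf("taxon_%02d", seq_len(n))
  stopifnot(all(cfg$labeled_taxa %in% ids))
  gc <- seq(gc_range[1], gc_range[2], length.out = n)
  set.seed(derive_seed(cfg$seed, 7L))
  seqs <- mapply(synth_16s_sequence, gc, trf_lengths,
                 MoreArgs = list(seq_length = seq_length))
  tax <- sprintf("Bacteria;synthetic_clade_%02d", seq_len(n))
  # the highest-numbered labeled taxon is archaeal, so multi-labeled
  # configurations mirror a mixed bacterial/archaeal assimilator set
  idx <- which(ids %in% cfg$labeled_taxa)
  if (length(idx) > 1L)
    tax[idx[length(idx)]] <- sprintf("Archaea;synthetic_clade_%02d",
                                     idx[length(idx)])
  out <- data.frame(id = ids, taxonomy = tax, seq_16S = unname(seqs),
                    abundance = rep(1 / n, n), gc_fraction = gc,
                    trf_length = trf_lengths,
                    labeled = ids %in% cfg$labeled_taxa,
                    stringsAsFactors = FALSE)
  class(out) <- c("sim_community", "data.frame")
  out
}

# Random sequence at a target GC with planted primer (concrete Ba27f
# expansion, M -> C) and planted GCGC such that the forward-strand T-RF is
# exactly `trf_length`. Accidental GCGC occurrences upstream of the
# planted site are destroyed (they would shorten the T-RF), and
# homopolymer runs of 6+ bases are broken everywhere (real amplifiable
# templates do not lose whole read populations to the homopolymer QC
# filter). Fix-up substitutions use A/T only, which can never create a new
# GCGC site.
synth_16s_sequence <- function(gc, trf_length, seq_length = 600) {
  primer <- "AGAGTTTGATCCTGGCTCAG"
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  body <- sample(c("A", "C", "G", "T"), seq_length - nchar(primer),
                 replace = TRUE, prob = p)
  s <- c(strsplit(primer, "")[[1]], body)
  site_start <- trf_length - 2L  # cut at offset 3 => length = site_start + 2
  s[site_start:(site_start + 3L)] <- c("G", "C", "G", "C")
  upstream_sites <- function(s) {
    str <- paste(s, collapse = "")
    hits <- sort(unique(c(
      gregexpr("GCGC", str, fixed = TRUE)[[1]],
      gregexpr("GCGC", substring(str, 2), fixed = TRUE)[[1]] + 1L)))
    hits[hits > 1 & hits < site_start]
  }
  long_runs <- function(s) {
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    starts[r$lengths >= 6L]
  }
  for (iter in 1:100) {
    bad <- upstream_sites(s)
    if (length(bad)) {               # kill the second G of the site
      pos <- bad[1] + 2L
      s[pos] <- if (identical(s[pos - 1L], "A") || identical(s[pos + 1L], "A"))
        "T" else "A"
      next
    }
    runs <- long_runs(s)
    if (length(runs)) {              # break the run at its 6th base
      pos <- runs[1] + 5L
      s[pos] <- if (s[pos] == "T" || s[pos] == "A") {
        if (s[pos] == "T") "A" else "T"
      } else "A"
      next
    }
    break
  }
  if (length(upstream_sites(s)) || length(long_runs(s)))
    stop("could not sanitize synthetic sequence")  # nocov
  paste(s, collapse = "")
}

# deterministic sub-seed, independent of R's RNG state, < 2^31
derive_seed <- function(seed, ...) {
  k <- c(seed, ...)
  s <- 0
  for (x in k) s <- (s * 69069 + as.numeric(x) + 1) %% 2147483647
  as.integer(s)
}

#' Buoyant density of unlabeled DNA from GC content
#'
#' Linear GC-density relation for double-stranded DNA in CsCl,
#' `rho = 1.660 + 0.098 * gc` (g cm^-3).
#'
#' @param gc_fraction GC content in `[0, 1]`.
#' @return Buoyant density, g cm^-3.
#' @export
unlabeled_density <- function(gc_fraction) {
  stopifnot(all(gc_fraction >= 0), all(gc_fraction <= 1))
  1.660 + 0.098 * gc_fraction
}

#' Buoyant density of partially 13C-labeled DNA
#'
#' Adds a linear label shift to the unlabeled density:
#' `rho = unlabeled_density(gc) + atom_frac * delta_rho_full_label`.
#'
#' @param gc_fraction GC content in `[0, 1]`.
#' @param atom_frac_13C Atom fraction 13C in `[0, 1]`.
#' @param delta_rho_full_label Shift at full labeling, g cm^-3
#'   (default 0.036).
#' @return Buoyant density, g cm^-3.
#' @export
labeled_density <- function(gc_fraction, atom_frac_13C,
                            delta_rho_full_label = 0.036) {
  stopifnot(all(atom_frac_13C >= 0), all(atom_frac_13C <= 1))
  unlabeled_density(gc_fraction) + atom_frac_13C * delta_rho_full_label
}

# atom fraction of a labeled taxon at `day` (step schedule at sampled days)
atom_fraction_at <- function(cfg, day) {
  sched_days <- as.integer(names(cfg$label_schedule))
  i <- match(day, sched_days)
  if (!is.na(i)) return(unname(cfg$label_schedule[i]))
  # between sampled days: last reached level
  j <- findInterval(day, sched_days)
  if (j == 0) 0 else unname(cfg$label_schedule[j])
}

# fraction density intervals, index 1 = densest (collected bottom-up)
fraction_intervals <- function(cfg) {
  b <- seq(cfg$density_range[1], cfg$density_range[2],
           length.out = cfg$n_fractions + 1)
  data.frame(index = seq_len(cfg$n_fractions),
             lower = rev(b[-length(b)]), upper = rev(b[-1]))
}

# taxon x fraction mass matrix (Gaussian banding, no noise)
taxon_fraction_mass <- function(community, cfg, day, treatment) {
  iv <- fraction_intervals(cfg)
  atom <- ifelse(community$labeled & treatment == "labeled",
                 atom_fraction_at(cfg, day), 0)
  rho <- labeled_density(community$gc_fraction, atom, cfg$delta_rho_full_label)
  if (any(rho - 3 * cfg$band_sigma < cfg$density_range[1]) ||
      any(rho + 3 * cfg$band_sigma > cfg$density_range[2]))
    warning("density grid does not cover all taxon bands +- 3 sigma")
  m <- vapply(seq_len(NROW(community)), function(t) {
    community$abundance[t] *
      (stats::pnorm(iv$upper, rho[t], cfg$band_sigma) -
       stats::pnorm(iv$lower, rho[t], cfg$band_sigma))
  }, numeric(cfg$n_fractions))
  dimnames(m) <- list(NULL, community$id)
  m  # fractions x taxa
}

#' Simulate one density gradient with T-RFLP payloads
#'
#' Distributes each taxon's DNA over the gradient fractions as a Gaussian
#' band centred on its (labeling-state-dependent) buoyant density, converts
#' per-fraction taxon masses to T-RF peak areas with lognormal
#' multiplicative noise and a detection floor, and back-computes
#' refractometer readings from the fraction densities. The noise draw for a
#' given (seed, day, taxon) is shared between treatments, so the labeled
#' and unlabeled gradients differ only for taxa with a nonzero label
#' schedule.
#'
#' @param community A [sim_community()].
#' @param cfg A [sim_config()].
#' @param day Sampling day.
#' @param treatment `"labeled"` or `"unlabeled"`.
#' @return List with `fractions` (a [gradient_fractions()] table),
#'   `profiles` (raw `trf_profile` per fraction, densest first), `peaks`
#'   (long raw peak table), and `mass` (noise-free taxon-by-fraction
#'   masses, the simulator ground truth).
#' @export
simulate_gradient <- function(community, cfg, day,
                              treatment = c("labeled", "unlabeled")) {
  treatment <- match.arg(treatment)
  iv <- fraction_intervals(cfg)
  mass <- taxon_fraction_mass(community, cfg, day, treatment)
  cv <- cfg$peak_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  noise <- vapply(seq_len(NROW(community)), function(t) {
    # treatment-independent noise stream per (seed, day, taxon)
    set.seed(derive_seed(cfg$seed, 11L, day, t))
    if (cv > 0) stats::rlnorm(cfg$n_fractions, -sdlog^2 / 2, sdlog)
    else rep(1, cfg$n_fractions)
  }, numeric(cfg$n_fractions))
  area <- mass * cfg$area_scale * noise

  cal <- density_calibration()
  mid <- (iv$lower + iv$upper) / 2
  ri <- round(refractive_index_from_density(mid, cal), 4)
  fractions <- gradient_fractions(
    data.frame(treatment = treatment, day = day, index = iv$index,
               refractive_index = ri), cal)

  profiles <- lapply(seq_len(cfg$n_fractions), function(i) {
    keep <- which(area[i, ] >= cfg$detection_floor)
    pk <- data.frame(length = community$trf_length[keep],
                     area = unname(area[i, keep]))
    pk <- pk[order(pk$length), , drop = FALSE]
    rownames(pk) <- NULL
    trf_profile(pk, fraction = as.list(fractions[i, c(
      "treatment", "day", "index", "refractive_index", "buoyant_density")]))
  })
  names(profiles) <- paste(treatment, day, iv$index, sep = "|")
  peaks <- do.call(rbind, lapply(profiles, function(p) {
    if (NROW(p) == 0L) return(NULL)
    fr <- attr(p, "fraction")
    data.frame(treatment = fr$treatment, day = fr$day,
               fraction_index = fr$index, trf_length = p$length,
               peak_area = p$area)
  }))
  rownames(peaks) <- NULL
  list(fractions = fractions, profiles = profiles, peaks = peaks, mass = mass)
}

#' Simulate amplicon reads from one gradient fraction
#'
#' Draws read counts from a multinomial over taxa weighted by the
#' fraction-specific DNA mass, then emits fixed-length reads from a fixed
#' window of each taxon's sequence with independent per-base substitution
#' errors and plausible Phred qualities. Deterministic given the seed.
#'
#' @param community A [sim_community()].
#' @param mass_row Named numeric vector of taxon masses in the fraction
#'   (one row of `simulate_gradient()$mass`).
#' @param cfg A [sim_config()].
#' @param day,treatment,fraction_index Identity of the fraction (used for
#'   read ids, the `sample` label, and the seed stream).
#' @param read_start First base of the read window (default 201, clear of
#'   the primer region).
#' @return Read data frame (`id`, `sequence`, `quality`, `sample`,
#'   `treatment`, `day`, `fraction_index`, `source_taxon`).
#' @export
simulate_reads <- function(community, mass_row, cfg, day, treatment,
                           fraction_index, read_start = 201) {
  stopifnot(cfg$reads_per_fraction > 0)
  w <- mass_row[community$id]
  if (sum(w) <= 0) stop("fraction has no DNA mass to sequence")
  set.seed(derive_seed(cfg$seed, 13L, day, treatment == "labeled", fraction_index))
  counts <- stats::rmultinom(1, cfg$reads_per_fraction, w)[, 1]
  len <- cfg$read_length
  sample_id <- sprintf("%s_d%02d_f%02d", treatment, day, fraction_index)
  out <- lapply(which(counts > 0), function(t) {
    n <- counts[t]
    tmpl <- substring(community$seq_16S[t], read_start, read_start + len - 1L)
    seqs <- vapply(seq_len(n), function(i) {
      ch <- strsplit(tmpl, "")[[1]]
      err <- stats::runif(len) < cfg$error_rate
      if (any(err))
        ch[err] <- vapply(ch[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1))
    q <- vapply(seq_len(n), function(i) {
      qq <- pmin(40L, pmax(25L, as.integer(round(stats::rnorm(len, 35, 2)))))
      intToUtf8(qq + 33L)
    }, character(1))
    data.frame(id = sprintf("%s_%s_r%04d", sample_id, community$id[t], seq_len(n)),
               sequence = seqs, quality = q, sample = sample_id,
               treatment = treatment, day = day,
               fraction_index = fraction_index,
               source_taxon = community$id[t], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# least-squares (lag, k) calibration of lagged first-order decay against
# the cumulative-degradation anchor schedule
fit_decay <- function(anchors = data.frame(day = c(23, 38, 63),
                                           remaining = c(0.67, 0.34, 0.02))) {
  obj <- function(p) {
    lag <- p[1]; k <- exp(p[2])
    r <- ifelse(anchors$day <= lag, 1, exp(-k * (anchors$day - lag)))
    sum((r - anchors$remaining)^2)
  }
  fit <- stats::optim(c(10, log(0.05)), obj, method = "Nelder-Mead")
  list(lag = fit$par[1], k = exp(fit$par[2]))
}

#' Simulate benzene degradation and 13C gas production
#'
#' By default benzene follows a monotone interpolation of the sampling
#' schedule — cumulative degradation of 0/33/66/100% at days 0/23/38/64,
#' the condition under which the gradient samples were drawn;
#' `curve = "fit"` instead uses a lagged first-order decay least-squares
#' calibrated against the same schedule (a single rate constant cannot
#' pass through all three interior anchors, so the fit is a mechanistic
#' approximation that under-degrades early). Degraded
#' carbon is partitioned into CH4, CO2, a biomass fraction (at most 10% by
#' default) and intermediates, conserving carbon exactly at every
#' timepoint. The default gas fractions `f_ch4 = 0.28`, `f_co2 = 0.44`
#' give 72% mineralization at completion.
#'
#' @param cfg A [sim_config()] (supplies the sampling days; the series is
#'   emitted daily from day 0 to the last sampling day).
#' @param f_ch4,f_co2 Fractions of degraded carbon recovered as CH4 and
#'   CO2.
#' @param f_biomass Fraction of degraded carbon in biomass (default 0.10,
#'   must be <= 0.10; `f_ch4 + f_co2 + f_biomass <= 1`).
#' @param benzene_umol Initial benzene per vial, umol (default 26.3:
#'   about 1.3 mM aqueous in 20 mL).
#' @param treatment Treatment label for the emitted series.
#' @param cfg_henry A [henry_config()] used to express remaining benzene
#'   as an aqueous concentration.
#' @param curve `"anchors"` (exact monotone interpolation of the sampling
#'   schedule, default) or `"fit"` (lagged first-order calibration).
#' @return Data frame of class `gas_series` with columns `day`,
#'   `treatment`, `benzene_aq` (mM), `ch4_13C`, `co2_13C`, `biomass_C`,
#'   `intermediates_C`, `degraded_C` (umol-C).
#' @export
simulate_gas <- function(cfg = sim_config(), f_ch4 = 0.28, f_co2 = 0.44,
                         f_biomass = 0.10, benzene_umol = 26.3,
                         treatment = "labeled",
                         cfg_henry = henry_config(),
                         curve = c("anchors", "fit")) {
  curve <- match.arg(curve)
  if (f_biomass > 0.10 + 1e-12) stop("biomass fraction must be <= 0.10")
  if (f_ch4 + f_co2 + f_biomass > 1 + 1e-12)
    stop("partition fractions must sum to <= 1")
  days <- seq(0, max(cfg$days))
  remaining <- if (curve == "fit") {
    dk <- fit_decay()
    ifelse(days <= dk$lag, 1, exp(-dk$k * (days - dk$lag)))
  } else {
    anchors_x <- c(0, 23, 38, 64)
    anchors_y <- c(1, 0.67, 0.34, 0)
    f <- stats::splinefun(anchors_x, anchors_y, method = "hyman")
    pmax(0, f(pmin(days, 64)))
  }
  total_C <- benzene_to_carbon(benzene_umol)
  degraded_C <- total_C * (1 - remaining)
  ch4 <- f_ch4 * degraded_C
  co2 <- f_co2 * degraded_C
  bio <- f_biomass * degraded_C
  interm <- degraded_C - ch4 - co2 - bio
  benzene_aq_mM <- benzene_umol * remaining /
    (cfg_henry$V_liq + cfg_henry$H_cc * cfg_henry$V_gas)  # umol / mL = mM
  out <- data.frame(day = days, treatment = treatment,
                    benzene_aq = benzene_aq_mM,
                    ch4_13C = ch4, co2_13C = co2, biomass_C = bio,
                    intermediates_C = interm, degraded_C = degraded_C)
  class(out) <- c("gas_series", "data.frame")
  out
}

#' Simulate a complete SIP experiment
#'
#' Runs [simulate_gradient()] for both treatments on every sampling day,
#' [simulate_reads()] on each day's heavy fractions, and [simulate_gas()],
#' returning everything the analysis modules consume plus the ground truth
#' (labeled taxa, the T-RF-to-taxon map, taxon densities).
#'
#' @param cfg A [sim_config()].
#' @param community Optional pre-built [sim_community()].
#' @param reads_for Days for which heavy-fraction reads are simulated
#'   (default: all days after day 0).
#' @return List of class `sip_experiment` with elements `community`,
#'   `gradients` (nested `[[treatment]][[day]]`), `reads` (per day, both
#'   treatments' heavy fractions), `gas`, `truth`.
#' @export
simulate_experiment <- function(cfg = sim_config(), community = NULL,
                                reads_for = NULL) {
  if (is.null(community)) community <- sim_community(cfg)
  if (is.null(reads_for)) reads_for <- setdiff(cfg$days, 0)
  gradients <- list()
  for (tr in c("labeled", "unlabeled")) {
    gradients[[tr]] <- lapply(cfg$days, function(d)
      simulate_gradient(community, cfg, d, tr))
    names(gradients[[tr]]) <- as.character(cfg$days)
  }
  reads <- lapply(reads_for, function(d) {
    per_tr <- lapply(c("labeled", "unlabeled"), function(tr) {
      g <- gradients[[tr]][[as.character(d)]]
      heavy <- select_heavy_fraction(g$fractions)
      i <- heavy$index
      simulate_reads(community, g$mass[which(g$fractions$index == i), ],
                     cfg, d, tr, i)
    })
    do.call(rbind, per_tr)
  })
  names(reads) <- as.character(reads_for)
  truth <- list(
    labeled_taxa = community$id[community$labeled],
    trf_map = stats::setNames(community$trf_length, community$id),
    unlabeled_densities = stats::setNames(
      unlabeled_density(community$gc_fraction), community$id))
  structure(list(community = community, gradients = gradients, reads = reads,
                 gas = simulate_gas(cfg), truth = truth, cfg = cfg),
            class = "sip_experiment")
}

#' Write a simulated experiment to analysis-ready files
#'
#' Emits the same TSV/CSV/FASTA/FASTQ formats the analysis functions
#' consume, plus a ground-truth JSON.
#'
#' @param exp A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fractions = file.path(dir, "fractions.tsv"),
             peaks = file.path(dir, "peaks.tsv"),
             gas = file.path(dir, "gas.csv"),
             refs = file.path(dir, "community_refs.fasta"),
             truth = file.path(dir, "truth.json"))
  frs <- do.call(rbind, lapply(exp$gradients, function(trl)
    do.call(rbind, lapply(trl, `[[`, "fractions"))))
  frs_out <- data.frame(treatment = frs$treatment, day = frs$day,
                        fraction_index = frs$index,
                        refractive_index = frs$refractive_index)
  utils::write.table(frs_out, paths["fractions"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pks <- do.call(rbind, lapply(exp$gradients, function(trl)
    do.call(rbind, lapply(trl, `[[`, "peaks"))))
  utils::write.table(pks, paths["peaks"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  gas <- exp$gas
  utils::write.csv(data.frame(day = gas$day, treatment = gas$treatment,
                              benzene_aq_mM = gas$benzene_aq,
                              ch4_umolC = gas$ch4_13C,
                              co2_umolC = gas$co2_13C),
                   paths["gas"], row.names = FALSE, quote = FALSE)
  fa <- Biostrings::DNAStringSet(stats::setNames(exp$community$seq_16S,
                                                 exp$community$taxonomy))
  Biostrings::writeXStringSet(fa, paths["refs"])
  jsonlite::write_json(exp$truth, paths["truth"], auto_unbox = TRUE)
  for (d in names(exp$reads)) {
    p <- file.path(dir, sprintf("reads_day%s.fastq", d))
    write_fastq(exp$reads[[d]], p)
    paths[paste0("reads_day", d)] <- p
  }
  invisible(paths)
}
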