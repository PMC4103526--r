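#' Refractometry calibration for CsCl buoyant density
#'
#' Linear calibration `d = alpha * n - beta` converting the refractive index
#' `n` of a CsCl gradient fraction to its buoyant density `d` (g cm^-3). The
#' default constants are the standard values for CsCl at 20 degrees C.
#'
#' @param alpha Slope of the calibration (dimensionless, > 0).
#' @param beta Intercept of the calibration (dimensionless, > 0).
#' @param temperature_C Temperature the constants refer to (informational).
#' @return An object of class `density_calibration`.
#' @examples
#' cal <- density_calibration()
#' density_from_refractive_index(1.3990, cal)
#' @export
density_calibration <- function(alpha = 10.927, beta = 13.593, temperature_C = 20) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0)
  structure(list(alpha = alpha, beta = beta, temperature_C = temperature_C),
            class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf("CsCl density calibration: d = %.3f * n - %.3f (at %s degC)\n",
              x$alpha, x$beta, format(x$temperature_C)))
  invisible(x)
}

#' Convert refractive index to buoyant density
#'
#' Applies the linear calibration `d = alpha * n - beta`. Vectorized over `n`.
#' Values outside the plausible CsCl refractive-index range (1.30-1.50) are
#' accepted with a warning, since they usually indicate a mistyped reading.
#'
#' @param n Refractive index (dimensionless).
#' @param cal A [density_calibration()].
#' @return Buoyant density in g cm^-3.
#' @export
density_from_refractive_index <- function(n, cal = density_calibration()) {
  if (!is.numeric(n) || any(!is.finite(n)))
    stop("refractive index must be finite numeric")
  if (any(n < 1.30 | n > 1.50))
    warning("refractive index outside the plausible CsCl range [1.30, 1.50]")
  cal$alpha * n - cal$beta
}

#' Invert the density calibration
#'
#' Returns the refractive index corresponding to a buoyant density,
#' `n = (d + beta) / alpha`. Used by the simulator to emit refractometer
#' readings for synthetic fractions.
#'
#' @param d Buoyant density in g cm^-3.
#' @inheritParams density_from_refractive_index
#' @return Refractive index (dimensionless).
#' @export
refractive_index_from_density <- function(d, cal = density_calibration()) {
  if (!is.numeric(d) || any(!is.finite(d))) stop("density must be finite numeric")
  (d + cal$beta) / cal$alpha
}

#' Build a gradient fraction table
#'
#' Validates and classes a per-fraction table. Fractions are numbered
#' bottom-up (index 1 = densest, collected first from the bottom of the
#' tube); all downstream comparisons use buoyant density, never the index.
#'
#' @param df Data frame with columns `treatment` ("labeled"/"unlabeled"),
#'   `day` (integer days), `index` (1-based fraction number) and
#'   `refractive_index`; a `buoyant_density` column is (re)computed.
#' @param cal A [density_calibration()].
#' @return `df` with `buoyant_density` appended, class `gradient_fractions`.
#' @export
gradient_fractions <- function(df, cal = density_calibration()) {
  need <- c("treatment", "day", "index", "refractive_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fraction table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(df$treatment %in% c("labeled", "unlabeled")))
    stop("treatment must be 'labeled' or 'unlabeled'")
  if (any(df$index < 1)) stop("fraction index must be >= 1")
  df$buoyant_density <- density_from_refractive_index(df$refractive_index, cal)
  class(df) <- unique(c("gradient_fractions", class(df)))
  df
}

# Nearest-neighbour match of density vector `da` into `db`; equidistant ties
# break toward the denser candidate (heavier DNA carries the signal).
match_density <- function(da, db, tie_tol = 1e-9) {
  vapply(da, function(d) {
    diff <- abs(db - d)
    j <- which(diff <= min(diff) + tie_tol)
    if (length(j) > 1L) j <- j[which.max(db[j])]
    j
  }, integer(1))
}

#' Pair gradient fractions across treatments by buoyant density
#'
#' For each fraction of `a`, finds the fraction of `b` with the same or
#' closest buoyant density. Equidistant ties break toward the denser
#' fraction of `b`. The pairing is deterministic and independent of row
#' order in `b`.
#'
#' @param a,b `gradient_fractions` tables (or any data frames with a
#'   `buoyant_density` column) from the same sampling day.
#' @return Data frame with one row per fraction of `a`: `a_index`, `b_index`
#'   (row numbers into `a` and `b`), `a_density`, `b_density`.
#' @export
match_fractions <- function(a, b) {
  if (NROW(a) == 0L || NROW(b) == 0L) stop("cannot match empty fraction lists")
  if ("day" %in% names(a) && "day" %in% names(b) &&
      length(unique(c(a$day, b$day))) > 1L)
    stop("fractions to match must come from the same day")
  j <- match_density(a$buoyant_density, b$buoyant_density)
  data.frame(a_index = seq_len(NROW(a)), b_index = j,
             a_density = a$buoyant_density, b_density = b$buoyant_density[j])
}

#' Select the heavy (or any target-density) fraction
#'
#' Returns the fraction whose buoyant density is closest to `target`
#' (default 1.732 g cm^-3, the conventional heavy-fraction density for
#' 13C-SIP). Ties break toward the denser fraction. The selection is
#' invariant to the order of the input rows.
#'
#' @param fractions A `gradient_fractions` table (or data frame with a
#'   `buoyant_density` column).
#' @param target Target buoyant density in g cm^-3.
#' @return The selected row of `fractions` (one-row data frame).
#' @export
select_heavy_fraction <- function(fractions, target = 1.732) {
  if (NROW(fractions) == 0L) stop("no fractions to select from")
  d <- fractions$buoyant_density
  if (is.null(d) || any(!is.finite(d))) stop("buoyant densities must be computed first")
  fractions[select_heavy_index(d, target), , drop = FALSE]
}

# index of the density closest to target; ties toward the denser value
select_heavy_index <- function(densities, target = 1.732, tie_tol = 1e-9) {
  if (length(densities) == 0L) stop("no fractions to select from")
  diff <- abs(densities - target)
  j <- which(diff <= min(diff) + tie_tol)
  if (length(j) > 1L) j <- j[which.max(densities[j])]
  unname(j)
}

#' Read a fraction table from TSV
#'
#' Expects columns `treatment`, `day`, `fraction_index`, `refractive_index`;
#' buoyant density is appended on load via the calibration.
#'
#' @param path Path to a tab-separated fraction table.
#' @inheritParams gradient_fractions
#' @return A `gradient_fractions` table.
#' @export
read_fraction_table <- function(path, cal = density_calibration()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("fraction_index" %in% names(df) && !"index" %in% names(df))
    names(df)[names(df) == "fraction_index"] <- "index"
  gradient_fractions(df, cal)
}
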