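# Unit conversions between SI and conventional units.
# Glucose: 1 mmol/l = 18.016 mg/dl. Insulin: 1 uU/ml = 6.0 pmol/l by
# default (6.945 is also in use; configurable where it matters).
MGDL_PER_MMOL <- 18.016
PMOL_PER_UU <- 6.0

#' Matsuda/DeFronzo whole-body insulin sensitivity index
#'
#' Computes ISI = 10000 / sqrt(G0 * I0 * Gmean * Imean) from a five-point
#' OGTT (0, 30, 60, 90, 120 min), with glucose in mg/dl and insulin in
#' uU/ml inside the formula; inputs are taken in SI units (glucose mmol/l,
#' insulin pmol/l) and converted internally. Means are unweighted arithmetic
#' means over the five samples.
#'
#' @param glucose Numeric matrix or vector of glucose (mmol/l); for a cohort,
#'   subjects in rows and the five time points in columns (0,30,60,90,120).
#' @param insulin Insulin (pmol/l), same shape.
#' @param pmol_per_uU Insulin conversion factor (pmol/l per uU/ml);
#'   default 6.0.
#' @return Positive numeric vector of ISI values (arbitrary units).
#' @examples
#' matsuda_isi(glucose = c(5, 6.5, 8, 7.5, 6.3),
#'             insulin = c(60, 360, 420, 330, 300))
#' @export
matsuda_isi <- function(glucose, insulin, pmol_per_uU = PMOL_PER_UU) {
  if (is.vector(glucose)) glucose <- matrix(glucose, nrow = 1)
  if (is.vector(insulin)) insulin <- matrix(insulin, nrow = 1)
  glucose <- as.matrix(glucose); insulin <- as.matrix(insulin)
  if (ncol(glucose) != 5L || ncol(insulin) != 5L)
    stop("ISI requires exactly the five OGTT time points 0/30/60/90/120 min")
  if (!all(dim(glucose) == dim(insulin)))
    stop("glucose and insulin must have identical dimensions")
  if (anyNA(glucose) || anyNA(insulin) ||
      any(glucose <= 0) || any(insulin <= 0))
    stop("all OGTT glucose and insulin values must be positive and present")
  g <- glucose * MGDL_PER_MMOL
  i <- insulin / pmol_per_uU
  10000 / sqrt(g[, 1] * i[, 1] * rowMeans(g) * rowMeans(i))
}

#' HOMA indices of insulin resistance and beta-cell function
#'
#' HOMA-IR = (G * I) / 22.5 and HOMA-B = 20 * I / (G - 3.5), with fasting
#' glucose G in mmol/l and fasting insulin I in uU/ml (converted from
#' pmol/l). HOMA-B is undefined at G <= 3.5 mmol/l and returned as NA with
#' a warning.
#'
#' @param fasting_glucose Fasting glucose, mmol/l (> 0).
#' @param fasting_insulin Fasting insulin, pmol/l (> 0).
#' @param pmol_per_uU Insulin conversion factor; default 6.0.
#' @return Data.frame with columns \code{homa_ir}, \code{homa_b}.
#' @export
homa_indices <- function(fasting_glucose, fasting_insulin,
                         pmol_per_uU = PMOL_PER_UU) {
  if (any(!is.finite(fasting_glucose)) || any(!is.finite(fasting_insulin)) ||
      any(fasting_glucose <= 0) || any(fasting_insulin <= 0))
    stop("fasting glucose and insulin must be positive")
  i_uU <- fasting_insulin / pmol_per_uU
  homa_ir <- fasting_glucose * i_uU / 22.5
  homa_b <- rep(NA_real_, length(fasting_glucose))
  ok <- fasting_glucose > 3.5
  if (!all(ok))
    warning("HOMA-B undefined for ", sum(!ok),
            " subject(s) with fasting glucose <= 3.5 mmol/l; returned NA")
  homa_b[ok] <- 20 * i_uU[ok] / (fasting_glucose[ok] - 3.5)
  data.frame(homa_ir = homa_ir, homa_b = homa_b)
}

#' Median split of the insulin sensitivity index
#'
#' Splits a cohort at the sample median ISI: subjects strictly below the
#' median are insulin resistant; subjects at or above it are insulin
#' sensitive (ties at the median fall on the sensitive side).
#'
#' @param isi Numeric vector of positive ISI values.
#' @return List with \code{threshold} (the median) and logical
#'   \code{resistant} mask.
#' @examples
#' median_isi_split(c(10, 14.3, 20))
#' @export
median_isi_split <- function(isi) {
  if (length(isi) == 0L) stop("empty ISI vector")
  thr <- stats::median(isi)
  list(threshold = thr, resistant = isi < thr)
}

#' Add metabolic index columns to a phenotype table
#'
#' Computes \code{isi_matsuda}, \code{homa_ir} and \code{homa_b} from the
#' OGTT columns \code{glucose_<t>_mmol_l} and \code{insulin_<t>_pmol_l}
#' (t in 0, 30, 60, 90, 120).
#'
#' @param phenotypes Phenotype data.frame.
#' @param pmol_per_uU Insulin conversion factor; default 6.0.
#' @return The data.frame with three columns appended.
#' @export
add_metabolic_indices <- function(phenotypes, pmol_per_uU = PMOL_PER_UU) {
  times <- c(0, 30, 60, 90, 120)
  gcols <- paste0("glucose_", times, "_mmol_l")
  icols <- paste0("insulin_", times, "_pmol_l")
  missing_cols <- setdiff(c(gcols, icols), names(phenotypes))
  if (length(missing_cols) > 0L)
    stop("phenotype table lacks OGTT column(s): ",
         paste(missing_cols, collapse = ", "))
  g <- as.matrix(phenotypes[, gcols])
  i <- as.matrix(phenotypes[, icols])
  phenotypes$isi_matsuda <- matsuda_isi(g, i, pmol_per_uU)
  h <- homa_indices(g[, 1], i[, 1], pmol_per_uU)
  phenotypes$homa_ir <- h$homa_ir
  phenotypes$homa_b <- h$homa_b
  phenotypes
}
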