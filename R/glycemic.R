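#' ADA-based glycemic classification from an OGTT
#'
#' Classifies subjects from fasting and 2-h post-load glucose (mmol/l) into
#' NGT, isolated IFG, isolated IGT, IFG+IGT, or DIABETES. Cut-offs follow
#' the American Diabetes Association: IFG at fasting >= 5.6 mmol/l, IGT at
#' 2-h >= 7.8 mmol/l, diabetes at fasting >= 7.0 or 2-h >= 11.1 mmol/l.
#' Diabetic subjects are excluded from all downstream analyses.
#'
#' @param fasting_glucose,twohour_glucose Numeric vectors, mmol/l; positive
#'   and finite.
#' @return Factor with levels NGT, ISOLATED_IFG, ISOLATED_IGT, IFG_IGT,
#'   DIABETES.
#' @examples
#' classify_glycemia(c(5.5, 5.6, 5.5, 5.6), c(7.7, 7.7, 7.8, 7.8))
#' @export
classify_glycemia <- function(fasting_glucose, twohour_glucose) {
  if (length(fasting_glucose) != length(twohour_glucose))
    stop("glucose vectors must have equal length")
  bad <- !is.finite(fasting_glucose) | !is.finite(twohour_glucose) |
    fasting_glucose <= 0 | twohour_glucose <= 0
  if (any(bad))
    stop("glucose values must be positive and non-missing (",
         sum(bad), " offending row(s))")
  lev <- c("NGT", "ISOLATED_IFG", "ISOLATED_IGT", "IFG_IGT", "DIABETES")
  ifg <- fasting_glucose >= 5.6
  igt <- twohour_glucose >= 7.8
  out <- ifelse(fasting_glucose >= 7.0 | twohour_glucose >= 11.1, "DIABETES",
         ifelse(ifg & igt, "IFG_IGT",
         ifelse(igt, "ISOLATED_IGT",
         ifelse(ifg, "ISOLATED_IFG", "NGT"))))
  factor(out, levels = lev)
}

#' Indicator columns for the composite prediabetes groups
#'
#' @param category Factor from \code{\link{classify_glycemia}}.
#' @return Data.frame with logical columns \code{igt_combined} (isolated IGT
#'   or IFG+IGT, i.e. elevated post-load glucose independently of fasting
#'   glycemia) and \code{prediabetes} (IFG and/or IGT). Diabetic rows get NA.
#' @export
glycemic_indicators <- function(category) {
  stopifnot(is.factor(category))
  igt_combined <- category %in% c("ISOLATED_IGT", "IFG_IGT")
  prediabetes <- category %in% c("ISOLATED_IFG", "ISOLATED_IGT", "IFG_IGT")
  igt_combined[category == "DIABETES"] <- NA
  prediabetes[category == "DIABETES"] <- NA
  data.frame(igt_combined = igt_combined, prediabetes = prediabetes)
}

#' Group counts for the glycemic category lattice
#'
#' Tallies the four non-diabetic categories and derives the composite
#' groups: combined IGT (isolated IGT plus IFG+IGT) and prediabetes
#' (IFG and/or IGT).
#'
#' @param classes Factor of glycemic categories (diabetes rows, if any, are
#'   dropped with a message).
#' @return Named integer vector with elements NGT, ISOLATED_IFG,
#'   ISOLATED_IGT, IFG_IGT, IGT_combined, prediabetes, total.
#' @examples
#' cl <- factor(rep(c("ISOLATED_IGT", "IFG_IGT"), c(140, 114)),
#'              levels = levels(classify_glycemia(5, 5)))
#' derive_groups(cl)[["IGT_combined"]]  # 254
#' @export
derive_groups <- function(classes) {
  stopifnot(is.factor(classes))
  if (any(classes == "DIABETES", na.rm = TRUE)) {
    message("dropping ", sum(classes == "DIABETES", na.rm = TRUE),
            " diabetic subject(s) from group counts")
    classes <- classes[classes != "DIABETES"]
  }
  tab <- table(factor(classes, levels = c("NGT", "ISOLATED_IFG",
                                          "ISOLATED_IGT", "IFG_IGT")))
  out <- c(tab,
           IGT_combined = unname(tab[["ISOLATED_IGT"]] + tab[["IFG_IGT"]]),
           prediabetes = unname(tab[["ISOLATED_IFG"]] +
                                tab[["ISOLATED_IGT"]] + tab[["IFG_IGT"]]),
           total = sum(tab))
  stats::setNames(as.integer(out), names(out))
}
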