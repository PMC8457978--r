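# Stratified PRS-by-exposure analysis: each lifestyle/diet exposure is
# dichotomized at a registry cutoff, category odds ratios are estimated
# within each stratum, and the PRS-by-exposure interaction is tested by
# likelihood ratio in a pooled logistic model with an ordinal PRS term.

#' Registry of exposure dichotomization cutoffs
#'
#' Ships the cutoffs used by the emulated study's stratified analysis: age
#' 55 y, BMI 25 kg/m2, energy at 100% of the estimated requirement,
#' carbohydrate 70 En%, protein 13 En%, fat 15 En%, fiber 5 g/d, Ca
#' 500 mg/d, seaweed 2.65 g/d, vegetables 160 g/d, fruits 82 g/d, milk
#' 150 ml/d, DII score 10.0, coffee 3 cups/week, alcohol 20 g/d; dietary
#' patterns use the 75th percentile of the factor score (marked
#' `percentile75`, resolved against the data at run time). All values are
#' overridable: the registry is an ordinary data frame.
#'
#' @return data frame with columns exposure, cutoff, units, type
#'   (`"value"` or `"percentile75"`).
#' @export
default_exposure_cutoffs <- function() {
  data.frame(
    exposure = c("age", "bmi", "energy_pct_eer", "cho_en_pct",
                 "protein_en_pct", "fat_en_pct", "fiber_g", "ca_mg",
                 "seaweed_g", "vegetables_g", "fruits_g", "milk_ml",
                 "dii", "coffee_cups_wk", "alcohol_g"),
    cutoff = c(55, 25, 100, 70, 13, 15, 5, 500, 2.65, 160, 82, 150,
               10.0, 3, 20),
    units = c("years", "kg/m2", "% EER", "En%", "En%", "En%", "g/d",
              "mg/d", "g/d", "g/d", "g/d", "ml/d", "score", "cups/wk",
              "g/d"),
    type = "value",
    stringsAsFactors = FALSE)
}

#' Dichotomize an exposure at a cutoff
#'
#' Low means strictly below the cutoff (a value exactly at the cutoff is
#' high); missing values stay missing. Warns when every non-missing value
#' falls on one side (the other stratum would be empty).
#'
#' @param values numeric exposure vector.
#' @param cutoff the cutoff value.
#' @return factor with levels low/high.
#' @export
dichotomize <- function(values, cutoff) {
  stopifnot(is.finite(cutoff))
  lab <- ifelse(is.na(values), NA_character_,
                ifelse(values < cutoff, "low", "high"))
  f <- factor(lab, levels = c("low", "high"))
  tt <- table(f)
  if (any(tt == 0) && sum(tt) > 0) {
    warning("empty stratum after dichotomizing at ", cutoff, call. = FALSE)
  }
  f
}

#' Stratum-specific PRS category odds ratios
#'
#' Fits the PRS-category logistic model separately within each exposure
#' stratum (low-PRS reference). An empty stratum-by-category cell is
#' flagged and its OR omitted rather than failing the whole exposure.
#'
#' @param phenotype 0/1 case vector.
#' @param categories PRS category factor.
#' @param stratum factor from [dichotomize()].
#' @param covariates optional data frame.
#' @return data frame with columns stratum, category, or, ci_lo, ci_hi, p,
#'   n, note.
#' @export
stratified_ors <- function(phenotype, categories, stratum, covariates = NULL) {
  lev <- levels(stratum)
  present <- lev[lev %in% unique(stats::na.omit(as.character(stratum)))]
  if (length(present) < 2L) {
    warning("stratum labels constant: single OR set returned", call. = FALSE)
  }
  out <- list()
  for (s in present) {
    sel <- !is.na(stratum) & stratum == s
    res <- try(category_or_fit(phenotype[sel],
                               droplevels(categories[sel]),
                               if (!is.null(covariates))
                                 covariates[sel, , drop = FALSE]),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      out[[s]] <- data.frame(stratum = s, category = NA_character_,
                             or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                             p = NA_real_, n = sum(sel),
                             note = trimws(attr(res, "condition")$message),
                             stringsAsFactors = FALSE)
    } else {
      res$stratum <- s
      res$note <- ""
      missing_cat <- setdiff(levels(categories)[-1], res$category)
      if (length(missing_cat)) {
        res <- rbind(res, data.frame(
          category = missing_cat, or = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, p = NA_real_, n = sum(sel), stratum = s,
          note = "empty category in stratum", stringsAsFactors = FALSE))
      }
      out[[s]] <- res[, c("stratum", "category", "or", "ci_lo", "ci_hi",
                          "p", "n", "note")]
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Likelihood-ratio test of the PRS-by-exposure interaction
#'
#' Pooled logistic fit of case status on the ordinal PRS term (0/1/2 for
#' low/medium/high), the stratum indicator, their product and the
#' covariates; the P-value is the likelihood-ratio comparison against the
#' fit without the product term (1 df). The binary-outcome analogue of a
#' two-way covariate-adjusted interaction model, reported as the single
#' per-exposure interaction P.
#'
#' @param phenotype 0/1 case vector.
#' @param categories PRS category factor.
#' @param stratum factor from [dichotomize()].
#' @param covariates optional data frame.
#' @param exposure_name used in error messages.
#' @return list with `p` (LRT P), `lr_stat`, `beta_interaction`, `n`.
#' @export
interaction_pvalue <- function(phenotype, categories, stratum,
                               covariates = NULL, exposure_name = "exposure") {
  df <- data.frame(.y = phenotype,
                   .prs = as.numeric(categories) - 1,
                   .strat = as.numeric(stratum) - 1)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    df <- cbind(df, as.data.frame(covariates))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.strat)) < 2L || length(unique(df$.prs)) < 2L) {
    stop("interaction not estimable for ", exposure_name,
         ": constant PRS or stratum", call. = FALSE)
  }
  covs <- df[, setdiff(names(df), c(".y", ".prs", ".strat")), drop = FALSE]
  Xc <- if (ncol(covs)) stats::model.matrix(~ ., covs)[, -1, drop = FALSE] else NULL
  X0 <- cbind(`(Intercept)` = 1, prs = df$.prs, strat = df$.strat, Xc)
  X1 <- cbind(X0[, 1:3, drop = FALSE], prs_x_strat = df$.prs * df$.strat, Xc)
  f0 <- fit_logistic(X0, df$.y)
  f1 <- fit_logistic(X1, df$.y)
  if (!f0$converged || !f1$converged) {
    stop("interaction model did not converge for ", exposure_name, call. = FALSE)
  }
  lr <- max(0, f0$deviance - f1$deviance)
  list(p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       lr_stat = lr, beta_interaction = unname(f1$beta["prs_x_strat"]),
       n = nrow(df))
}

#' Full gene-environment interaction table
#'
#' Applies [dichotomize()], [stratified_ors()] and [interaction_pvalue()]
#' per exposure in the cutoff registry and assembles the stratified OR grid
#' with one interaction P per exposure. Exposures that fail (all-missing,
#' non-convergent) still produce rows, with the failure noted, so the table
#' shape matches the registry.
#'
#' @param phenotype 0/1 case vector.
#' @param categories PRS category factor.
#' @param exposures data frame of exposure values, columns named as in the
#'   registry.
#' @param cutoffs registry data frame, see [default_exposure_cutoffs()].
#' @param covariates optional data frame.
#' @return data frame: exposure, cutoff, stratum, category, or, ci_lo,
#'   ci_hi, p, n, interaction_p, note; row order follows the registry.
#' @export
interaction_table <- function(phenotype, categories, exposures,
                              cutoffs = default_exposure_cutoffs(),
                              covariates = NULL) {
  rows <- list()
  for (i in seq_len(nrow(cutoffs))) {
    ex <- cutoffs$exposure[i]
    vals <- exposures[[ex]]
    blank <- data.frame(exposure = ex, cutoff = cutoffs$cutoff[i],
                        stratum = NA_character_, category = NA_character_,
                        or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = NA_real_, n = 0L, interaction_p = NA_real_,
                        note = "", stringsAsFactors = FALSE)
    if (is.null(vals) || all(is.na(vals))) {
      blank$note <- "exposure missing"
      rows[[i]] <- blank
      next
    }
    cut <- cutoffs$cutoff[i]
    if (!is.na(cutoffs$type[i]) && cutoffs$type[i] == "percentile75") {
      cut <- stats::quantile(vals, 0.75, na.rm = TRUE, names = FALSE)
    }
    strat <- suppressWarnings(dichotomize(vals, cut))
    ors <- try(stratified_ors(phenotype, categories, strat, covariates),
               silent = TRUE)
    ip <- try(interaction_pvalue(phenotype, categories, strat, covariates,
                                 exposure_name = ex), silent = TRUE)
    if (inherits(ors, "try-error")) {
      blank$note <- trimws(attr(ors, "condition")$message)
      rows[[i]] <- blank
      next
    }
    ors$exposure <- ex
    ors$cutoff <- cut
    ors$interaction_p <- if (inherits(ip, "try-error")) NA_real_ else ip$p
    if (inherits(ip, "try-error")) {
      ors$note <- paste0(ors$note, "; interaction: ",
                         trimws(attr(ip, "condition")$message))
    }
    rows[[i]] <- ors[, names(blank)]
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
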