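## Tillering-index construction and genotype-phenotype association:
## a univariate split-plot (repeated-measures) ANOVA with genotype as
## the between-subject factor tested against subject-within-genotype,
## and a one-way ANOVA for the independent control trait (culm
## diameter). Half-call genotypes carry no diploid class and are
## excluded from association.

.MEASUREMENT_DAYS <- c(15, 20, 25, 30, 35, 40, 50, 60)

#' Tillering index
#'
#' Ratio of the sum of tiller lengths to plant height; 0 for an
#' untillered plant.
#'
#' @param tillerLengths Numeric vector of tiller lengths (cm),
#'   \code{>= 0}; may be empty.
#' @param plantHeight Plant height (cm), \code{> 0}.
#' @return Numeric ratio.
#' @examples
#' tilleringIndex(c(10, 20, 30), 60)  # 1
#' @export
tilleringIndex <- function(tillerLengths, plantHeight) {
  if (length(plantHeight) != 1L || is.na(plantHeight) ||
      plantHeight <= 0)
    stop("plant height must be a single value > 0")
  if (any(tillerLengths < 0)) stop("tiller lengths must be >= 0")
  if (length(tillerLengths) == 0L) return(0)
  sum(tillerLengths) / plantHeight
}

#' Box-Cox power transform
#'
#' \eqn{\lambda = 0}: \eqn{\ln(y + \mathrm{offset})}; otherwise
#' \eqn{((y + \mathrm{offset})^\lambda - 1)/\lambda}. Monotone in y.
#' The default offset of 1 makes the log transform defined for the
#' zero tillering index of untillered plants.
#'
#' @param values Numeric vector.
#' @param lambda Power exponent (default 0 = log).
#' @param offset Shift added before transforming (default 1).
#' @return Transformed numeric vector.
#' @export
boxcoxTransform <- function(values, lambda = 0, offset = 1) {
  y <- values + offset
  bad <- which(y <= 0)
  if (length(bad))
    stop("nonpositive shifted value at index: ",
         paste(bad, collapse = ", "))
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' Association analysis configuration
#'
#' @param boxcoxLambda Box-Cox exponent (default 0 = log).
#' @param boxcoxOffset Shift added before the transform (default 1).
#' @param alpha Significance level (default 0.05).
#' @param measurementDays Allowed measurement schedule.
#' @return List of settings for \code{\link{repeatedMeasuresAnova}}.
#' @export
assocConfig <- function(boxcoxLambda = 0, boxcoxOffset = 1,
                        alpha = 0.05,
                        measurementDays = .MEASUREMENT_DAYS) {
  if (boxcoxLambda == 0 && boxcoxOffset <= 0)
    stop("offset must be > 0 when lambda = 0 and responses may be 0")
  list(boxcox_lambda = boxcoxLambda, boxcox_offset = boxcoxOffset,
       alpha = alpha, measurement_days = measurementDays)
}

## long-format analysis frame: one row per plant x day with the
## response, full-diploid genotypes only
.assocFrame <- function(pt, response, config) {
  df <- phenotypeRecords(pt)
  df <- df[df$genotype_call %in% c("HH", "Hh", "hh"), , drop = FALSE]
  if (nrow(df) == 0L) stop("no plants with a full diploid genotype")
  offSchedule <- !df$day %in% config$measurement_days
  if (any(offSchedule)) {
    message("dropping ", sum(offSchedule),
            " record(s) off the measurement schedule")
    df <- df[!offSchedule, , drop = FALSE]
  }
  resp <- switch(response,
    tillering_index = {
      tl <- parseTillerLengths(df$tiller_lengths)
      mapply(tilleringIndex, tl, df$plant_height)
    },
    tiller_number = df$tiller_number,
    stop("unknown response: ", response))
  droplevels(data.frame(plant = factor(df$plant_id),
                        genotype = factor(df$genotype_call,
                                          levels = c("hh", "Hh", "HH")),
                        day = factor(df$day),
                        y = boxcoxTransform(resp, config$boxcox_lambda,
                                            config$boxcox_offset)))
}

#' Repeated-measures (split-plot) ANOVA of genotype on a longitudinal
#' response
#'
#' Univariate split-plot decomposition with between-subject factor
#' genotype (hh / Hh / HH), within-subject factor day and their
#' interaction. The genotype F-test uses subject-within-genotype as its
#' error stratum; day and genotype x day are tested against the
#' within-subject residual. Genotype is the only term in its stratum,
#' so its sum of squares is unambiguous under unbalanced group sizes.
#' Plants with missing time points are dropped listwise (with a
#' message); no sphericity correction is applied.
#'
#' @param pt A \linkS4class{PhenotypeTable}.
#' @param response \code{"tillering_index"} or \code{"tiller_number"}.
#' @param config Settings from \code{\link{assocConfig}}.
#' @return Data.frame ANOVA table with rows \code{genotype},
#'   \code{subject_within_genotype}, \code{day}, \code{genotype:day}
#'   and \code{residual}: columns \code{ss}, \code{df}, \code{ms},
#'   \code{F}, \code{p}.
#' @export
repeatedMeasuresAnova <- function(pt, response = "tillering_index",
                                  config = assocConfig()) {
  stopifnot(is(pt, "PhenotypeTable"))
  long <- .assocFrame(pt, response, config)
  nDays <- length(unique(long$day))
  perPlant <- table(long$plant)
  if (any(perPlant < 2L))
    stop("every plant needs >= 2 time points")
  incomplete <- names(perPlant)[perPlant < nDays]
  if (length(incomplete)) {
    message("dropping ", length(incomplete),
            " plant(s) with missing time points")
    long <- droplevels(long[!long$plant %in% incomplete, ,
                            drop = FALSE])
  }
  plantsPerGeno <- rowSums(table(long$genotype, long$plant) > 0)
  if (any(plantsPerGeno < 2L))
    stop("each genotype class needs >= 2 plants (counts: ",
         paste(plantsPerGeno, collapse = "/"), ")")
  fit <- stats::aov(y ~ genotype * day + Error(plant), data = long)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: plant"]][[1L]])
  within <- as.data.frame(sm[["Error: Within"]][[1L]])
  rn <- function(df) trimws(rownames(df))
  b <- between[match(c("genotype", "Residuals"), rn(between)), ]
  w <- within[match(c("day", "genotype:day", "Residuals"),
                    rn(within)), ]
  out <- data.frame(
    effect = c("genotype", "subject_within_genotype", "day",
               "genotype:day", "residual"),
    ss = c(b[["Sum Sq"]], w[["Sum Sq"]]),
    df = c(b[["Df"]], w[["Df"]]),
    ms = c(b[["Mean Sq"]], w[["Mean Sq"]]),
    F = c(b[["F value"]], w[["F value"]]),
    p = c(b[["Pr(>F)"]], w[["Pr(>F)"]]))
  rownames(out) <- out$effect
  out
}

#' One-way ANOVA
#'
#' Standard one-way decomposition (used for the culm-diameter control
#' trait versus genotype).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @return List with \code{F}, \code{p}, \code{df_between},
#'   \code{df_within}, \code{ss_between}, \code{ss_within}.
#' @export
onewayAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 observations")
  tab <- stats::anova(stats::lm(values ~ groups))
  list(F = tab$`F value`[1L], p = tab$`Pr(>F)`[1L],
       df_between = tab$Df[1L], df_within = tab$Df[2L],
       ss_between = tab$`Sum Sq`[1L], ss_within = tab$`Sum Sq`[2L])
}
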