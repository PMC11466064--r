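# Percent maximal possible effect (%MPE) on withdrawal-threshold series:
# 0% at the post-injury (predrug) baseline, 100% at full reversal to the
# pre-injury baseline. No clipping is applied: values above 100% or below
# 0% are meaningful (overshoot / worsening) and clipping would bias means.

#' Percent maximal possible effect
#'
#' \eqn{\%MPE(t) = 100 (E(t) - E_{predrug}) / (E_{preCCI} - E_{predrug})},
#' where \eqn{E(t)} is the withdrawal threshold at time t,
#' \eqn{E_{predrug}} the post-injury pre-drug baseline and
#' \eqn{E_{preCCI}} the pre-injury baseline. Vectorized over \code{et}.
#'
#' @param et threshold(s) at the evaluated time point(s), grams.
#' @param ePredrug post-injury, pre-drug threshold, grams.
#' @param ePreCCI pre-injury baseline threshold, grams.
#' @return Percent MPE (may exceed 100 or be negative; never clipped).
#' @examples
#' computeMPE(4, ePredrug = 2, ePreCCI = 6)  # 50
#' @export
computeMPE <- function(et, ePredrug, ePreCCI) {
  den <- ePreCCI - ePredrug
  if (any(den == 0))
    stop("ePreCCI equals ePredrug: no sensitization to reverse (zero denominator)")
  # ratio first so the 0% and 100% identities are exact in floating point
  100 * ((et - ePredrug) / den)
}

checkBehaviorTable <- function(cohort) {
  need <- c("animal_id", "time_h", "threshold_g", "e_predrug_g", "e_precci_g")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("behavior table lacks columns: ", paste(miss, collapse = ", "))
  invisible(cohort)
}

#' Per-animal %MPE at every measured time point
#'
#' @param cohort long-format behavior table with columns \code{animal_id},
#'   \code{time_h}, \code{threshold_g}, \code{e_predrug_g},
#'   \code{e_precci_g} (and any grouping columns, which are carried along).
#' @return The table with an added \code{mpe} column.
#' @export
mpeTable <- function(cohort) {
  checkBehaviorTable(cohort)
  cohort$mpe <- computeMPE(cohort$threshold_g, cohort$e_predrug_g,
                           cohort$e_precci_g)
  cohort
}

#' Windowed mean %MPE per animal
#'
#' Arithmetic mean of per-time-point %MPE over the requested window,
#' computed per animal (the per-animal-then-average reading of windowed
#' effect summaries). The default window averages the 0.5 h and 1 h time
#' points, the usual peak-effect window for intrathecal modulators.
#'
#' @param cohort behavior table (see \code{\link{mpeTable}}).
#' @param timepoints numeric time points (h) to average; all must be present
#'   for every animal.
#' @return data.frame with one row per animal: \code{animal_id}, any
#'   constant grouping columns (\code{group}, \code{genotype},
#'   \code{treatment}, \code{sex} if present), \code{mpe_window}.
#' @export
windowMeanMPE <- function(cohort, timepoints = c(0.5, 1)) {
  m <- mpeTable(cohort)
  out <- lapply(split(m, m$animal_id), function(a) {
    missing <- setdiff(timepoints, a$time_h)
    if (length(missing))
      stop("animal ", a$animal_id[1], " lacks time point(s): ",
           paste(missing, collapse = ", "))
    sel <- a[a$time_h %in% timepoints, ]
    row <- data.frame(animal_id = a$animal_id[1],
                      mpe_window = mean(sel$mpe))
    for (gc in intersect(c("group", "genotype", "treatment", "sex"),
                         names(a)))
      row[[gc]] <- a[[gc]][1]
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare windowed %MPE between two cohorts
#'
#' Group means and SEMs of per-animal window means with an unpaired
#' two-sided t test (see \code{\link{compareGroups}}).
#'
#' @param cohortA,cohortB behavior tables for the two groups (>= 2 animals
#'   each).
#' @param timepoints window time points in hours.
#' @param labels group labels, cohortA first.
#' @return A \linkS4class{GroupComparison} of windowed mean %MPE.
#' @export
compareMPEGroups <- function(cohortA, cohortB, timepoints = c(0.5, 1),
                             labels = c("groupA", "groupB")) {
  wa <- windowMeanMPE(cohortA, timepoints)
  wb <- windowMeanMPE(cohortB, timepoints)
  compareGroups(wa$mpe_window, wb$mpe_window,
                measure = "window_mean_mpe_percent", labels = labels)
}
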