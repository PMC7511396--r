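#' Partition ATP production into OXPHOS and glycolysis from an inhibitor plate
#'
#' Untreated wells define 100%; with condition means U (untreated),
#' O (oligomycin, OXPHOS inhibited), D (2-deoxyglucose, glycolysis
#' inhibited) and B (both inhibitors):
#' \deqn{\%OXPHOS = 100 (U - O) / U, \quad \%glycolysis = 100 (U - D) / U,
#'   \quad residual = 100 B / U.}
#' Condition means are plain arithmetic means of wells (no outlier
#' rejection; set `robust = TRUE` for medians). Missing conditions yield
#' `NA` fields, never zero. Negative inhibition (inhibited mean above
#' untreated) is reported as a negative percentage with a warning, not
#' clipped. The three percentages need not add to 100; deviations beyond 10
#' points are flagged, never corrected.
#'
#' @param plate an `atp_plate` (or any data.frame with condition and
#'   luminescence columns).
#' @param robust use medians instead of means.
#' @return object of class `metabolic_partition`: list with pct_oxphos,
#'   pct_glycolysis, pct_residual_both, untreated_mean, n per condition and
#'   a `flags` character vector.
#' @export
atp_partition <- function(plate, robust = FALSE) {
  stopifnot(all(c("condition", "luminescence") %in% names(plate)))
  if (any(plate$luminescence < 0)) stop("luminescence must be >= 0")
  est <- if (robust) stats::median else mean
  means <- tapply(plate$luminescence, plate$condition, est)
  if (!"untreated" %in% names(means))
    stop("no untreated wells: the partition is undefined")
  U <- unname(means[["untreated"]])
  if (U <= 0) stop("untreated mean must be > 0 (got ", U, ")")
  g <- function(cond) if (cond %in% names(means)) unname(means[[cond]])
       else NA_real_
  O <- g("oligomycin"); D <- g("2DG"); B <- g("both")
  res <- list(
    pct_oxphos = 100 * (U - O) / U,
    pct_glycolysis = 100 * (U - D) / U,
    pct_residual_both = 100 * B / U,
    untreated_mean = U,
    n = table(plate$condition),
    flags = character(0)
  )
  neg <- c(oxphos = isTRUE(res$pct_oxphos < 0),
           glycolysis = isTRUE(res$pct_glycolysis < 0))
  if (any(neg)) {
    warning("negative inhibition (treated mean above untreated) for: ",
            paste(names(neg)[neg], collapse = ", "))
    res$flags <- c(res$flags, paste0("negative_", names(neg)[neg]))
  }
  total <- res$pct_oxphos + res$pct_glycolysis + res$pct_residual_both
  if (is.finite(total) && abs(total - 100) > 10)
    res$flags <- c(res$flags, sprintf("components_sum_%.1f", total))
  class(res) <- "metabolic_partition"
  res
}

#' @export
print.metabolic_partition <- function(x, ...) {
  cat(sprintf(
    "ATP partition: %%OXPHOS = %.1f, %%glycolysis = %.1f, residual(both) = %.1f (untreated mean %.3g)\n",
    x$pct_oxphos, x$pct_glycolysis, x$pct_residual_both, x$untreated_mean))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize cellular ATP levels to the control group (percent of control)
#'
#' Group means are scaled so the control mean is 100; each group's SD is
#' propagated on the same scale (SD x 100 / control mean).
#'
#' @param values numeric well/luminescence values (untreated wells).
#' @param groups group labels, same length.
#' @param control_group label of the reference group.
#' @return data.frame: group, pct_mean, pct_sd, n; control row has
#'   pct_mean = 100 by construction.
#' @export
normalize_atp <- function(values, groups, control_group = "control") {
  if (!control_group %in% groups)
    stop("control group not present: ", control_group)
  cm <- mean(values[groups == control_group])
  if (!is.finite(cm) || cm <= 0)
    stop("control mean must be > 0 to normalize (got ", cm, ")")
  gs <- unique(groups)
  data.frame(
    group = gs,
    pct_mean = vapply(gs, function(g) 100 * mean(values[groups == g]) / cm,
                      numeric(1)),
    pct_sd = vapply(gs, function(g) 100 * stats::sd(values[groups == g]) / cm,
                    numeric(1)),
    n = vapply(gs, function(g) sum(groups == g), integer(1)),
    row.names = NULL
  )
}

#' Metabolic-switch time-course from per-day partitions
#'
#' Orders per-day partitions and reports the first day at which
#' %OXPHOS exceeds %glycolysis (the metabolic switch from glycolysis to
#' oxidative phosphorylation during neuronal differentiation).
#'
#' @param partitions a data.frame with columns day, pct_oxphos,
#'   pct_glycolysis (one row per timepoint), or a named list of
#'   `metabolic_partition` objects keyed by day.
#' @return list with `table` (day-ordered partitions) and `switch_day`
#'   (`NA` when no switch occurs).
#' @export
metabolic_switch_timecourse <- function(partitions) {
  if (!is.data.frame(partitions)) {
    partitions <- do.call(rbind, lapply(names(partitions), function(d) {
      p <- partitions[[d]]
      data.frame(day = as.numeric(d), pct_oxphos = p$pct_oxphos,
                 pct_glycolysis = p$pct_glycolysis,
                 pct_residual_both = p$pct_residual_both)
    }))
  }
  stopifnot(all(c("day", "pct_oxphos", "pct_glycolysis") %in%
                  names(partitions)))
  if (nrow(partitions) < 2)
    stop("a switch time-course needs at least 2 timepoints")
  if (is.unsorted(partitions$day)) {
    warning("timepoints were not in day order; sorting")
    partitions <- partitions[order(partitions$day), , drop = FALSE]
  }
  over <- which(partitions$pct_oxphos > partitions$pct_glycolysis)
  list(table = partitions,
       switch_day = if (length(over)) partitions$day[min(over)] else NA_real_)
}
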