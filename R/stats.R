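#' Two-way fixed-effects ANOVA with Sidak or Tukey contrasts
#'
#' Standard two-factor decomposition (genotype x timepoint with
#' interaction), followed by genotype contrasts within each timepoint.
#' Sidak adjustment is `1 - (1 - p)^k` over the `k` reported contrasts;
#' Tukey uses the studentized-range distribution via `emmeans`. The unit of
#' replication is whatever one row represents — average cells to one value
#' per differentiation round before calling this, to match the reported n
#' and avoid pseudoreplication.
#'
#' @param data data.frame with columns `value`, `genotype`, `timepoint`.
#' @param correction "sidak" or "tukey".
#' @return list: `anova_table` (factor, df, F, p), `contrasts` (timepoint,
#'   contrast, estimate, p_raw, p_adj), `correction`, `fit`.
#' @export
two_way_anova <- function(data, correction = c("sidak", "tukey")) {
  correction <- match.arg(correction)
  stopifnot(all(c("value", "genotype", "timepoint") %in% names(data)))
  data$genotype <- factor(data$genotype)
  data$timepoint <- factor(data$timepoint)
  if (nlevels(data$genotype) < 2 || nlevels(data$timepoint) < 2)
    stop("both factors need at least 2 levels")
  tab <- table(data$genotype, data$timepoint)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: genotype ", rownames(tab)[miss[1]],
         " x timepoint ", colnames(tab)[miss[2]])
  }
  if (any(tab < 2))
    stop("each design cell needs at least 2 replicates")
  fit <- stats::aov(value ~ genotype * timepoint, data = data)
  s <- summary(fit)[[1]]
  anova_table <- data.frame(
    factor = trimws(rownames(s)),
    df = s$Df, F = s$`F value`, p = s$`Pr(>F)`,
    row.names = NULL
  )
  emm <- emmeans::emmeans(fit, ~ genotype | timepoint)
  raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  if (correction == "sidak") {
    k <- nrow(raw)
    p_adj <- 1 - (1 - raw$p.value)^k
  } else {
    adj <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
    p_adj <- adj$p.value
  }
  contrasts <- data.frame(timepoint = raw$timepoint, contrast = raw$contrast,
                          estimate = raw$estimate, p_raw = raw$p.value,
                          p_adj = pmin(p_adj, 1))
  list(anova_table = anova_table, contrasts = contrasts,
       correction = correction, fit = fit)
}

#' Repeated-measures ANOVA across all time points
#'
#' Mixed design: genotype between subjects, time within subjects (subject =
#' replicate differentiation round). The genotype main effect is tested in
#' the between-subject stratum against subject-within-genotype variation —
#' the "ANOVA repeated measures across all time points" comparison used for
#' mitophagy time-courses.
#'
#' @param data data.frame with columns `value`, `genotype`, `time`,
#'   `subject` (subject ids must be unique across genotypes).
#' @return list: `strata` (stratum, factor, df, F, p), `genotype_p`, `fit`.
#' @export
repeated_measures_anova <- function(data) {
  stopifnot(all(c("value", "genotype", "time", "subject") %in% names(data)))
  data$genotype <- factor(data$genotype)
  data$time <- factor(data$time)
  data$subject <- factor(data$subject)
  by_gt <- split(data$time, data$genotype)
  frames <- lapply(by_gt, function(t) sort(unique(as.character(t))))
  if (length(unique(vapply(frames, paste, character(1), collapse = ","))) > 1)
    stop("groups must share the same time points")
  subj_per_g <- tapply(data$subject, data$genotype,
                       function(s) length(unique(s)))
  if (any(subj_per_g < 2))
    stop("each genotype needs at least 2 subjects (replicate rounds)")
  cross <- table(data$subject, data$genotype)
  if (any(rowSums(cross > 0) > 1))
    stop("subject ids must be unique to one genotype")
  fit <- stats::aov(value ~ genotype * time + Error(subject / time),
                    data = data)
  s <- summary(fit)
  strata <- do.call(rbind, lapply(names(s), function(nm) {
    t1 <- s[[nm]][[1]]
    data.frame(stratum = nm, factor = trimws(rownames(t1)), df = t1$Df,
               F = t1$`F value`, p = t1$`Pr(>F)`, row.names = NULL)
  }))
  gp <- strata$p[strata$stratum == "Error: subject" &
                   strata$factor == "genotype"]
  list(strata = strata,
       genotype_p = if (length(gp)) gp else NA_real_,
       fit = fit)
}
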