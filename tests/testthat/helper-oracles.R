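# shared statistical oracles: brute-force sums of squares for the
# balanced two-factor design

balanced_design <- function(shift = 0, seed = 1, reps = 4) {
  set.seed(seed)
  d <- expand.grid(genotype = c("control", "PRKN"),
                   timepoint = c("d12", "d17", "d27"), rep = seq_len(reps))
  d$value <- rnorm(nrow(d), sd = 1) + ifelse(d$genotype == "PRKN", shift, 0)
  d
}

# brute-force two-way ANOVA sums of squares for a balanced design
ss_oracle <- function(d) {
  gm <- mean(d$value)
  ga <- tapply(d$value, d$genotype, mean)
  gb <- tapply(d$value, d$timepoint, mean)
  gab <- tapply(d$value, list(d$genotype, d$timepoint), mean)
  n_a <- table(d$genotype)[1]; n_b <- table(d$timepoint)[1]
  n_ab <- table(d$genotype, d$timepoint)[1, 1]
  ss_a <- sum(n_a * (ga - gm)^2)
  ss_b <- sum(n_b * (gb - gm)^2)
  ss_ab <- n_ab * sum((sweep(sweep(gab, 1, ga), 2, gb) + gm)^2)
  cell_mean <- gab[cbind(as.character(d$genotype), as.character(d$timepoint))]
  ss_e <- sum((d$value - cell_mean)^2)
  df_a <- nlevels(factor(d$genotype)) - 1
  df_b <- nlevels(factor(d$timepoint)) - 1
  df_ab <- df_a * df_b
  df_e <- nrow(d) - nlevels(factor(d$genotype)) * nlevels(factor(d$timepoint))
  c(F_a = (ss_a / df_a) / (ss_e / df_e),
    F_b = (ss_b / df_b) / (ss_e / df_e),
    F_ab = (ss_ab / df_ab) / (ss_e / df_e))
}
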