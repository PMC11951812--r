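# Independent rank-formula oracles, coded from the textbook definitions
# (rank sums with tie correction), kept separate from the package path.

kw_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  n_tot <- length(values)
  r <- rank(values)
  rank_sums <- tapply(r, groups, sum)
  n_g <- tapply(r, groups, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rank_sums^2 / n_g) - 3 * (n_tot + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n_tot^3 - n_tot))
}

dunn_oracle <- function(values, groups, i, j) {
  groups <- as.factor(groups)
  n_tot <- length(values)
  r <- rank(values)
  ties <- table(values)
  v <- n_tot * (n_tot + 1) / 12 - sum(ties^3 - ties) / (12 * (n_tot - 1))
  mri <- mean(r[groups == i]); mrj <- mean(r[groups == j])
  (mri - mrj) / sqrt(v * (1 / sum(groups == i) + 1 / sum(groups == j)))
}
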