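# Brute-force AMOVA oracle: direct nested sums-of-squares decomposition on
# the 2N allele indicators (alleles within individuals within populations),
# written independently of the package's estimator and frozen before it.
# Returns c(a, b, c) variance components; NA when undefined.
oracle_amova_components <- function(dos, grp) {
  ok <- !is.na(dos)
  dos <- dos[ok]
  grp <- factor(grp[ok])
  grp <- droplevels(grp)
  if (nlevels(grp) < 2) return(c(NA_real_, NA_real_, NA_real_))
  y <- unlist(lapply(dos, function(d)
    if (d == 0) c(0, 0) else if (d == 1) c(1, 0) else c(1, 1)))
  ind <- rep(seq_along(dos), each = 2)
  pop <- rep(as.integer(grp), each = 2)
  r <- nlevels(grp)
  n_ind <- length(dos)
  if (n_ind <= r) return(c(NA_real_, NA_real_, NA_real_))
  ybar <- mean(y)
  pop_means <- tapply(y, pop, mean)
  pop_n <- tapply(y, pop, length)
  ind_means <- tapply(y, ind, mean)
  ind_pop <- tapply(pop, ind, function(p) p[1])
  ss_pop <- sum(pop_n * (pop_means - ybar)^2)
  ss_ind <- sum(2 * (ind_means - pop_means[as.character(ind_pop)])^2)
  ss_wi <- sum((y - ind_means[as.character(ind)])^2)
  ms_a <- ss_pop / (r - 1)
  ms_b <- ss_ind / (n_ind - r)
  ms_c <- ss_wi / n_ind
  ni <- as.numeric(table(grp))
  nc <- (n_ind - sum(ni^2) / n_ind) / (r - 1)
  c(a = (ms_a - ms_b) / (2 * nc), b = (ms_b - ms_c) / 2, c = ms_c)
}

oracle_amova_phi <- function(dos, grp) {
  comp <- oracle_amova_components(dos, grp)
  tot <- sum(comp)
  if (is.na(tot) || tot == 0) return(NA_real_)
  comp[[1]] / tot
}
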