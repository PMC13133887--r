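# Shared fixtures and independent oracles for the test suite.

# Brute-force box-count oracle: explicit loop over every grid box, summing the
# sub-array directly. Deliberately independent of the coordinate-division
# implementation in box_counts().
oracle_box_counts <- function(mask, box_sizes) {
  d <- dim(mask)
  lapply(box_sizes, function(eps) {
    starts <- expand.grid(i = seq(1, d[1], by = eps),
                          j = seq(1, d[2], by = eps),
                          k = seq(1, d[3], by = eps))
    masses <- vapply(seq_len(nrow(starts)), function(r) {
      i <- starts$i[r]; j <- starts$j[r]; k <- starts$k[r]
      sum(mask[i:min(i + eps - 1, d[1]),
               j:min(j + eps - 1, d[2]),
               k:min(k + eps - 1, d[3])])
    }, numeric(1))
    masses[masses > 0]
  })
}

# Two independent log-log regressions via stats::lm on oracle counts.
oracle_multifractal_range <- function(box_sizes, counts) {
  k <- length(box_sizes)
  x <- log(1 / box_sizes); y <- log(counts)
  lo <- seq_len(ceiling(k / 2))
  hi <- (k - ceiling(k / 2) + 1):k
  s_lo <- unname(coef(stats::lm(y[lo] ~ x[lo]))[2])
  s_hi <- unname(coef(stats::lm(y[hi] ~ x[hi]))[2])
  abs(s_lo - s_hi)
}

random_mask <- function(dims, density, seed) {
  set.seed(seed)
  array(as.integer(runif(prod(dims)) < density), dim = dims)
}

# Two-column cohort with an exact sample Spearman/Pearson correlation target
# is fiddly; instead build two columns with exact Pearson r via Gram-Schmidt.
correlated_pair <- function(n, r, seed) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1 <- (z1 - mean(z1)) / sd(z1)
  z2 <- resid(lm(z2 ~ z1))
  z2 <- (z2 - mean(z2)) / sd(z2)
  data.frame(x1 = z1, x2 = r * z1 + sqrt(1 - r^2) * z2)
}

# Minimal subject record satisfying the IDF labelling inputs.
base_record <- function(...) {
  rec <- list(sex = "male", waist_cm = 80, bmi = 24, triglyceride = 1.0,
              hdl_c = 1.5, diabetes = 0, hypertension = 0)
  mod <- list(...)
  rec[names(mod)] <- mod
  rec
}
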