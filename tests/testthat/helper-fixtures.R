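# Shared fixture builders and independent oracles used across the suite.

# A tiny genotype panel with fully controllable dosages.
toy_geno <- function(dosages, chrom = NULL, pos = NULL, ea = NULL, oa = NULL,
                     eaf = NULL, info = NULL) {
  dosages <- as.matrix(dosages)
  nv <- ncol(dosages)
  geno_matrix(
    dosages = dosages,
    sample_ids = sprintf("s%02d", seq_len(nrow(dosages))),
    variants = tibble::tibble(
      chrom = chrom %||% rep(1L, nv),
      pos = pos %||% seq(1000L, by = 1000L, length.out = nv),
      ea = ea %||% rep("A", nv),
      oa = oa %||% rep("G", nv),
      eaf = eaf %||% (colMeans(dosages) / 2),
      info = info %||% rep(1, nv)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal cohort tibble for Cox toys: one numeric covariate mapped onto
# the `bmi` block of an adult spec.
toy_cohort <- function(time, event, x) {
  tibble::tibble(
    id = sprintf("p%03d", seq_along(time)),
    cohort = "adult", baseline_age = 40, sex = "F",
    followup_time = time, event = event, bmi = x,
    fpg = 5, hba1c = 30, twohpg = 6,
    mother_diab = "no", father_diab = "no", birthweight_g = NA_real_
  )
}

# Exhaustive pair-enumeration oracle for Harrell's C under censoring.
harrell_brute <- function(time, event, score) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ti <- time[i]; tj <- time[j]; ei <- event[i]; ej <- event[j]
      usable <- (ti < tj && ei == 1) || (tj < ti && ej == 1) ||
        (ti == tj && ei != ej)
      if (!usable) next
      worse <- if (ti < tj || (ti == tj && ei == 1)) i else j
      other <- if (worse == i) j else i
      den <- den + 1
      if (score[worse] > score[other]) num <- num + 1
      else if (score[worse] == score[other]) num <- num + 0.5
    }
  }
  c(c = num / den, usable = den)
}

# Brute-force Cox partial likelihood for one covariate (no ties assumed).
cox_pl_brute <- function(time, event, x) {
  negll <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    -ll
  }
  stats::optimize(negll, c(-8, 8))$minimum
}

# Hand Kaplan-Meier complement at a horizon (product-limit, loop form).
km_brute <- function(time, event, horizon) {
  s <- 1
  for (t in sort(unique(time[event == 1 & time <= horizon]))) {
    d <- sum(event == 1 & time == t)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  1 - s
}
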