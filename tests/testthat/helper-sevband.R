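# Shared test helpers: independent band oracle, random scheme generator,
# and compact observation builders.

# Brute-force band assignment by linear scan over the five explicit
# intervals [0,b0], (b0,b1], (b1,b2], (b2,b3], (b3,Inf). Independent of
# findInterval-based production code.
oracle_band <- function(dev, boundaries) {
  lower <- c(0, boundaries)
  upper <- c(boundaries, Inf)
  vapply(dev, function(d) {
    for (k in 0:4) {
      lo <- lower[k + 1]
      hi <- upper[k + 1]
      inside <- if (k == 0) d >= 0 && d <= hi else d > lo && d <= hi
      if (inside) return(k)
    }
    stop("no band contains deviation ", d)
  }, numeric(1))
}

random_band_scheme <- function() {
  b <- sort(round(runif(4, 0, 50), 3))
  while (any(diff(b) <= 0)) b <- sort(round(runif(4, 0, 50), 3))
  band_scheme(b,
              sample(c("absolute", "percent"), 1),
              sample(c("increase", "decrease", "either"), 1))
}

# One-timepoint observation tibble from named per-animal values.
make_obs <- function(values, criterion, group = "g1", timepoint = "t1",
                     status = "alive", study = "s1", phase = "p1") {
  tibble::tibble(
    study_id = study, phase_id = phase, group_id = group,
    animal_id = names(values), timepoint = timepoint,
    criterion = criterion, value = unname(values), status = status
  )
}

make_baselines <- function(animals, criterion, baseline) {
  tibble::tibble(animal_id = animals, criterion = criterion,
                 baseline_value = baseline)
}

# Scores placed directly in band k for a given criterion scheme via
# midpoint deviations, so tests can construct exact score columns.
values_for_bands <- function(bands_obj, band, baseline) {
  b <- bands_obj$boundaries
  lower <- c(0, b)[band + 1]
  upper <- c(b, NA)[band + 1]
  dev <- ifelse(band == 4, 1.5 * b[4], (lower + upper) / 2)
  delta <- if (bands_obj$deviation_kind == "percent") dev / 100 * baseline else dev
  if (bands_obj$direction == "decrease") baseline - delta else baseline + delta
}
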