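# Shared fixtures: a 10-Mb study chromosome with a 2-Mb central
# zero-recombination satellite zone and 100-kb unmarked telomeric caps.
study_landscape <- function(chrom_length = 1e7, total_cm = 20,
                            zone = c(4e6, 6e6)) {
  recombination_landscape(
    chrom_length,
    breakpoints = c(1e5, zone[1], zone[2], chrom_length - 1e5),
    rates = c(0, 1, 0, 1, 0),
    total_cm = total_cm, zero_zone = zone)
}

# zone-delineation landscape: 12 Mb, 2.5-Mb zero zone, 1.5-Mb flanks of
# suppressed recombination accumulating ~1.2 cM each
zone_landscape <- function() {
  recombination_landscape(
    12e6,
    breakpoints = c(1e5, 3.3e6, 4.8e6, 7.3e6, 8.8e6, 11.9e6),
    rates = c(0, 3.8, 0.8, 0, 0.8, 3.8, 0),
    total_cm = 3.8 * (3.2 + 3.1) + 0.8 * (1.5 + 1.5),
    zero_zone = c(4.8e6, 7.3e6))
}

# match each true crossover to a retained call of the same sample whose
# interval (optionally expanded by `slack` bp) contains the true position
recovery_stats <- function(calls, truth, slack = 0) {
  hit <- mapply(function(s, x) {
    any(calls$sample == s & calls$start - slack <= x &
          x < calls$end + slack)
  }, truth$sample, truth$pos)
  correct <- if (nrow(calls) == 0) logical(0) else
    mapply(function(s, a, b) {
      any(truth$sample == s & truth$pos >= a - slack & truth$pos < b + slack)
    }, calls$sample, calls$start, calls$end)
  list(sensitivity = mean(hit), precision = mean(correct),
       n_true = nrow(truth), n_calls = nrow(calls))
}
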