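# Shared fixtures: the standard screening configuration and an independent
# brute-force oracle for the overlap bounds.

std_cohort <- function(size = NULL) cohort(0.0146, size)
std_timing <- function() protocol_timing(262, 776)
std_rad <- function() operating_point(0.90, 0.92)
std_ai <- function() operating_point(0.80, 0.80)

# Brute-force overlap oracle: per disease stratum, scan all candidate joint
# "both flag" cells on a fine grid, keep those yielding a valid 2x2 table
# (all four cells non-negative), and take the extremes. Deliberately knows
# nothing about Frechet bounds.
oracle_overlap_bounds <- function(rad_op, ai_op, prevalence, step = 1e-4) {
  stratum <- function(p_rad, p_ai) {
    cand <- seq(0, 1, by = step)
    ok <- cand <= p_rad + step & cand <= p_ai + step &
      (1 - p_rad - p_ai + cand) >= -step
    c(min = min(cand[ok]), max = max(cand[ok]))
  }
  d <- stratum(rad_op$sensitivity, ai_op$sensitivity)
  h <- stratum(1 - rad_op$specificity, 1 - ai_op$specificity)
  p <- prevalence
  list(minimum = p * d[["min"]] + (1 - p) * h[["min"]],
       maximum = p * d[["max"]] + (1 - p) * h[["max"]])
}

flag_rate_of <- function(cr) cr$tp + cr$fp

# Random operating points on a fixed-seed grid for property-style tests.
random_operating_points <- function(n, seed) {
  set.seed(seed)
  data.frame(sens = runif(n), spec = runif(n))
}
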