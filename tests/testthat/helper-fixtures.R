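# constant greenhouse climate: the analytic backbone for simulator oracles
const_climate <- function(n, par = 375, temp = 20) {
  climate_series(seq_len(n), rep(par, n), rep(temp, n))
}

# day-by-day iteration of the first-order elongation law with a fractional
# final step: the independent oracle for frozen final lengths
iterate_elongation <- function(target, duration, k = 0.5, len = 3) {
  age <- 0
  while (age < duration) {
    frac <- min(1, duration - age)
    len <- len + frac * k * (target - len)
    age <- age + 1
  }
  len
}
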