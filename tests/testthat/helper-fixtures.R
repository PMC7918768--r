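# Hand-constructed fixtures with exactly known summary statistics.

# n = 1000 sample engineered to have sample SD exactly 1 and range exactly
# 10: {0, 10} plus 499 symmetric pairs 5 +/- c with c = sqrt(949/998)
# (SS = 50 + 998 c^2 = 999, so var = 999/999 = 1)
scott_fixture <- function() {
  c_ <- sqrt(949 / 998)
  c(0, 10, rep(5 - c_, 499), rep(5 + c_, 499))
}

# n = 1000 sample with IQR exactly 1 (type-7 quantiles: Q1 at sorted
# position 250.75, Q3 at 750.25) and range 10:
# 0, 350 @ 4.5, 298 @ 5, 350 @ 5.5, 10
fd_fixture <- function() {
  c(0, rep(4.5, 350), rep(5, 298), rep(5.5, 350), 10)
}

# small fixed cohort-like table used by the regression oracle tests
fixed_table <- function() {
  data.frame(
    subject_id = rep(1:4, each = 2),
    sex = rep(c("F", "F", "M", "M"), each = 2),
    side = rep(c("left", "right"), 4),
    age = c(25, 25, 31, 31, 28, 28, 36, 36),
    bmi = c(24, 24, 29, 29, 26, 26, 30, 30),
    feat = c(1.2, 1.9, 3.1, 2.4, 4.8, 5.2, 6.9, 7.3),
    MVIC = c(150, 148, 162, 170, 201, 214, 255, 241)
  )
}
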