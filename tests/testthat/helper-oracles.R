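# Independent oracles, deliberately implemented along different routes
# than the package code they check.

# Molar mass by brute-force token summation over the formula string.
oracle_mr <- function(text) {
  masses <- c(C = 12, H = 1, O = 16, N = 14, S = 32)
  s <- gsub("[ _]", "", text)
  total <- 0
  while (nzchar(s)) {
    el <- substr(s, 1, 1)
    s <- substr(s, 2, nchar(s))
    num <- regmatches(s, regexpr("^[0-9]+", s))
    n <- if (length(num)) as.numeric(num) else 1
    if (length(num)) s <- substr(s, nchar(num) + 1, nchar(s))
    total <- total + masses[[el]] * n
  }
  total
}

# Anaerobic mineralization coefficients by solving the elemental
# balance as a linear system (not the closed-form expressions):
# unknowns water w, ch4 m, co2 c with nh3 = d, h2s = e fixed.
#   C: m + c = x
#   H: y + 2w = 4m + 3d + 2e
#   O: z + w = 2c
oracle_buswell <- function(x, y, z = 0, d = 0, e = 0) {
  A <- rbind(
    c(0, 1, 1),   # C
    c(2, -4, 0),  # H
    c(1, 0, -2)   # O
  )
  b <- c(x, 3 * d + 2 * e - y, -z)
  sol <- solve(A, b)
  list(water = sol[1], ch4 = sol[2], co2 = sol[3], nh3 = d, h2s = e)
}

# Atoms on each side of the balanced reaction, from a coefficient set.
oracle_balance_gap <- function(f, co) {
  lhs <- c(C = f$x,
           H = f$y + 2 * co$water,
           O = f$z + co$water,
           N = f$d, S = f$e)
  rhs <- c(C = co$ch4 + co$co2,
           H = 4 * co$ch4 + 3 * co$nh3 + 2 * co$h2s,
           O = 2 * co$co2,
           N = co$nh3, S = co$h2s)
  max(abs(lhs - rhs))
}

# Random valid formulas (methane-positive not guaranteed).
random_formula_string <- function() {
  x <- sample(1:20, 1)
  y <- sample(0:40, 1)
  z <- sample(0:10, 1)
  d <- sample(0:3, 1)
  e <- sample(0:2, 1)
  paste0("C", x,
         if (y > 0) paste0("H", y) else "",
         if (z > 0) paste0("O", z) else "",
         if (d > 0) paste0("N", d) else "",
         if (e > 0) paste0("S", e) else "")
}

# A hand-built gas curve with an exact final value (L STP).
flat_rise_curve <- function(final_l, mode = "methane_production",
                            times = c(0, 10, 20, 30)) {
  gas_curve(times, final_l * seq(0, 1, length.out = length(times)),
            mode = mode)
}
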