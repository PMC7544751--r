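# Independent oracles used across the suite. These deliberately avoid the
# package's C++ paths: pure-R point-membership tests, brute-force fits,
# and quadrature-based densities.

# Pure-R inside/outside test for a placed region (signed-distance style
# oracle, independent of the C++ geometry kernel).
r_inside <- function(reg, p) {
  d <- p - reg$center
  s <- reg$shape
  if (s$kind == "box") return(all(abs(d) <= s$half))
  ax <- match(s$axis, c("x", "y", "z"))
  tr <- setdiff(1:3, ax)
  if (s$kind == "cylinder") {
    r2 <- sum(d[tr]^2)
    return(abs(d[ax]) <= s$half_length && r2 <= s$r_outer^2 &&
             (s$r_inner == 0 || r2 >= s$r_inner^2))
  }
  abs(d[ax]) <= s$half_length &&
    (d[tr[1]] / s$semi_a)^2 + (d[tr[2]] / s$semi_b)^2 <= 1
}

# Highest-priority region containing p, by brute force over the R-side
# region list (world last).
r_locate <- function(scene, p) {
  for (reg in scene$regions) if (r_inside(reg, p)) return(reg$name)
  "<outside>"
}

# Textbook normal-equations least squares.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Chi-square goodness of fit of draws against a (possibly unnormalised)
# density, integrated per bin by quadrature.
gof_pvalue <- function(draws, density, lower, upper, bins = 40) {
  br <- seq(lower, upper, length.out = bins + 1)
  obs <- as.numeric(table(cut(draws, br, include.lowest = TRUE)))
  pr <- vapply(seq_len(bins), function(i)
    integrate(density, br[i], br[i + 1])$value, 0)
  pr <- pr / sum(pr)
  expected <- length(draws) * pr
  chi <- sum((obs - expected)^2 / expected)
  stats::pchisq(chi, df = bins - 1, lower.tail = FALSE)
}

finger_slopes_from_tally <- function(tally, scene) {
  df <- dose_from_tally(tally, scene)
  df <- df[!is.na(df$finger), ]
  list(slope = stats::setNames(df$dose_Gy / tally$histories, df$finger),
       sigma = stats::setNames(df$sigma_Gy / tally$histories, df$finger))
}
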