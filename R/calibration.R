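#' Default class-conditional calibration targets
#'
#' Per-class (non-MAFLD = 0, MAFLD = 1) mean/Q1/Q3 targets for the 25
#' continuous variables and per-class positive rates for the 6 binary
#' features, describing the descriptive statistics of a T2DM clinic cohort.
#' These are the generator defaults; every entry is overridable through
#' [cohort_sim_config()].
#'
#' @return A list with elements `continuous` (data frame: name, class,
#'   mean, q1, q3) and `binary` (data frame: name, class, rate).
#' @export
mafld_calibration_targets <- function() {
  # name, mean0, q1_0, q3_0, mean1, q1_1, q3_1
  cont <- read.csv(text = "name,mean0,q1_0,q3_0,mean1,q1_1,q3_1
age,60.4,53,68,55.3,47,64
alkp,146.6,100,173,162.9,112,200
alt,21.5,15,25,38,24.5,48
ast,19.2,15,22,28,19,33
bmi,28.5,25.1,31.2,31.1,27.2,34.3
chl,171.4,140,198.5,181.1,148,208
cr,1,0.8,1.1,1,0.9,1.1
crp,1.4,1,1.4,1.8,1,1.9
dbp,76.8,70,80,79,75,80
ddm,11.4,4,17,10.3,4,15
fbs,157.5,121.5,182,158.1,121,179.5
hba1c,7.6,6.5,8.5,7.6,6.5,8.5
hdl,44.9,37,52,43.9,37,50
height,163.3,156,170,165.2,158,173
hip,104.7,100,109,109,102,114
homa,3.8,2.5,4.5,4.6,2.8,5.5
hpp2,210.9,154.5,250,213.3,150,255
insulin,9.7,8,10.3,12.1,8.1,14
ldl,95.6,71,117,102,77,124
plt,247.5,226.1,267.8,266.9,249.3,295
tg,160.7,103.5,195,182.6,115,226
ua,5,4,5.6,5.3,4.2,6
vitd,26.9,20,30,23.5,16.1,28.1
waist,98.1,91,103,103.2,96,110
weight,75.8,67,83,84.8,73,94", stringsAsFactors = FALSE)
  continuous <- rbind(
    data.frame(name = cont$name, class = 0L, mean = cont$mean0,
               q1 = cont$q1_0, q3 = cont$q3_0),
    data.frame(name = cont$name, class = 1L, mean = cont$mean1,
               q1 = cont$q1_1, q3 = cont$q3_1)
  )
  bin <- read.csv(text = "name,rate0,rate1
sex,0.490,0.584
cad,0.122,0.099
cva,0.011,0.006
htn,0.213,0.189
retino,0.060,0.044
smoking,0.019,0.016", stringsAsFactors = FALSE)
  binary <- rbind(
    data.frame(name = bin$name, class = 0L, rate = bin$rate0),
    data.frame(name = bin$name, class = 1L, rate = bin$rate1)
  )
  list(continuous = continuous, binary = binary)
}

Z25 <- stats::qnorm(0.25)
Z75 <- stats::qnorm(0.75)

# Skewness ratio r = (mean - Q1)/(Q3 - Q1) determines the log-normal shape:
# r -> 1/2 as sigma -> 0 (normal limit), r grows without bound with sigma.
lognorm_shape_ratio <- function(sigma) {
  (exp(sigma^2 / 2) - exp(sigma * Z25)) /
    (exp(sigma * Z75) - exp(sigma * Z25))
}

#' Solve a shifted log-normal to match a mean and quartile pair
#'
#' Finds (shift, mu, sigma) such that `shift + exp(mu + sigma * Z)` (Z
#' standard normal) has the requested mean, first and third quartile.
#' Right-skewed targets (mean above the quartile midpoint relative to the
#' IQR) use the direct family; left-skewed targets use the reflected
#' family `shift - exp(mu + sigma * Z)`; the symmetric boundary case
#' degenerates to a plain normal. Targets too extreme for the family fall
#' back to matching mean and Q3 only, with a flag.
#'
#' @param mean,q1,q3 targets, `q1 < q3`.
#' @return list(family, shift, mu, sigma, sd, fallback) where family is
#'   one of `"lognormal"`, `"reflected"`, `"normal"`.
#' @export
solve_shifted_lognormal <- function(mean, q1, q3) {
  stopifnot(q1 < q3)
  r <- (mean - q1) / (q3 - q1)
  eps <- 1e-4
  if (abs(r - 0.5) < eps) {
    return(list(family = "normal", shift = mean, mu = NA_real_,
                sigma = NA_real_, sd = (q3 - q1) / (Z75 - Z25),
                fallback = FALSE))
  }
  reflected <- r < 0.5
  rr <- if (reflected) 1 - r else r
  f <- function(s) lognorm_shape_ratio(s) - rr
  upper <- 12
  if (f(upper) < 0) {
    # Mean too far above Q3 for the family: match mean and Q3 only.
    sigma <- 1
    mu <- log((q3 - mean) / (exp(sigma * Z75) - exp(sigma^2 / 2)))
    if (!is.finite(mu)) mu <- 0
    shift <- mean - exp(mu + sigma^2 / 2)
    return(list(family = "lognormal", shift = shift, mu = mu, sigma = sigma,
                sd = NA_real_, fallback = TRUE))
  }
  sigma <- stats::uniroot(f, c(1e-8, upper), tol = 1e-12)$root
  if (reflected) {
    # X = shift - exp(mu + sigma Z); quartiles swap under reflection.
    scale <- (q3 - q1) / (exp(sigma * Z75) - exp(sigma * Z25))
    mu <- log(scale)
    shift <- mean + exp(mu + sigma^2 / 2)
    list(family = "reflected", shift = shift, mu = mu, sigma = sigma,
         sd = NA_real_, fallback = FALSE)
  } else {
    scale <- (q3 - q1) / (exp(sigma * Z75) - exp(sigma * Z25))
    mu <- log(scale)
    shift <- mean - exp(mu + sigma^2 / 2)
    list(family = "lognormal", shift = shift, mu = mu, sigma = sigma,
         sd = NA_real_, fallback = FALSE)
  }
}

# Quantile function of a solved marginal, vectorised over p.
shifted_lognormal_quantile <- function(par, p) {
  switch(par$family,
    normal = stats::qnorm(p, mean = par$shift, sd = par$sd),
    lognormal = par$shift + exp(par$mu + par$sigma * stats::qnorm(p)),
    reflected = par$shift - exp(par$mu + par$sigma * stats::qnorm(1 - p)),
    stop("unknown marginal family")
  )
}

shifted_lognormal_mean <- function(par) {
  switch(par$family,
    normal = par$shift,
    lognormal = par$shift + exp(par$mu + par$sigma^2 / 2),
    reflected = par$shift - exp(par$mu + par$sigma^2 / 2)
  )
}
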