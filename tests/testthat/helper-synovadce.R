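# Shared fixtures and independent oracles, built in code.

std_protocol <- dce_protocol("standard")
ltr_protocol <- dce_protocol("ltr")
pop_aif_std <- make_population_aif(aif_params(), std_protocol)
pop_aif_ltr <- make_population_aif(aif_params(), ltr_protocol)

# Independent convolution oracle: direct trapezoidal quadrature of the
# extended Tofts integral at each output time (O(n^2), no recursion).
oracle_tofts_ct <- function(ktrans, ve, vp, times_s, cp) {
  kep_s <- (ktrans / ve) / 60
  kt_s <- ktrans / 60
  vapply(seq_along(times_s), function(j) {
    ts <- times_s[1:j]
    f <- cp[1:j] * exp(-kep_s * (times_s[j] - ts))
    integral <- if (j == 1L) 0 else sum(diff(ts) * (f[-1L] + f[-j]) / 2)
    vp * cp[j] + kt_s * integral
  }, numeric(1))
}

# small boxcar AIF on a fine grid: cp = 1 on [0, T_s], 0 after
boxcar_aif <- function(T_s = 300, t_end = 400, dt = 0.1) {
  tt <- seq(0, t_end, by = dt)
  aif(tt, as.numeric(tt <= T_s))
}

# tiny pipeline config: small ROIs, fast fits
tiny_config <- function(seed = 1L, n_subjects = 2L, noise_sd = 0) {
  cfg <- default_config(seed = seed)
  cfg$simulation$n_subjects <- as.integer(n_subjects)
  cfg$simulation$population$volume_mean <- 300
  cfg$simulation$population$volume_sd <- 100
  cfg$simulation$population$noise_sd <- noise_sd
  cfg$simulation$grid_shape <- c(10L, 10L, 3L)
  cfg$simulation$voxel_size <- c(4, 4, 6)
  cfg
}

# balanced two-visit cohort table of plain correlated values, for the
# statistics modules (no imaging involved)
random_cohort_table <- function(n = 30, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    vars <- c("volume_mm3", "rer", "re_late", "re_max", "ve", "ktrans", "koos_pain")
    tab <- data.frame(subject_id = rep(sprintf("P%03d", 1:n), each = 2),
                      visit = rep(c("baseline", "followup"), n),
                      protocol = "standard")
    for (v in vars) {
      bl <- rnorm(n, 10, 2)
      fu <- bl * 0.8 + rnorm(n, 0, 1)
      tab[[v]] <- as.vector(rbind(bl, fu))
    }
    tab
  })
}
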