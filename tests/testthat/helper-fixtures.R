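# Published pediatric extrapolation grid (adult row omitted), used to check
# the allometric rebuild.  Column order matches pediatric_parameter_table().
published_pediatric_grid <- function() {
  cols <- c("cl", "v2", "q", "v3", "ka", "v4", "clm", "q1", "v5",
            "alag1", "fm", "clm1")
  m <- matrix(c(
    174.13,  93.28, 24.89, 140.19, 5.22,  34.10,  4.71, 16.61,  80.83, 0.160, 0.70,  60.07,
    165.27,  87.00, 23.62, 130.76, 5.22,  31.81,  4.47, 15.76,  75.39, 0.160, 0.70,  57.02,
    260.33, 159.46, 37.21, 239.65, 5.22,  58.29,  7.04, 24.83, 138.18, 0.160, 0.70,  89.81,
    259.33, 158.65, 37.06, 238.43, 5.22,  58.00,  7.01, 24.74, 137.47, 0.160, 0.70,  89.47,
    433.78, 315.00, 62.00, 473.42, 5.22, 115.16, 11.72, 41.38, 272.96, 0.160, 0.70, 149.65,
    439.41, 320.47, 62.80, 481.63, 5.22, 117.15, 11.88, 41.92, 277.70, 0.160, 0.70, 151.59,
    589.42, 474.09, 84.24, 712.51, 5.22, 173.31, 15.93, 56.22, 410.82, 0.160, 0.70, 203.35,
    522.85, 404.07, 74.73, 607.28, 5.22, 147.72, 14.13, 49.87, 350.14, 0.160, 0.70, 180.38),
    nrow = 8, byrow = TRUE, dimnames = list(NULL, cols))
  cells <- data.frame(age_years = rep(c(2, 6, 12, 17), each = 2),
                      sex = rep(c("F", "M"), 4))
  cbind(cells, as.data.frame(m))
}

# dense grid for mass-balance AUC checks (SPIR t1/2 ~ 8 h, CAN ~ 30 h)
dense_auc_grid <- function() {
  sort(unique(c(seq(0, 2, 0.02), seq(2, 24, 0.1), seq(24, 120, 0.5),
                seq(121, 400, 2))))
}

# random but physiologic parameter draw for property tests
random_params <- function() {
  jit <- function(x) x * exp(stats::runif(1, -0.5, 0.5))
  pk_params(cl = jit(629), clm1 = jit(217), v2 = jit(517), q = jit(89.9),
            v3 = jit(777), ka = jit(5.22), alag1 = stats::runif(1, 0, 0.5),
            fm = stats::runif(1, 0.3, 0.95), clm = jit(17), v4 = jit(189),
            q1 = jit(60), v5 = jit(448))
}
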