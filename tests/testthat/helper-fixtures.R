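# small in-code fixtures shared across test files

flat_image <- function(rgb, h = 4, w = 5) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# independent OLS oracle: normal equations, intercept first
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# independent oracle for the 3x4 affine chip fit: one normal-equations
# solve per output channel
affine_fit_oracle <- function(obs, ref) {
  X <- cbind(as.matrix(obs), 1)
  t(solve(crossprod(X), crossprod(X, as.matrix(ref))))
}

rms <- function(x) sqrt(mean(x^2))

cohort_features <- function(cohort) {
  data.frame(sample_id = cohort$samples$sample_id,
             v_l_mv = cohort$samples$v_l_mv,
             r_over_g = cohort$samples$r_over_g,
             label = cohort$samples$class_label)
}
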