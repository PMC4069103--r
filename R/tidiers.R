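# broom-style accessors for the fitted objects

#' @exportS3Method generics::tidy
tidy.phstab_infit <- function(x, ...) {
  tibble::tibble(
    term = c("A_0", "k_in"),
    estimate = c(x$A_0, x$k_in),
    std.error = c(x$A_0_se, x$k_in_se)
  )
}

#' @exportS3Method generics::glance
glance.phstab_infit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n)
}

#' @exportS3Method generics::tidy
tidy.phstab_mmfit <- function(x, ...) {
  tibble::tibble(
    term = c("k_cat", "K_M"),
    estimate = c(x$k_cat, x$K_M),
    std.error = c(x$k_cat_se, x$K_M_se)
  )
}

#' @exportS3Method generics::glance
glance.phstab_mmfit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, nobs = x$n,
    efficiency = x$efficiency
  )
}
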