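#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed for a named stage, derived from the master seed.
# Keeps each stage on its own stream: adding draws in one stage never
# perturbs another stage's output.
stream_seed <- function(master_seed, label) {
  s <- as.double(master_seed %% 2147483647L)
  for (ch in utf8ToInt(label)) s <- (s * 31 + ch) %% 2147483647
  as.integer(max(1, s))
}

with_stream <- function(master_seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(master_seed, label))
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("configuration error: '%s' must be a single number in [%s, %s]",
          name, format(lower), format(upper))
  invisible(x)
}

#' Sample group labels
#'
#' The four disease states of the cohort: normal donor liver (NOR),
#' HCV-cirrhosis (CIR), early-stage tumors T1/T2 (HCC_EARLY) and
#' late-stage tumors T3/T4 (HCC_LATE).
#'
#' @return Character vector of the four group labels, in cohort order.
#' @export
sample_groups <- function() c("NOR", "CIR", "HCC_EARLY", "HCC_LATE")
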