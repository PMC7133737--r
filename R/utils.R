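#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef lm median quantile runif rlnorm sd setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Evaluate `code` with a temporary RNG seed; the caller's RNG state is
# restored on exit so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop_domain(sprintf("`%s` = %g is outside its admissible range", name, x))
  invisible(x)
}

rel_diff <- function(a, b) abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)

extdata <- function(file) {
  path <- system.file("extdata", file, package = "salivapk")
  if (!nzchar(path)) {
    # during in-source development (pkgload) inst/ may not be flattened yet
    path <- system.file("inst", "extdata", file, package = "salivapk")
  }
  if (!nzchar(path)) stop_domain("fixture file not found: ", file)
  path
}
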