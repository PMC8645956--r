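# Internal helpers shared across modules.

# Energy unit: 1 cmH2O * 1 L = 0.0980665 J.
.CMH2O_L_TO_J <- 0.0980665

#' Joules per cmH2O-litre
#'
#' Conversion constant used for all mechanical energy/power results:
#' 1 cmH2O x 1 L = 0.0980665 J.
#'
#' @return A single numeric value.
#' @export
cmh2o_l_to_joule <- function() .CMH2O_L_TO_J

.stop_data <- function(...) stop(sprintf(...), call. = FALSE)

# Cumulative trapezoid zeroed at the first sample.
.cumtrapz0 <- function(x, y) {
  if (length(x) < 2L) return(rep(0, length(x)))
  as.numeric(pracma::cumtrapz(x, y))
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

# Local seeding: set the RNG when a seed is supplied without touching the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
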