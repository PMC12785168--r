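# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentage summaries in
#' the field round half away from zero (60.79 -> 61, 71.945 -> 71.95 at two
#' digits), so that convention is used wherever percentages are reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded with halves moving away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Min-max normalization to [0, 1]; a constant vector maps to all zeros so a
# metric that does not discriminate contributes nothing to a composite score.
minmax01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Stable, platform-independent integer hash of a string, used to derive
# per-target RNG seeds from a single pipeline seed. Kept below 2^31 together
# with any base seed it is added to.
stable_hash <- function(s) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 1000003
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the package log level
#'
#' @param level one of "debug", "info", "warn", "error".
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("organgrn.log_level", "info")
  options(organgrn.log_level = level)
  invisible(old)
}

grn_log <- function(level, ...) {
  cur <- getOption("organgrn.log_level", "info")
  if (log_levels[[level]] >= log_levels[[cur]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

# Directed pairs are keyed as "regulator\ttarget" for set operations.
pair_key <- function(regulator, target) paste(regulator, target, sep = "\t")
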