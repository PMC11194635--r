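# Internal helpers shared across modules.

#' @useDynLib radlung, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate approx cor median pchisq predict quantile
#'   rbinom rlnorm rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed from a master seed and a string tag
#'
#' A cohort run uses one master seed; every per-patient or per-stage
#' random draw is made under a sub-seed derived from the master seed and
#' a stable tag (e.g. the patient identifier), so partial reruns
#' reproduce individual patients without replaying the whole stream.
#' Implemented as a polynomial rolling hash modulo a Mersenne prime so
#' the result is identical across platforms and fits in a 32-bit
#' integer.
#'
#' @param seed Master integer seed.
#' @param ... Character or numeric tags appended to the hash stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), function(x) paste(as.character(x),
                                                    collapse = ","),
                       character(1)), collapse = "|")
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tags)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# md5 of an R object via its serialized form written to a temp file;
# used for config fingerprints and manifest hashes.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

file_md5 <- function(path) unname(tools::md5sum(path))

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 1

# Validate that a config list only uses known keys (strict mode).
check_known_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  assert_that(length(unknown) == 0, "unknown %s key(s): %s", where,
              paste(unknown, collapse = ", "))
  invisible(TRUE)
}
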